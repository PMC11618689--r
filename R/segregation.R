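# Stage 2: pedigree-based inheritance-mode calling per proband.
#
# Four callers share one prepared representation: a genotype lookup where a
# genotype is "observed" only if it passed the quality filter. A missing or
# quality-failed genotype in a relative is unknown — it never counts as
# homozygous reference, so sequencing dropout cannot create de novo calls.

# Build shared structures: observed-genotype lookup and per-proband relatives.
prep_segregation <- function(genotypes, pedigree, freq_class) {
  if (!"qc_pass" %in% names(genotypes)) {
    genotypes <- apply_quality_filter(genotypes)
  }
  geno <- genotypes |>
    dplyr::mutate(
      variant_key = variant_key(chrom, pos, ref, alt),
      gt_obs = ifelse(qc_pass, gt, NA_integer_)
    )
  genotyped <- unique(geno$sample_id)
  probands <- pedigree |> dplyr::filter(role == "proband")
  relatives <- probands |>
    dplyr::select(proband_id = individual_id, family_id,
                  father_id, mother_id) |>
    dplyr::mutate(
      father_id = ifelse(father_id %in% genotyped, father_id, NA_character_),
      mother_id = ifelse(mother_id %in% genotyped, mother_id, NA_character_)
    )
  sibs <- pedigree |>
    dplyr::filter(role == "sibling", individual_id %in% genotyped) |>
    dplyr::select(family_id, sibling_id = individual_id)
  list(geno = geno, probands = probands, relatives = relatives,
       siblings = sibs, freq = freq_class)
}

# Summarise relatives' genotypes at each candidate: clear / carrier / unknown.
relative_status <- function(cand, rel_long, geno) {
  if (nrow(rel_long) == 0) {
    return(dplyr::mutate(cand, rel_carrier = FALSE, rel_unknown = FALSE))
  }
  status <- rel_long |>
    dplyr::inner_join(cand[, c("proband_id", "variant_key")],
                      by = "proband_id", relationship = "many-to-many") |>
    dplyr::left_join(
      dplyr::select(geno, sample_id, variant_key, gt_obs),
      by = c(rel_id = "sample_id", "variant_key")
    ) |>
    dplyr::group_by(proband_id, variant_key) |>
    dplyr::summarise(
      rel_carrier = any(!is.na(gt_obs) & gt_obs >= 1L),
      rel_unknown = any(is.na(gt_obs)),
      .groups = "drop"
    )
  cand |>
    dplyr::left_join(status, by = c("proband_id", "variant_key")) |>
    dplyr::mutate(rel_carrier = tidyr::replace_na(rel_carrier, FALSE),
                  rel_unknown = tidyr::replace_na(rel_unknown, FALSE))
}

pass_fail <- function(x) ifelse(x, "pass", "fail")

#' Call de novo variants
#'
#' A de novo variant is a heterozygous *private* variant in a proband, absent
#' (observed homozygous reference) from the father, the mother, and the
#' sibling(s) when available. The proband genotype must additionally satisfy
#' (1) GQ >= 99, (2) AD-Alt >= 10, (3) AD-Ref >= 10, (4) allele balance
#' AD-Alt/DP in \[0.3, 0.7\]; the site must satisfy (5) QUAL >= 999 and
#' (6) both alleles <= 50 bp. An unknown genotype in an available relative
#' makes the candidate not-evaluable rather than de novo; with both parents
#' missing the mode is not evaluable at all.
#'
#' @param genotypes Long genotype tibble (quality columns added if absent).
#' @param pedigree Pedigree tibble ([read_pedigree()]).
#' @param freq_class Frequency classes from [classify_frequency()].
#' @return One row per evaluated proband-variant candidate with per-criterion
#'   evidence columns (`"pass"`/`"fail"`/`"not-evaluable"`), `one_parent_only`,
#'   and `called` (logical). Candidates are private het proband genotypes.
#' @export
call_de_novo <- function(genotypes, pedigree, freq_class) {
  prep <- prep_segregation(genotypes, pedigree, freq_class)
  private_keys <- prep$freq$variant_key[prep$freq$is_private]
  cand <- prep$geno |>
    dplyr::filter(sample_id %in% prep$probands$individual_id,
                  qc_pass, !is.na(gt), gt == 1L,
                  variant_key %in% private_keys) |>
    dplyr::rename(proband_id = sample_id) |>
    dplyr::left_join(prep$relatives, by = "proband_id")
  if (nrow(cand) == 0) return(empty_de_novo())
  rel_long <- dplyr::bind_rows(
    prep$relatives |>
      dplyr::filter(!is.na(father_id)) |>
      dplyr::transmute(proband_id, rel_id = father_id),
    prep$relatives |>
      dplyr::filter(!is.na(mother_id)) |>
      dplyr::transmute(proband_id, rel_id = mother_id),
    prep$relatives |>
      dplyr::inner_join(prep$siblings, by = "family_id",
                        relationship = "many-to-many") |>
      dplyr::transmute(proband_id, rel_id = sibling_id)
  )
  cand <- relative_status(cand, rel_long, prep$geno)
  cand |>
    dplyr::mutate(
      n_parents = (!is.na(father_id)) + (!is.na(mother_id)),
      crit_gq = pass_fail(!is.na(gq) & gq >= 99),
      crit_ad_alt = pass_fail(!is.na(ad_alt) & ad_alt >= 10),
      crit_ad_ref = pass_fail(!is.na(ad_ref) & ad_ref >= 10),
      crit_allele_balance = pass_fail(
        !is.na(ad_alt) & !is.na(dp) & dp > 0 &
          ad_alt / dp >= 0.3 & ad_alt / dp <= 0.7),
      crit_site_qual = pass_fail(!is.na(qual) & qual >= 999),
      crit_allele_len = pass_fail(nchar(ref) <= 50 & nchar(alt) <= 50),
      crit_absent_relatives = dplyr::case_when(
        n_parents == 0L ~ "not-evaluable",
        rel_carrier ~ "fail",
        rel_unknown ~ "not-evaluable",
        TRUE ~ "pass"
      ),
      one_parent_only = n_parents == 1L,
      called = crit_gq == "pass" & crit_ad_alt == "pass" &
        crit_ad_ref == "pass" & crit_allele_balance == "pass" &
        crit_site_qual == "pass" & crit_allele_len == "pass" &
        crit_absent_relatives == "pass"
    ) |>
    dplyr::select(proband_id, family_id, chrom, pos, ref, alt, variant_key,
                  dplyr::starts_with("crit_"), one_parent_only, called)
}

empty_de_novo <- function() {
  tibble::tibble(
    proband_id = character(0), family_id = character(0),
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), variant_key = character(0),
    crit_gq = character(0), crit_ad_alt = character(0),
    crit_ad_ref = character(0), crit_allele_balance = character(0),
    crit_site_qual = character(0), crit_allele_len = character(0),
    crit_absent_relatives = character(0),
    one_parent_only = logical(0), called = logical(0)
  )
}

#' Call compound heterozygous variant pairs
#'
#' Inherited heterozygous variants in the same gene, one present in
#' heterozygous form in the father only and one in the mother only, both het
#' in the proband. Each member must pass AD-Alt >= 10, AD-Ref >= 10, and
#' allele balance in \[0.3, 0.7\] on the proband genotype. Calling requires
#' both parents; probands with a missing parent yield no pairs (the mode is
#' not possible).
#'
#' @inheritParams call_de_novo
#' @param annotation Annotation tibble supplying the `gene` column.
#' @return One row per unordered qualifying pair: proband, gene, the paternal
#'   variant (`*_1`, origin father) and the maternal variant (`*_2`).
#' @export
call_compound_het <- function(genotypes, pedigree, freq_class, annotation) {
  prep <- prep_segregation(genotypes, pedigree, freq_class)
  if (!"variant_key" %in% names(annotation)) {
    annotation <- dplyr::mutate(
      annotation, variant_key = variant_key(chrom, pos, ref, alt))
  }
  rare_keys <- prep$freq$variant_key[prep$freq$is_rare]
  both_parents <- prep$relatives |>
    dplyr::filter(!is.na(father_id), !is.na(mother_id))
  cand <- prep$geno |>
    dplyr::filter(sample_id %in% both_parents$proband_id,
                  qc_pass, !is.na(gt), gt == 1L,
                  variant_key %in% rare_keys,
                  !is.na(ad_alt), !is.na(ad_ref), !is.na(dp), dp > 0,
                  ad_alt >= 10, ad_ref >= 10,
                  ad_alt / dp >= 0.3, ad_alt / dp <= 0.7) |>
    dplyr::rename(proband_id = sample_id) |>
    dplyr::inner_join(both_parents, by = "proband_id") |>
    dplyr::inner_join(dplyr::select(annotation, variant_key, gene),
                      by = "variant_key") |>
    dplyr::filter(!is.na(gene))
  if (nrow(cand) == 0) return(empty_compound_het())
  lut_f <- dplyr::transmute(prep$geno, sample_id, variant_key,
                            gt_father = gt_obs)
  lut_m <- dplyr::transmute(prep$geno, sample_id, variant_key,
                            gt_mother = gt_obs)
  cand <- cand |>
    dplyr::left_join(lut_f, by = c(father_id = "sample_id", "variant_key")) |>
    dplyr::left_join(lut_m, by = c(mother_id = "sample_id", "variant_key")) |>
    dplyr::mutate(origin = dplyr::case_when(
      !is.na(gt_father) & gt_father == 1L &
        !is.na(gt_mother) & gt_mother == 0L ~ "father",
      !is.na(gt_mother) & gt_mother == 1L &
        !is.na(gt_father) & gt_father == 0L ~ "mother",
      TRUE ~ NA_character_
    )) |>
    dplyr::filter(!is.na(origin))
  pat <- cand |> dplyr::filter(origin == "father")
  mat <- cand |> dplyr::filter(origin == "mother")
  pairs <- dplyr::inner_join(
    dplyr::select(pat, proband_id, family_id, gene,
                  chrom_1 = chrom, pos_1 = pos, ref_1 = ref, alt_1 = alt,
                  variant_key_1 = variant_key),
    dplyr::select(mat, proband_id, gene,
                  chrom_2 = chrom, pos_2 = pos, ref_2 = ref, alt_2 = alt,
                  variant_key_2 = variant_key),
    by = c("proband_id", "gene"), relationship = "many-to-many"
  )
  dplyr::arrange(pairs, proband_id, gene, variant_key_1, variant_key_2)
}

empty_compound_het <- function() {
  tibble::tibble(
    proband_id = character(0), family_id = character(0), gene = character(0),
    chrom_1 = character(0), pos_1 = integer(0), ref_1 = character(0),
    alt_1 = character(0), variant_key_1 = character(0),
    chrom_2 = character(0), pos_2 = integer(0), ref_2 = character(0),
    alt_2 = character(0), variant_key_2 = character(0)
  )
}

#' Call inherited homozygous variants
#'
#' A rare variant homozygous-alternate in the proband, present in
#' heterozygous form in both parents (the available parent when one is
#' missing, flagged `one_parent_only`), and not homozygous in either parent
#' or in any unaffected sibling (full-penetrance assumption). Chromosome-X
#' alternate calls in male probands are hemizygous rather than homozygous
#' and are left to the X-linked caller.
#'
#' @inheritParams call_de_novo
#' @return One row per call with `one_parent_only` and `called`.
#' @export
call_inherited_homozygous <- function(genotypes, pedigree, freq_class) {
  prep <- prep_segregation(genotypes, pedigree, freq_class)
  rare_keys <- prep$freq$variant_key[prep$freq$is_rare]
  sex_of <- stats::setNames(prep$probands$sex, prep$probands$individual_id)
  cand <- prep$geno |>
    dplyr::filter(sample_id %in% prep$probands$individual_id,
                  qc_pass, !is.na(gt), gt == 2L,
                  variant_key %in% rare_keys) |>
    # chrX alt calls in males are hemizygous, not homozygous: they belong
    # to the X-linked caller, not the autosomal recessive one
    dplyr::filter(!(is_chrx(chrom) &
                      unname(sex_of[sample_id]) == "male")) |>
    dplyr::rename(proband_id = sample_id) |>
    dplyr::left_join(prep$relatives, by = "proband_id")
  if (nrow(cand) == 0) return(empty_simple_call())
  lut_f <- dplyr::transmute(prep$geno, sample_id, variant_key,
                            gt_father = gt_obs)
  lut_m <- dplyr::transmute(prep$geno, sample_id, variant_key,
                            gt_mother = gt_obs)
  lut <- dplyr::select(prep$geno, sample_id, variant_key, gt_obs)
  cand <- cand |>
    dplyr::select(-gt_obs) |>
    dplyr::left_join(lut_f, by = c(father_id = "sample_id", "variant_key")) |>
    dplyr::left_join(lut_m, by = c(mother_id = "sample_id", "variant_key"))
  sib_hom <- prep$relatives |>
    dplyr::inner_join(prep$siblings, by = "family_id",
                      relationship = "many-to-many") |>
    dplyr::transmute(proband_id, rel_id = sibling_id) |>
    dplyr::inner_join(cand[, c("proband_id", "variant_key")],
                      by = "proband_id", relationship = "many-to-many") |>
    dplyr::left_join(lut, by = c(rel_id = "sample_id", "variant_key")) |>
    dplyr::group_by(proband_id, variant_key) |>
    dplyr::summarise(sib_is_hom = any(!is.na(gt_obs) & gt_obs >= 2L),
                     .groups = "drop")
  cand |>
    dplyr::left_join(sib_hom, by = c("proband_id", "variant_key")) |>
    dplyr::mutate(
      sib_is_hom = tidyr::replace_na(sib_is_hom, FALSE),
      n_parents = (!is.na(father_id)) + (!is.na(mother_id)),
      father_ok = is.na(father_id) | (!is.na(gt_father) & gt_father == 1L),
      mother_ok = is.na(mother_id) | (!is.na(gt_mother) & gt_mother == 1L),
      one_parent_only = n_parents == 1L,
      called = n_parents >= 1L & father_ok & mother_ok & !sib_is_hom
    ) |>
    dplyr::filter(called) |>
    dplyr::select(proband_id, family_id, chrom, pos, ref, alt, variant_key,
                  one_parent_only, called)
}

empty_simple_call <- function() {
  tibble::tibble(
    proband_id = character(0), family_id = character(0),
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), variant_key = character(0),
    one_parent_only = logical(0), called = logical(0)
  )
}

#' Call X-linked recessive variants
#'
#' Rare chromosome-X variants outside the pseudoautosomal regions, present in
#' a male proband (hemizygous: haploid dosage 1 or diploid homozygous
#' encoding) and heterozygous in the mother. The father's genotype is not
#' consulted. With the mother missing the mode is not evaluable. Female
#' probands are excluded by default; `allow_female_probands = TRUE` relaxes
#' this (calls are then flagged in `female_proband`).
#'
#' @inheritParams call_de_novo
#' @param allow_female_probands Permit affected female carriers (default
#'   FALSE).
#' @param exclude_par Exclude PAR1/PAR2 positions (default TRUE).
#' @return One row per call with `one_parent_only`, `female_proband`,
#'   `called`.
#' @export
call_x_linked <- function(genotypes, pedigree, freq_class,
                          allow_female_probands = FALSE,
                          exclude_par = TRUE) {
  prep <- prep_segregation(genotypes, pedigree, freq_class)
  rare_keys <- prep$freq$variant_key[prep$freq$is_rare]
  sex_of <- stats::setNames(prep$probands$sex, prep$probands$individual_id)
  cand <- prep$geno |>
    dplyr::filter(sample_id %in% prep$probands$individual_id,
                  qc_pass, !is.na(gt),
                  is_chrx(chrom),
                  variant_key %in% rare_keys) |>
    dplyr::rename(proband_id = sample_id)
  if (exclude_par && nrow(cand) > 0) {
    cand <- cand |> dplyr::filter(!in_par_region(chrom, pos))
  }
  if (nrow(cand) == 0) return(empty_x_linked())
  cand <- cand |>
    dplyr::mutate(
      sex = unname(sex_of[proband_id]),
      hemizygous = (ploidy == 1L & gt == 1L) | gt == 2L
    ) |>
    dplyr::filter(hemizygous,
                  sex == "male" | allow_female_probands) |>
    dplyr::left_join(prep$relatives, by = "proband_id")
  if (nrow(cand) == 0) return(empty_x_linked())
  lut_m <- dplyr::transmute(prep$geno, sample_id, variant_key,
                            gt_mother = gt_obs)
  cand |>
    dplyr::left_join(lut_m, by = c(mother_id = "sample_id", "variant_key")) |>
    dplyr::mutate(
      mother_available = !is.na(mother_id),
      mother_het = mother_available & !is.na(gt_mother) & gt_mother == 1L,
      one_parent_only = is.na(father_id) | is.na(mother_id),
      female_proband = sex == "female",
      called = mother_het
    ) |>
    dplyr::filter(called) |>
    dplyr::select(proband_id, family_id, chrom, pos, ref, alt, variant_key,
                  one_parent_only, female_proband, called)
}

empty_x_linked <- function() {
  tibble::tibble(
    proband_id = character(0), family_id = character(0),
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), variant_key = character(0),
    one_parent_only = logical(0), female_proband = logical(0),
    called = logical(0)
  )
}

#' Run all four inheritance-mode callers
#'
#' Orchestrates [call_de_novo()], [call_compound_het()],
#' [call_inherited_homozygous()], and [call_x_linked()]. De novo, homozygous,
#' and X-linked calling run with one parent when the other is missing
#' (flagged `one_parent_only`); compound-het calling requires both parents.
#' Compound-het pairs are emitted as two rows sharing a `pair_id`, with
#' `partner_variant_key` linking the members.
#'
#' @inheritParams call_compound_het
#' @param ... Passed to [call_x_linked()].
#' @return A tibble of inheritance calls: `proband_id`, `family_id`, `mode`
#'   (`de_novo`, `compound_het`, `inherited_hom`, `x_linked`), variant key
#'   columns, `pair_id`/`partner_variant_key` (compound het only),
#'   `one_parent_only`.
#' @export
segregate_all <- function(genotypes, pedigree, freq_class, annotation, ...) {
  dn <- call_de_novo(genotypes, pedigree, freq_class) |>
    dplyr::filter(called) |>
    dplyr::transmute(proband_id, family_id, mode = "de_novo",
                     chrom, pos, ref, alt, variant_key,
                     pair_id = NA_character_,
                     partner_variant_key = NA_character_, one_parent_only)
  ch_pairs <- call_compound_het(genotypes, pedigree, freq_class, annotation)
  ch <- if (nrow(ch_pairs) == 0) NULL else {
    ch_pairs <- dplyr::mutate(
      ch_pairs,
      pair_id = paste(proband_id, gene,
                      seq_len(nrow(ch_pairs)), sep = "|"))
    dplyr::bind_rows(
      ch_pairs |>
        dplyr::transmute(proband_id, family_id, mode = "compound_het",
                         chrom = chrom_1, pos = pos_1, ref = ref_1,
                         alt = alt_1, variant_key = variant_key_1, pair_id,
                         partner_variant_key = variant_key_2,
                         one_parent_only = FALSE),
      ch_pairs |>
        dplyr::transmute(proband_id, family_id, mode = "compound_het",
                         chrom = chrom_2, pos = pos_2, ref = ref_2,
                         alt = alt_2, variant_key = variant_key_2, pair_id,
                         partner_variant_key = variant_key_1,
                         one_parent_only = FALSE)
    )
  }
  ih <- call_inherited_homozygous(genotypes, pedigree, freq_class) |>
    dplyr::transmute(proband_id, family_id, mode = "inherited_hom",
                     chrom, pos, ref, alt, variant_key,
                     pair_id = NA_character_,
                     partner_variant_key = NA_character_, one_parent_only)
  xl <- call_x_linked(genotypes, pedigree, freq_class, ...) |>
    dplyr::transmute(proband_id, family_id, mode = "x_linked",
                     chrom, pos, ref, alt, variant_key,
                     pair_id = NA_character_,
                     partner_variant_key = NA_character_, one_parent_only)
  dplyr::bind_rows(dn, ch, ih, xl) |>
    dplyr::arrange(proband_id, mode, variant_key)
}

#' Per-proband inheritance-mode counts
#'
#' @param calls Output of [segregate_all()].
#' @return Tibble with one row per (proband, mode) and `n` calls (compound
#'   het counted as variants, i.e., two per pair).
#' @export
count_calls_per_proband <- function(calls) {
  calls |> dplyr::count(proband_id, mode, name = "n")
}
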