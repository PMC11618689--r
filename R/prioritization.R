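# Stage 3: damaging classification, known/novel gene tiering, the seven-step
# prioritization ladder, the oversized-gene missense-rate filter, and final
# within-proband ranking.

#' Classify variants as possibly damaging
#'
#' A variant is possibly damaging if it is (1) a splice-site variant, (2) an
#' exonic variant with a predicted protein effect of frameshift indel,
#' nonframeshift indel, stopgain, stoploss, or unknown effect, or (3) an
#' exonic nonsynonymous SNV predicted damaging by at least one of SIFT and
#' PolyPhen-2 HumVar. Synonymous SNVs and benign-predicted missense are not
#' damaging; absent predictions count as not damaging for basis (3).
#'
#' @param annotation Annotation tibble with `effect` and the two prediction
#'   columns.
#' @return The input with `is_possibly_damaging` (logical) and
#'   `damaging_basis` (`"splice-site"`,
#'   `"protein-truncating-or-indel-or-unknown"`, `"missense-predicted"`, or
#'   `NA`).
#' @export
classify_damaging <- function(annotation) {
  basis2 <- c("frameshift-insertion", "frameshift-deletion",
              "nonframeshift-insertion", "nonframeshift-deletion",
              "stopgain", "stoploss", "unknown")
  annotation |>
    dplyr::mutate(
      damaging_basis = dplyr::case_when(
        effect == "splice-site" ~ "splice-site",
        effect %in% basis2 ~ "protein-truncating-or-indel-or-unknown",
        effect == "nonsynonymous-SNV" &
          (dplyr::coalesce(sift_damaging, FALSE) |
             dplyr::coalesce(polyphen_humvar_damaging, FALSE)) ~
          "missense-predicted",
        TRUE ~ NA_character_
      ),
      is_possibly_damaging = !is.na(damaging_basis)
    )
}

#' Tier genes as known or novel
#'
#' A gene is "known" iff its SFARI Gene score is 1, 2, or S, or it is
#' OMIM-annotated with a neurological phenotype; all other genes (including
#' SFARI score 3 and genes absent from the metadata) are "novel".
#'
#' @param gene_metadata Gene metadata tibble ([read_gene_metadata()]).
#' @return The input with a `tier` column (`"known"`/`"novel"`).
#' @export
tier_gene <- function(gene_metadata) {
  gene_metadata |>
    dplyr::mutate(
      tier = ifelse(
        (!is.na(sfari_score) & sfari_score %in% c("1", "2", "S")) |
          dplyr::coalesce(omim_neuro, FALSE),
        "known", "novel")
    )
}

# Does a ClinVar label assert only benign / likely benign?
clinvar_is_benign <- function(x) {
  toks <- stringr::str_split(stringr::str_to_lower(
    gsub("_", " ", ifelse(is.na(x), "", x))), "[/;,|]")
  vapply(toks, function(t) {
    t <- trimws(t)
    t <- t[t != ""]
    length(t) > 0 && all(t %in% c("benign", "likely benign"))
  }, logical(1))
}

#' Run the seven-step prioritization ladder
#'
#' Only possibly-damaging inheritance calls enter the ladder; other calls are
#' carried through with every step marked not-applicable. The steps are:
#' (1) exclude a variant present in more than one unrelated person (different
#' family); (2) assign the known/novel gene tier; (3) flag genes recurrently
#' hit by different variants in different people; (4) score deleteriousness
#' from SIFT, PolyPhen-2 HumVar, VEST, CADD, and phyloP; (5) flag constrained
#' genes (pLI > 0.5 and LOEUF < 0.5); (6) drop ClinVar benign / likely
#' benign; (7) drop variants with one or more homozygous carriers in gnomAD.
#' Steps 3-5 are rank components, not filters; only steps 1, 6, and 7 remove
#' variants. The full step trace is retained for audit.
#'
#' @param calls Inheritance calls from [segregate_all()].
#' @param annotation Annotation tibble.
#' @param gene_metadata Gene metadata tibble.
#' @param vest_min,cadd_min,phylop_min Conventional thresholds for counting a
#'   VEST / CADD / phyloP score as supporting deleteriousness (defaults 0.5,
#'   20, 2).
#' @return One row per input call with `entered`, `tier`, `recurrent_gene`,
#'   `deleterious_score`, `constraint_priority`, step trace columns
#'   `step1`..`step7` (`"kept"`/`"dropped"`/`"na"`), `kept`, and
#'   `dropped_step` (first dropping step or `NA`).
#' @export
prioritize_candidates <- function(calls, annotation, gene_metadata,
                                  vest_min = 0.5, cadd_min = 20,
                                  phylop_min = 2) {
  if (!"variant_key" %in% names(annotation)) {
    annotation <- dplyr::mutate(
      annotation, variant_key = variant_key(chrom, pos, ref, alt))
  }
  ann <- classify_damaging(annotation)
  gm <- tier_gene(gene_metadata)
  p <- calls |>
    dplyr::left_join(
      dplyr::select(ann, variant_key, gene, effect, damaging_basis,
                    is_possibly_damaging,
                    dplyr::any_of(c("sift_damaging",
                                    "polyphen_humvar_damaging", "vest",
                                    "cadd", "phylop", "alphamissense",
                                    "clinvar_significance",
                                    "gnomad_hom_carriers"))),
      by = "variant_key"
    ) |>
    dplyr::mutate(
      entered = dplyr::coalesce(is_possibly_damaging, FALSE),
      tier = "novel"
    )
  for (col in c("sift_damaging", "polyphen_humvar_damaging", "vest", "cadd",
                "phylop", "alphamissense", "clinvar_significance",
                "gnomad_hom_carriers")) {
    if (!col %in% names(p)) p[[col]] <- NA
  }
  # step 1: exact same variant in more than one unrelated person
  fam_per_key <- p |>
    dplyr::filter(entered) |>
    dplyr::distinct(variant_key, family_id) |>
    dplyr::count(variant_key, name = "n_families")
  p <- p |>
    dplyr::left_join(fam_per_key, by = "variant_key") |>
    dplyr::mutate(
      shared_cross_family = entered &
        dplyr::coalesce(n_families, 0L) > 1L)
  # step 2: gene tier
  p <- p |>
    dplyr::select(-tier) |>
    dplyr::left_join(dplyr::select(gm, gene = symbol, tier,
                                   dplyr::any_of(c("pli", "loeuf"))),
                     by = "gene") |>
    dplyr::mutate(tier = dplyr::coalesce(tier, "novel"))
  # step 3: recurrently hit genes (distinct variants in distinct people)
  recurrent <- p |>
    dplyr::filter(entered, !shared_cross_family, !is.na(gene)) |>
    dplyr::distinct(gene, variant_key, proband_id) |>
    dplyr::group_by(gene) |>
    dplyr::summarise(
      recurrent_gene = dplyr::n_distinct(variant_key) > 1L &
        dplyr::n_distinct(proband_id) > 1L,
      .groups = "drop")
  p <- p |>
    dplyr::left_join(recurrent, by = "gene") |>
    dplyr::mutate(recurrent_gene = dplyr::coalesce(recurrent_gene, FALSE))
  # steps 4-5: soft rank components
  p <- p |>
    dplyr::mutate(
      deleterious_score = dplyr::case_when(
        damaging_basis %in% c("splice-site",
                              "protein-truncating-or-indel-or-unknown") ~ 5L,
        TRUE ~ as.integer(
          dplyr::coalesce(sift_damaging, FALSE) +
            dplyr::coalesce(polyphen_humvar_damaging, FALSE) +
            dplyr::coalesce(vest >= vest_min, FALSE) +
            dplyr::coalesce(cadd >= cadd_min, FALSE) +
            dplyr::coalesce(phylop >= phylop_min, FALSE))
      ),
      constraint_priority = dplyr::coalesce(pli > 0.5, FALSE) &
        dplyr::coalesce(loeuf < 0.5, FALSE),
      # steps 6-7: hard filters
      clinvar_benign = clinvar_is_benign(clinvar_significance),
      gnomad_hom = dplyr::coalesce(gnomad_hom_carriers, 0) >= 1
    )
  p <- p |>
    dplyr::mutate(
      dropped_step = dplyr::case_when(
        !entered ~ NA_integer_,
        shared_cross_family ~ 1L,
        clinvar_benign ~ 6L,
        gnomad_hom ~ 7L,
        TRUE ~ NA_integer_
      ),
      kept = entered & is.na(dropped_step),
      step1 = dplyr::case_when(!entered ~ "na",
                               shared_cross_family ~ "dropped",
                               TRUE ~ "kept"),
      step2 = ifelse(entered & step1 == "kept", "kept", "na"),
      step3 = step2, step4 = step2, step5 = step2,
      step6 = dplyr::case_when(
        !entered | step1 == "dropped" ~ "na",
        clinvar_benign ~ "dropped",
        TRUE ~ "kept"),
      step7 = dplyr::case_when(
        !entered | step1 == "dropped" | step6 == "dropped" ~ "na",
        gnomad_hom ~ "dropped",
        TRUE ~ "kept")
    ) |>
    dplyr::select(-n_families)
  p
}

#' Gene-length-normalized missense rate per proband
#'
#' For oversized genes the raw missense count is compared against the
#' population baseline: the rate is the number of base pairs carrying
#' missense mutations in the gene in one proband divided by the gene's coding
#' length, compared to the gnomAD missense rate per bp.
#'
#' @param variants Per-proband variant tibble with `proband_id`, `gene`, and
#'   `effect` columns (e.g. prioritized calls).
#' @param gene_metadata Gene metadata with `coding_length_bp` and
#'   `gnomad_missense_rate`.
#' @param genes Oversized genes to evaluate (default `"TTN"`).
#' @return One row per (proband, gene): `missense_bp`, `coding_length_bp`,
#'   `rate`, `reference_rate`, `exceeds` (logical).
#' @export
gene_missense_rate <- function(variants, gene_metadata, genes = "TTN") {
  meta <- gene_metadata |>
    dplyr::filter(symbol %in% genes) |>
    dplyr::select(gene = symbol, coding_length_bp, gnomad_missense_rate)
  no_len <- meta$gene[is.na(meta$coding_length_bp)]
  if (length(no_len) > 0) {
    rlang::warn(paste("missing coding length; missense-rate filter not",
                      "applied to:", paste(no_len, collapse = ", ")))
    meta <- meta |> dplyr::filter(!is.na(coding_length_bp))
  }
  variants |>
    dplyr::filter(gene %in% meta$gene, effect == "nonsynonymous-SNV") |>
    dplyr::distinct(proband_id, gene, variant_key, .keep_all = TRUE) |>
    dplyr::group_by(proband_id, gene) |>
    dplyr::summarise(missense_bp = sum(nchar(ref)), .groups = "drop") |>
    dplyr::inner_join(meta, by = "gene") |>
    dplyr::mutate(
      rate = missense_bp / coding_length_bp,
      reference_rate = gnomad_missense_rate,
      exceeds = !is.na(reference_rate) & rate > reference_rate
    )
}

#' Apply the oversized-gene missense-rate filter
#'
#' Drops a proband's prioritized variants in an oversized gene when the
#' proband's missense rate in that gene exceeds the gnomAD reference rate
#' (see [gene_missense_rate()]). Dropped rows get `dropped_step = 8` and a
#' `"gene-missense-rate"` trace entry in `step_missense`.
#'
#' @param prioritized Output of [prioritize_candidates()].
#' @param gene_metadata Gene metadata tibble.
#' @param genes Oversized genes (default `"TTN"`).
#' @return `prioritized` with updated `kept`/`dropped_step` and a
#'   `step_missense` column.
#' @export
apply_gene_missense_rate_filter <- function(prioritized, gene_metadata,
                                            genes = "TTN") {
  rates <- gene_missense_rate(dplyr::filter(prioritized, kept),
                              gene_metadata, genes)
  drops <- rates |>
    dplyr::filter(exceeds) |>
    dplyr::select(proband_id, gene)
  prioritized |>
    dplyr::left_join(dplyr::mutate(drops, mr_drop = TRUE),
                     by = c("proband_id", "gene")) |>
    dplyr::mutate(
      mr_drop = dplyr::coalesce(mr_drop, FALSE) & kept,
      step_missense = dplyr::case_when(
        !kept & !mr_drop ~ "na",
        mr_drop ~ "dropped",
        TRUE ~ "kept"),
      dropped_step = ifelse(mr_drop, 8L, dropped_step),
      kept = kept & !mr_drop
    ) |>
    dplyr::select(-mr_drop)
}

#' Rank a proband's surviving variants
#'
#' Total order per proband: known-gene variants over novel; stopgain /
#' stoploss / frameshift over nonsynonymous SNVs; de novo over inherited
#' modes; then descending AlphaMissense score (absent scores sort last);
#' then the soft ladder components (gene recurrence, deleteriousness score,
#' constraint) and finally a deterministic tie-break on the variant key.
#'
#' @param prioritized Output of [prioritize_candidates()] (or the
#'   missense-rate-filtered version); only `kept` rows are ranked.
#' @return Kept rows with a `rank` column, ordered within proband.
#' @export
rank_proband_variants <- function(prioritized) {
  truncating <- c("stopgain", "stoploss", "frameshift-insertion",
                  "frameshift-deletion")
  prioritized |>
    dplyr::filter(kept) |>
    dplyr::mutate(
      rk_tier = ifelse(tier == "known", 0L, 1L),
      rk_effect = ifelse(effect %in% truncating, 0L, 1L),
      rk_mode = ifelse(mode == "de_novo", 0L, 1L),
      rk_am = -dplyr::coalesce(alphamissense, -Inf)
    ) |>
    dplyr::group_by(proband_id) |>
    dplyr::arrange(rk_tier, rk_effect, rk_mode, rk_am,
                   !recurrent_gene, -deleterious_score,
                   !constraint_priority, variant_key,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::starts_with("rk_"))
}
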