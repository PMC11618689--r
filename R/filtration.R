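# Stage 1: genotype-level quality filtering and rare/novel/private
# frequency classification, with per-exome count summaries.

#' Apply the genotype quality filter
#'
#' A sample's genotype at a site is retained iff read depth >= `min_dp` and
#' genotype quality >= `min_gq`. Retention is per genotype, not per site.
#' Genotypes with absent DP or GQ are dropped conservatively, with the reason
#' recorded.
#'
#' @param genotypes Long genotype tibble (see [read_cohort_vcf()]).
#' @param min_dp Minimum read depth (default 10).
#' @param min_gq Minimum genotype quality, Phred (default 30).
#' @return The input with added columns `qc_pass` (logical) and `qc_reason`
#'   (`"pass"`, `"fail-dp"`, `"fail-gq"`, `"missing-dp"`, `"missing-gq"`).
#'   Count reasons with `dplyr::count(out, qc_reason)`.
#' @export
apply_quality_filter <- function(genotypes, min_dp = 10, min_gq = 30) {
  genotypes |>
    dplyr::mutate(
      qc_reason = dplyr::case_when(
        is.na(dp) ~ "missing-dp",
        is.na(gq) ~ "missing-gq",
        dp < min_dp ~ "fail-dp",
        gq < min_gq ~ "fail-gq",
        TRUE ~ "pass"
      ),
      qc_pass = qc_reason == "pass"
    )
}

#' Classify variants as rare, novel, and private
#'
#' A variant is *rare* iff every available population allele frequency
#' (overall and sub-population `af_*` columns) is strictly below `max_af`;
#' absent frequencies do not veto rarity. It is *novel* iff it is absent from
#' all frequency databases (every `af_*` entry missing, or no annotation row).
#' It is *private* iff it is novel and carried (alternate dosage >= 1 over
#' quality-retained genotypes) by exactly one individual in the cohort.
#' By construction private implies novel implies rare.
#'
#' @param genotypes Quality-annotated genotype tibble from
#'   [apply_quality_filter()].
#' @param annotation Annotation tibble ([read_annotation_table()]); variants
#'   without a row are treated as absent from all databases.
#' @param max_af Rarity cutoff on every population frequency (default 0.01).
#' @return One row per variant: key columns, `n_carriers`, `is_rare`,
#'   `is_novel`, `is_private`.
#' @export
classify_frequency <- function(genotypes, annotation = NULL, max_af = 0.01) {
  if (!"qc_pass" %in% names(genotypes)) {
    genotypes <- apply_quality_filter(genotypes)
  }
  carriers <- genotypes |>
    dplyr::group_by(chrom, pos, ref, alt) |>
    dplyr::summarise(
      n_carriers = sum(qc_pass & !is.na(gt) & gt >= 1L),
      .groups = "drop"
    ) |>
    dplyr::mutate(variant_key = variant_key(chrom, pos, ref, alt))
  af_cols <- if (is.null(annotation)) character(0) else
    grep("^af_", names(annotation), value = TRUE)
  if (is.null(annotation) || length(af_cols) == 0) {
    freq <- tibble::tibble(variant_key = character(0),
                           max_seen_af = numeric(0),
                           n_db = integer(0))
  } else {
    if (!"variant_key" %in% names(annotation)) {
      annotation <- dplyr::mutate(
        annotation, variant_key = variant_key(chrom, pos, ref, alt))
    }
    afm <- as.matrix(annotation[, af_cols, drop = FALSE])
    freq <- tibble::tibble(
      variant_key = annotation$variant_key,
      max_seen_af = apply(afm, 1L, function(v) {
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      }),
      n_db = rowSums(!is.na(afm))
    )
  }
  carriers |>
    dplyr::left_join(freq, by = "variant_key") |>
    dplyr::mutate(
      is_rare = is.na(max_seen_af) | max_seen_af < max_af,
      is_novel = is.na(n_db) | n_db == 0L,
      is_private = is_novel & n_carriers == 1L
    ) |>
    dplyr::select(chrom, pos, ref, alt, variant_key, n_carriers,
                  is_rare, is_novel, is_private)
}

#' Per-exome variant count summary across pipeline stages
#'
#' Counts per sample at each stage of the filtration ladder: raw,
#' quality-filtered, rare (split het/hom), novel, private, private coding,
#' and private damaging. SNV/indel split is by allele length (both alleles
#' length 1 = SNV). Counts are of post-split biallelic records.
#'
#' @param genotypes Quality-annotated genotype tibble.
#' @param freq_class Output of [classify_frequency()].
#' @param annotation Optional annotation tibble, used for the coding /
#'   damaging private subsets (requires `effect` plus the SIFT/PolyPhen
#'   columns).
#' @return A tibble with one row per (sample, stage): `sample_id`, `stage`,
#'   `n`, `n_snv`, `n_indel`, plus `n_het`/`n_hom` where defined. Stage order
#'   is recorded in the `stage` factor levels.
#' @export
summarize_exome_counts <- function(genotypes, freq_class, annotation = NULL) {
  stages <- c("raw", "quality", "rare", "novel", "private",
              "private_coding", "private_damaging")
  g <- genotypes |>
    dplyr::mutate(variant_key = variant_key(chrom, pos, ref, alt)) |>
    dplyr::left_join(
      dplyr::select(freq_class, variant_key, is_rare, is_novel, is_private),
      by = "variant_key"
    )
  if (!is.null(annotation)) {
    if (!"variant_key" %in% names(annotation)) {
      annotation <- dplyr::mutate(
        annotation, variant_key = variant_key(chrom, pos, ref, alt))
    }
    g <- g |>
      dplyr::left_join(
        dplyr::select(annotation, variant_key, effect,
                      dplyr::any_of(c("sift_damaging",
                                      "polyphen_humvar_damaging"))),
        by = "variant_key"
      )
  } else {
    g$effect <- NA_character_
    g$sift_damaging <- NA
    g$polyphen_humvar_damaging <- NA
  }
  g <- g |>
    dplyr::mutate(
      carried = !is.na(gt) & gt >= 1L,
      is_snv = nchar(ref) == 1L & nchar(alt) == 1L,
      coding = !is.na(effect) & effect != "other",
      damaging = coding & !is.na(effect) & effect == "nonsynonymous-SNV" &
        (dplyr::coalesce(sift_damaging, FALSE) |
           dplyr::coalesce(polyphen_humvar_damaging, FALSE))
    )
  stage_mask <- list(
    raw = g$carried,
    quality = g$carried & g$qc_pass,
    rare = g$carried & g$qc_pass & g$is_rare,
    novel = g$carried & g$qc_pass & g$is_novel,
    private = g$carried & g$qc_pass & g$is_private,
    private_coding = g$carried & g$qc_pass & g$is_private & g$coding,
    private_damaging = g$carried & g$qc_pass & g$is_private & g$damaging
  )
  out <- purrr::map_dfr(stages, function(s) {
    gm <- g[stage_mask[[s]], , drop = FALSE]
    gm |>
      dplyr::group_by(sample_id) |>
      dplyr::summarise(
        n = dplyr::n(),
        n_snv = sum(is_snv),
        n_indel = sum(!is_snv),
        n_het = sum(gt == 1L),
        n_hom = sum(gt >= 2L),
        .groups = "drop"
      ) |>
      dplyr::mutate(stage = s)
  })
  all_samples <- unique(genotypes$sample_id)
  tidyr::crossing(sample_id = all_samples,
                  stage = factor(stages, levels = stages)) |>
    dplyr::left_join(dplyr::mutate(out, stage = factor(stage, levels = stages)),
                     by = c("sample_id", "stage")) |>
    dplyr::mutate(dplyr::across(c(n, n_snv, n_indel, n_het, n_hom),
                                ~ tidyr::replace_na(.x, 0L)))
}
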