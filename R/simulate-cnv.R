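# Synthetic CNV segment tables with planted truth for every filter rule.

#' Simulate CNV segments, locus tables, and an SV frequency table
#'
#' Plants, per proband, a handful of neutral background segments (these fail
#' the significance filter) and one passing call (deletions and duplications
#' alternating), plus one decoy per filter rule when `decoys = TRUE` and the
#' pedigree has at least 10 probands: a non-significant segment, a
#' copy-neutral segment, a sub-threshold log2 segment, a copy-number /
#' direction contradiction, an identical segment in two unrelated probands,
#' a deletion fully inside a common (>1%) DEL structural variant, plus two
#' controls expected to survive (containment in a common DUP, and in a rare
#' DEL). One proband is made an outlier with `n_outlier_segments` extra
#' segments. Known-locus tables overlap two of the planted survivors.
#'
#' @param pedigree Pedigree tibble; segments are planted in probands.
#' @param seed Integer seed.
#' @param n_background_min,n_background_max Neutral segments per proband
#'   (default 3 to 6).
#' @param n_outlier_segments Extra segments for the outlier proband
#'   (default 174).
#' @param decoys Plant filter decoys (default TRUE).
#' @return List of tibbles: `segments`, `asd_loci`, `syndromic_loci`,
#'   `sv_table`, `truth` (per segment: `seg_id`, `class`,
#'   `expected_reason`, `"none"` meaning expected to survive).
#' @export
simulate_cnv_cohort <- function(pedigree, seed = 1, n_background_min = 3,
                                n_background_max = 6,
                                n_outlier_segments = 174, decoys = TRUE) {
  set.seed(seed)
  pro <- pedigree |> dplyr::filter(role == "proband")
  if (nrow(pro) < 2) rlang::abort("need at least two probands")
  decoys <- decoys && nrow(pro) >= 10
  ids <- pro$individual_id
  fams <- stats::setNames(pro$family_id, ids)
  segs <- list()
  truth <- list()
  sid <- 0L
  add <- function(sample_id, chrom, start, end, log2, cn, p, class,
                  expected_reason) {
    sid <<- sid + 1L
    segs[[sid]] <<- tibble::tibble(
      seg_id = sprintf("seg%05d", sid), sample_id = sample_id,
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      log2_ratio = log2, copy_number = as.integer(cn), p_value = p)
    truth[[sid]] <<- tibble::tibble(
      seg_id = sprintf("seg%05d", sid), sample_id = sample_id,
      family_id = unname(fams[sample_id]), class = class,
      expected_reason = expected_reason)
  }
  bg_chrom <- function(j) paste0("chr", 1 + (j - 1L) %% 22L)
  for (i in seq_along(ids)) {
    s <- ids[i]
    outlier <- decoys && i == 1L
    n_bg <- sample(n_background_min:n_background_max, 1) +
      if (outlier) n_outlier_segments else 0L
    for (j in seq_len(n_bg)) {
      start <- 10e6 + ((j - 1L) %/% 22L) * 5e6
      len <- round(stats::runif(1, 20e3, 200e3))
      add(s, bg_chrom(j), start, start + len,
          round(stats::runif(1, -0.1, 0.1), 3), 2L,
          round(stats::runif(1, 0.05, 0.95), 4),
          if (outlier) "outlier_background" else "background_neutral",
          if (outlier) "outlier-sample" else "low-significance")
    }
    if (outlier) next
    # one passing call per proband, deletions and duplications alternating
    len <- round(stats::runif(1, 86e3, 400e3))
    start <- 50e6 + ((i - 1L) %/% 22L) * 2e6
    chrom <- bg_chrom(i)
    if (i %% 2L == 0L) {
      add(s, chrom, start, start + len, -1.0, 1L, 0.01,
          "planted_deletion", "none")
    } else {
      add(s, chrom, start, start + len, 0.8, 3L, 0.01,
          "planted_duplication", "none")
    }
  }
  if (decoys) {
    dk <- function(i) ids[i]
    add(dk(2), "chr10", 70e6, 70.2e6, -1.0, 1L, 0.2,
        "decoy_low_significance", "low-significance")
    add(dk(3), "chr10", 72e6, 72.2e6, -0.1, 2L, 0.01,
        "decoy_neutral_copy", "neutral-copy")
    add(dk(4), "chr10", 74e6, 74.2e6, -0.3, 1L, 0.01,
        "decoy_sub_threshold_log2", "sub-threshold-log2")
    add(dk(5), "chr10", 76e6, 76.2e6, 0.8, 1L, 0.01,
        "decoy_inconsistent", "inconsistent-direction")
    add(dk(6), "chr22", 40e6, 40.2e6, -1.0, 1L, 0.01,
        "decoy_cross_family", "duplicate-cross-family")
    add(dk(7), "chr22", 40e6, 40.2e6, -1.0, 1L, 0.01,
        "decoy_cross_family", "duplicate-cross-family")
    add(dk(8), "chr21", 30e6, 30.1e6, -1.0, 1L, 0.01,
        "decoy_common_sv", "common-sv")
    add(dk(9), "chr20", 25e6, 25.1e6, -1.0, 1L, 0.01,
        "control_type_mismatch_sv", "none")
    add(dk(10), "chr19", 15e6, 15.1e6, -1.0, 1L, 0.01,
        "control_rare_sv", "none")
  }
  segments <- dplyr::bind_rows(segs)
  truth <- dplyr::bind_rows(truth)
  # planted segments within one sample must not overlap
  ov <- segments |>
    dplyr::group_by(sample_id, chrom) |>
    dplyr::arrange(start, .by_group = TRUE) |>
    dplyr::summarise(bad = any(start < dplyr::lag(end, default = -1L)),
                     .groups = "drop")
  if (any(ov$bad)) rlang::abort("overlapping planted segments in a sample")

  surv <- truth |>
    dplyr::filter(class %in% c("planted_deletion", "planted_duplication")) |>
    dplyr::inner_join(segments, by = c("seg_id", "sample_id"))
  mk_locus <- function(prefix, row) {
    tibble::tibble(
      locus_id = paste0(prefix, "_", row$seg_id),
      chrom = row$chrom,
      start = as.integer(row$start + 50e3),
      end = as.integer(row$start + 5e6)
    )
  }
  asd_loci <- if (nrow(surv) >= 1) mk_locus("sfari", surv[1, ]) else
    tibble::tibble(locus_id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0))
  syndromic_loci <- if (nrow(surv) >= 2) mk_locus("decipher", surv[2, ]) else
    tibble::tibble(locus_id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0))
  sv_table <- tibble::tibble(
    sv_id = c("sv_common_del", "sv_common_dup", "sv_rare_del"),
    chrom = c("chr21", "chr20", "chr19"),
    start = as.integer(c(29.9e6, 24.9e6, 14.9e6)),
    end = as.integer(c(30.3e6, 25.3e6, 15.3e6)),
    sv_type = c("DEL", "DUP", "DEL"),
    frequency = c(0.02, 0.02, 0.005)
  )
  list(segments = segments, asd_loci = asd_loci,
       syndromic_loci = syndromic_loci, sv_table = sv_table, truth = truth)
}
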