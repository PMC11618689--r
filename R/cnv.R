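# Stage 4: CNV segment post-processing — outlier-sample exclusion,
# significance/copy-number/log2 filtering, cross-family dedup, known-locus
# overlap annotation, and SV-frequency containment filtering.
# Intervals are 0-based half-open throughout (CNVkit convention).

#' Exclude samples with an outlying number of CNV segments
#'
#' Samples whose raw segment count exceeds `median + k * MAD` over all
#' samples are removed entirely. The exclusion bound is explicit and
#' configurable because such removals are otherwise ad hoc judgments.
#'
#' @param segments CNV segment tibble ([read_cnv_segments()]).
#' @param k MAD multiplier (default 3).
#' @return A list with `segments` (retained) and `excluded_samples` (tibble
#'   of `sample_id`, `n_segments`, `bound`).
#' @export
exclude_outlier_samples <- function(segments, k = 3) {
  counts <- segments |> dplyr::count(sample_id, name = "n_segments")
  bound <- stats::median(counts$n_segments) +
    k * stats::mad(counts$n_segments)
  excluded <- counts |>
    dplyr::filter(n_segments > bound) |>
    dplyr::mutate(bound = bound)
  list(
    segments = segments |>
      dplyr::filter(!sample_id %in% excluded$sample_id),
    excluded_samples = excluded
  )
}

#' Filter CNV segments and deduplicate across families
#'
#' Keeps segments with p < 0.05 and copy number in \{0, 1, 3, 4\}, calling a
#' deletion when the log2 read-depth ratio is <= -0.5 (copy number 0/1) and a
#' duplication when it is >= 0.5 (copy number 3/4); a copy-number /
#' log2-direction contradiction is dropped as inconsistent. The exact same
#' segment (chrom, start, end, direction) occurring in probands of more than
#' one family is then dropped from all carriers.
#'
#' @param segments CNV segment tibble (after outlier exclusion).
#' @param pedigree Pedigree tibble, used to map samples to families for the
#'   cross-family dedup. Samples absent from the pedigree are treated as
#'   their own family.
#' @return One row per input segment with `direction`
#'   (`"deletion"`/`"duplication"`/`NA`) and `dropped_reason` (`"none"` for
#'   kept calls, else `"low-significance"`, `"neutral-copy"`,
#'   `"sub-threshold-log2"`, `"inconsistent-direction"`,
#'   `"duplicate-cross-family"`).
#' @export
filter_cnv_segments <- function(segments, pedigree = NULL) {
  fam <- if (is.null(pedigree)) {
    tibble::tibble(sample_id = character(0), family_id = character(0))
  } else {
    dplyr::select(pedigree, sample_id = individual_id, family_id)
  }
  calls <- segments |>
    dplyr::left_join(fam, by = "sample_id") |>
    dplyr::mutate(
      family_id = dplyr::coalesce(family_id, sample_id),
      direction = dplyr::case_when(
        log2_ratio <= -0.5 & copy_number %in% c(0L, 1L) ~ "deletion",
        log2_ratio >= 0.5 & copy_number %in% c(3L, 4L) ~ "duplication",
        TRUE ~ NA_character_
      ),
      dropped_reason = dplyr::case_when(
        !(p_value < 0.05) ~ "low-significance",
        !copy_number %in% c(0L, 1L, 3L, 4L) ~ "neutral-copy",
        abs(log2_ratio) < 0.5 ~ "sub-threshold-log2",
        is.na(direction) ~ "inconsistent-direction",
        TRUE ~ "none"
      )
    )
  dup <- calls |>
    dplyr::filter(dropped_reason == "none") |>
    dplyr::distinct(chrom, start, end, direction, family_id) |>
    dplyr::count(chrom, start, end, direction, name = "n_families") |>
    dplyr::filter(n_families > 1L) |>
    dplyr::mutate(dup_cross = TRUE) |>
    dplyr::select(-n_families)
  calls |>
    dplyr::left_join(dup, by = c("chrom", "start", "end", "direction")) |>
    dplyr::mutate(
      dropped_reason = ifelse(
        dropped_reason == "none" & dplyr::coalesce(dup_cross, FALSE),
        "duplicate-cross-family", dropped_reason)
    ) |>
    dplyr::select(-dup_cross)
}

# GRanges from a half-open interval tibble (converted to 1-based closed).
cnv_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

overlap_annotation <- function(calls, loci, prefix) {
  out_ids <- rep(NA_character_, nrow(calls))
  out_bp <- rep(0L, nrow(calls))
  if (nrow(loci) > 0 && nrow(calls) > 0) {
    hits <- GenomicRanges::findOverlaps(cnv_granges(calls),
                                        cnv_granges(loci))
    if (length(hits) > 0) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- pmin(calls$end[qi], loci$end[si]) -
        pmax(calls$start[qi], loci$start[si])
      agg <- tibble::tibble(qi = qi, id = loci$locus_id[si], bp = ov) |>
        dplyr::group_by(qi) |>
        dplyr::summarise(ids = paste(id, collapse = ","),
                         bp = sum(bp), .groups = "drop")
      out_ids[agg$qi] <- agg$ids
      out_bp[agg$qi] <- agg$bp
    }
  }
  calls[[paste0(prefix, "_loci")]] <- out_ids
  calls[[paste0(prefix, "_overlap_bp")]] <- out_bp
  calls[[paste0(prefix, "_overlap_fraction")]] <-
    out_bp / (calls$end - calls$start)
  calls
}

#' Annotate CNV calls with known-locus overlaps
#'
#' Records any >= 1 bp intersection with known ASD CNV loci (SFARI-style)
#' and syndromic loci (DECIPHER-style), with overlap bp and fraction of the
#' call covered. Annotation only: overlap never drops a call and does not
#' imply causality.
#'
#' @param calls Output of [filter_cnv_segments()].
#' @param asd_loci,syndromic_loci Locus tibbles ([read_locus_table()]).
#' @return `calls` with `asd_loci`, `asd_overlap_bp`, `asd_overlap_fraction`,
#'   and the `syndromic_*` equivalents.
#' @export
annotate_known_loci <- function(calls, asd_loci, syndromic_loci) {
  calls |>
    overlap_annotation(asd_loci, "asd") |>
    overlap_annotation(syndromic_loci, "syndromic")
}

#' Drop CNV calls contained in common structural variants
#'
#' A call is dropped (reason `"common-sv"`) iff its interval is entirely
#' contained within a structural variant of matching type (DEL for
#' deletions, DUP for duplications) whose population frequency exceeds
#' `max_freq`. Type matching can be disabled.
#'
#' @param calls Output of [filter_cnv_segments()].
#' @param sv_table SV frequency tibble ([read_sv_table()]).
#' @param max_freq Frequency bound (default 0.01).
#' @param match_type Require the SV type to match the call direction
#'   (default TRUE).
#' @return `calls` with `dropped_reason` updated.
#' @export
apply_sv_frequency_filter <- function(calls, sv_table, max_freq = 0.01,
                                      match_type = TRUE) {
  common <- sv_table |> dplyr::filter(frequency > max_freq)
  if (nrow(common) == 0 || nrow(calls) == 0) return(calls)
  live <- which(calls$dropped_reason == "none")
  if (length(live) == 0) return(calls)
  hits <- GenomicRanges::findOverlaps(cnv_granges(calls[live, ]),
                                      cnv_granges(common), type = "within")
  if (length(hits) == 0) return(calls)
  qi <- live[S4Vectors::queryHits(hits)]
  si <- S4Vectors::subjectHits(hits)
  type_ok <- if (match_type) {
    (calls$direction[qi] == "deletion" & common$sv_type[si] == "DEL") |
      (calls$direction[qi] == "duplication" & common$sv_type[si] == "DUP")
  } else rep(TRUE, length(qi))
  drop_idx <- unique(qi[type_ok])
  calls$dropped_reason[drop_idx] <- "common-sv"
  calls
}

#' Full CNV post-processing pipeline
#'
#' Runs outlier-sample exclusion, the significance/copy-number/log2 filter
#' with cross-family dedup, known-locus annotation, and the common-SV
#' containment filter. Excluded samples' segments are carried in the output
#' with reason `"outlier-sample"` so that every input segment has exactly
#' one fate.
#'
#' @param segments Raw CNV segment tibble.
#' @param pedigree Pedigree tibble (for family mapping).
#' @param asd_loci,syndromic_loci Optional locus tibbles.
#' @param sv_table Optional SV frequency tibble.
#' @param outlier_k MAD multiplier for [exclude_outlier_samples()].
#' @return Tibble of CNV calls with `direction`, locus annotations, and one
#'   `dropped_reason` per segment (`"none"` = kept).
#' @export
cnv_pipeline <- function(segments, pedigree = NULL, asd_loci = NULL,
                         syndromic_loci = NULL, sv_table = NULL,
                         outlier_k = 3) {
  excl <- exclude_outlier_samples(segments, k = outlier_k)
  calls <- filter_cnv_segments(excl$segments, pedigree)
  empty_loci <- tibble::tibble(locus_id = character(0), chrom = character(0),
                               start = integer(0), end = integer(0))
  calls <- annotate_known_loci(calls,
                               asd_loci %||% empty_loci,
                               syndromic_loci %||% empty_loci)
  if (!is.null(sv_table)) {
    calls <- apply_sv_frequency_filter(calls, sv_table)
  }
  outliers <- segments |>
    dplyr::filter(sample_id %in% excl$excluded_samples$sample_id) |>
    dplyr::mutate(family_id = NA_character_, direction = NA_character_,
                  dropped_reason = "outlier-sample")
  dplyr::bind_rows(calls, outliers)
}

#' Mean size of kept CNV calls
#'
#' @param calls Output of [cnv_pipeline()] or [filter_cnv_segments()].
#' @return Mean of `end - start` (bp) over kept calls.
#' @export
mean_cnv_size <- function(calls) {
  kept <- calls |> dplyr::filter(dropped_reason == "none")
  mean(kept$end - kept$start)
}
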