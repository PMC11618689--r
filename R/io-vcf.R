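# Multi-sample VCF input/output.
#
# The pipeline's working representation of a cohort callset is a long tibble
# with one row per sample per biallelic site. Multiallelic records are split
# into per-allele rows at read time (with per-allele AD), then left-aligned
# and trimmed, because every downstream rule is per-allele.

#' Read a multi-sample VCF into a long genotype tibble
#'
#' Parses a VCF 4.x file (FORMAT fields GT, DP, GQ, AD expected but optional)
#' and returns one row per sample per biallelic variant. Multiallelic records
#' are split per ALT allele: the genotype dosage of each row counts only that
#' allele, and the AD field is split so that `ad_alt` is the depth of that
#' allele while `ad_ref` is the reference depth. Missing FORMAT fields are
#' `NA`, never zero; a missing genotype (`./.`) has `gt = NA`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param chrom_style Chromosome naming dialect, see [normalize_chrom()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `sample_id`, `gt` (alternate-allele dosage, 0/1/2 or `NA`), `ploidy`,
#'   `dp`, `gq`, `ad_ref`, `ad_alt`.
#' @export
read_cohort_vcf <- function(path, chrom_style = "chr") {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) rlang::abort(paste0("malformed VCF '", path, "': ",
                                            conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_mat <- vcf@gt
  samples <- colnames(gt_mat)[-1L]
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    fmt <- strsplit(gt_mat[i, 1L], ":", fixed = TRUE)[[1]]
    vals <- strsplit(unname(gt_mat[i, -1L]), ":", fixed = TRUE)
    field <- function(nm) {
      j <- match(nm, fmt)
      if (is.na(j)) return(rep(NA_character_, length(samples)))
      vapply(vals, function(v) if (length(v) >= j) v[j] else NA_character_,
             character(1))
    }
    gt_str <- field("GT")
    dp <- suppressWarnings(as.integer(field("DP")))
    gq <- suppressWarnings(as.integer(field("GQ")))
    ad_str <- field("AD")
    alleles <- strsplit(gt_str, "[/|]")
    ploidy <- vapply(alleles, length, integer(1))
    missing_gt <- vapply(alleles, function(a) {
      length(a) == 0L || any(a == ".") || all(is.na(a))
    }, logical(1))
    ad_parts <- strsplit(ad_str, ",", fixed = TRUE)
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    per_allele <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      norm <- trim_alleles(as.integer(fix[i, "POS"]), fix[i, "REF"], alts[k])
      dosage <- ifelse(missing_gt, NA_integer_,
                       vapply(alleles, function(a) sum(a == as.character(k)),
                              integer(1)))
      ad_ref <- vapply(ad_parts, function(p) {
        if (length(p) < 1L || is.na(p[1L]) || p[1L] == ".") NA_integer_
        else suppressWarnings(as.integer(p[1L]))
      }, integer(1))
      ad_alt <- vapply(ad_parts, function(p) {
        if (length(p) < k + 1L || is.na(p[k + 1L]) || p[k + 1L] == ".")
          NA_integer_
        else suppressWarnings(as.integer(p[k + 1L]))
      }, integer(1))
      per_allele[[k]] <- tibble::tibble(
        chrom = normalize_chrom(fix[i, "CHROM"], chrom_style),
        pos = norm$pos, ref = norm$ref, alt = norm$alt, qual = qual,
        sample_id = samples, gt = dosage, ploidy = ploidy,
        dp = dp, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt
      )
    }
    rows[[i]] <- dplyr::bind_rows(per_allele)
  }
  dplyr::bind_rows(rows)
}

#' Write a long genotype tibble as a multi-sample VCF
#'
#' Inverse of [read_cohort_vcf()] for already-split biallelic data: one VCF
#' record per (chrom, pos, ref, alt), FORMAT `GT:DP:GQ:AD`. Round-tripping a
#' tibble produced by [read_cohort_vcf()] reproduces it field for field.
#'
#' @param genotypes Long genotype tibble (see [read_cohort_vcf()]).
#' @param path Output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(genotypes, path) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual", "sample_id", "gt",
                  "dp", "gq", "ad_ref", "ad_alt") %in% names(genotypes)))
  if (!"ploidy" %in% names(genotypes)) genotypes$ploidy <- 2L
  samples <- unique(genotypes$sample_id)
  enc_gt <- function(gt, ploidy) {
    dplyr::case_when(
      is.na(gt) & ploidy == 1L ~ ".",
      is.na(gt)                ~ "./.",
      ploidy == 1L             ~ as.character(gt),
      gt == 0L                 ~ "0/0",
      gt == 1L                 ~ "0/1",
      TRUE                     ~ "1/1"
    )
  }
  fmt_int <- function(x) ifelse(is.na(x), ".", as.character(x))
  sites <- genotypes |>
    dplyr::mutate(
      cell = paste(enc_gt(gt, ploidy), fmt_int(dp), fmt_int(gq),
                   paste0(fmt_int(ad_ref), ",", fmt_int(ad_alt)), sep = ":")
    ) |>
    dplyr::select(chrom, pos, ref, alt, qual, sample_id, cell) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cell")
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  qual_str <- ifelse(is.na(sites$qual), ".",
                     sub("\\.0+$", "", format(sites$qual, trim = TRUE,
                                              scientific = FALSE)))
  body_left <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                     qual_str, ".", ".", "GT:DP:GQ:AD", sep = "\t")
  cells <- as.matrix(sites[, samples, drop = FALSE])
  body <- paste(body_left, apply(cells, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
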