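# Small in-code fixtures shared across tests.

# one genotype row with sensible defaults
geno_row <- function(sample_id, gt, chrom = "chr1", pos = 100L, ref = "A",
                     alt = "G", qual = 1500, dp = 40L, gq = 99L,
                     ad_alt = NULL, ploidy = 2L) {
  if (is.null(ad_alt)) {
    ad_alt <- if (is.na(gt)) NA_integer_ else
      c(0L, 20L, 40L)[gt + 1L]
  }
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    qual = qual, sample_id = sample_id, gt = as.integer(gt),
    ploidy = as.integer(ploidy), dp = as.integer(dp), gq = as.integer(gq),
    ad_ref = as.integer(ifelse(is.na(ad_alt), NA, dp - ad_alt)),
    ad_alt = as.integer(ad_alt)
  )
}

# a quad family pedigree: father, mother, affected proband, unaffected sib
quad_pedigree <- function(fid = "FAM1", proband_sex = "male",
                          with_father = TRUE, with_sibling = TRUE) {
  rows <- tibble::tibble(
    family_id = fid,
    individual_id = paste0(fid, c("_FA", "_MO", "_P", "_S")),
    father_id = c(NA, NA, if (with_father) paste0(fid, "_FA") else NA,
                  if (with_father) paste0(fid, "_FA") else NA),
    mother_id = c(NA, NA, paste0(fid, "_MO"), paste0(fid, "_MO")),
    sex = c("male", "female", proband_sex, "female"),
    affected = c(FALSE, FALSE, TRUE, FALSE)
  )
  keep <- rep(TRUE, 4)
  if (!with_father) keep[1] <- FALSE
  if (!with_sibling) keep[4] <- FALSE
  build_ped_from_rows(rows[keep, ])
}

# genotypes for one variant across a quad
quad_variant <- function(gt_fa, gt_mo, gt_p, gt_s = 0L, fid = "FAM1",
                         ...) {
  dplyr::bind_rows(
    if (!is.null(gt_fa)) geno_row(paste0(fid, "_FA"), gt_fa, ...),
    if (!is.null(gt_mo)) geno_row(paste0(fid, "_MO"), gt_mo, ...),
    geno_row(paste0(fid, "_P"), gt_p, ...),
    if (!is.null(gt_s)) geno_row(paste0(fid, "_S"), gt_s, ...)
  )
}

# minimal annotation row
ann_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                    gene = "GENE1", effect = "nonsynonymous-SNV",
                    af_gnomad = NA_real_, af_1000g = NA_real_,
                    sift_damaging = TRUE,
                    polyphen_humvar_damaging = FALSE,
                    clinvar_significance = NA_character_,
                    gnomad_hom_carriers = NA_real_,
                    alphamissense = NA_real_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene, effect = effect, af_gnomad = af_gnomad,
                 af_1000g = af_1000g, sift_damaging = sift_damaging,
                 polyphen_humvar_damaging = polyphen_humvar_damaging,
                 clinvar_significance = clinvar_significance,
                 gnomad_hom_carriers = gnomad_hom_carriers,
                 alphamissense = alphamissense)
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
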