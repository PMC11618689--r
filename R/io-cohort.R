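# Emit a simulated cohort in the exact formats the readers consume.

#' Write a simulated cohort to a directory
#'
#' Emits `cohort.vcf`, `cohort.ped`, `annotation.tsv`, `gene_metadata.tsv`,
#' `phenotypes.tsv`, `truth.tsv`, and a `manifest.json` run manifest listing
#' the files written. The files round-trip through [read_cohort_vcf()],
#' [read_pedigree()], and the table readers.
#'
#' @param cohort List from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    ped = file.path(dir, "cohort.ped"),
    annotation = file.path(dir, "annotation.tsv"),
    gene_metadata = file.path(dir, "gene_metadata.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_cohort_vcf(cohort$genotypes, paths[["vcf"]])
  write_pedigree(cohort$pedigree, paths[["ped"]])
  write_annotation_table(cohort$annotation, paths[["annotation"]])
  write_gene_metadata(cohort$gene_metadata, paths[["gene_metadata"]])
  write_phenotypes(cohort$phenotypes, paths[["phenotypes"]])
  write_tsv_plain(cohort$truth, paths[["truth"]])
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(files = as.list(basename(paths)),
         n_samples = length(unique(cohort$genotypes$sample_id)),
         n_sites = nrow(dplyr::distinct(cohort$genotypes,
                                        chrom, pos, ref, alt))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = manifest))
}
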