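# Shared helpers: variant keys, allele normalization, chromosome dialects.

#' Build a variant key string
#'
#' Variants are identified throughout the pipeline by the tuple
#' (chrom, pos, ref, alt), serialized as `"chrom:pos:ref:alt"`.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Normalize chromosome names to one dialect
#'
#' Either strips or adds the `"chr"` prefix so that all tables in a run share
#' one naming convention. The default keeps the `"chrX"` style used by the
#' annotation tables.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"chr"` (default) or `"plain"`.
#' @return Character vector.
#' @export
normalize_chrom <- function(chrom, style = c("chr", "plain")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", chrom)
  if (style == "chr") paste0("chr", bare) else bare
}

#' Left-align and trim a ref/alt allele pair
#'
#' Minimal normalization applied after multiallelic splitting: shared trailing
#' bases are trimmed first, then shared leading bases (advancing `pos`), always
#' leaving at least one base in each allele.
#'
#' @param pos 1-based position.
#' @param ref,alt Single allele strings.
#' @return A list with elements `pos`, `ref`, `alt`.
#' @keywords internal
trim_alleles <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim common suffix
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim common prefix, advancing pos
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]
    a <- a[-1L]
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

# Pseudoautosomal regions on GRCh38 chrX (1-based, inclusive).
# X-linked calling and planting exclude these by default.
par_regions_grch38 <- function() {
  tibble::tibble(
    region = c("PAR1", "PAR2"),
    chrom  = "chrX",
    start  = c(10001L, 155701383L),
    end    = c(2781479L, 156030895L)
  )
}

#' Is a position inside a pseudoautosomal region?
#'
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
in_par_region <- function(chrom, pos) {
  par <- par_regions_grch38()
  chrom <- normalize_chrom(chrom)
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par))) {
    out <- out | (chrom == par$chrom[i] & pos >= par$start[i] & pos <= par$end[i])
  }
  out
}

is_chrx <- function(chrom) normalize_chrom(chrom) == "chrX"

# readr wrapper with quiet column guessing
read_tsv_quiet <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  show_col_types = FALSE, na = c("NA", "", "."))
}

write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}
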