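# Readers and writers for the pipeline's tab-separated side tables:
# pedigree (PED), variant annotation, gene metadata, CNV segments,
# known-CNV locus tables, SV frequency table, and phenotypes.

#' Functional effect vocabulary
#'
#' The closed set of functional effect classes used by the annotation tables
#' and every downstream rule.
#'
#' @return Character vector of effect labels.
#' @export
effect_levels <- function() {
  c("nonsynonymous-SNV", "synonymous-SNV", "stopgain", "stoploss",
    "frameshift-insertion", "frameshift-deletion", "nonframeshift-insertion",
    "nonframeshift-deletion", "splice-site", "unknown", "other")
}

#' Read a PED-style pedigree file
#'
#' Expects the classic 6 columns (family, individual, father, mother, sex,
#' phenotype) with sex coded 1 = male / 2 = female, phenotype 2 = affected /
#' 1 = unaffected, and `0` for a missing parent. Roles are inferred: an
#' affected child is a proband, an unaffected child a sibling, parents are
#' father/mother, and the mother of a parent is a grandmother. Unaffected
#' relatives beyond the nuclear family (grandmothers) are treated as
#' unaffected controls.
#'
#' @param path Path to a whitespace- or tab-separated PED file.
#' @return A tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id` (`NA` when missing), `sex` ("male"/"female"), `affected`
#'   (logical), `role`, and `one_parent_family` (logical, TRUE when the
#'   family's proband is missing exactly one parent in the file).
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex",
                                         "phenotype"),
                           colClasses = "character")
  build_pedigree(tibble::tibble(
    family_id = raw$family_id,
    individual_id = raw$individual_id,
    father_id = dplyr::na_if(raw$father_id, "0"),
    mother_id = dplyr::na_if(raw$mother_id, "0"),
    sex = raw$sex,
    affected = raw$phenotype
  ))
}

# Shared validation + role inference for pedigrees from file or simulator.
build_pedigree <- function(ped) {
  if (!all(ped$sex %in% c("1", "2", "male", "female"))) {
    rlang::abort("pedigree contains an unknown sex code (must be 1/2)")
  }
  ped$sex <- ifelse(ped$sex %in% c("1", "male"), "male", "female")
  if (is.character(ped$affected)) {
    if (!all(ped$affected %in% c("1", "2"))) {
      rlang::abort("pedigree phenotype must be coded 2 (affected) / 1")
    }
    ped$affected <- ped$affected == "2"
  }
  # cycle check: walking parent links from any individual must terminate
  parent_of <- stats::setNames(
    purrr::map2(ped$father_id, ped$mother_id, ~ c(.x, .y)),
    ped$individual_id
  )
  for (id in ped$individual_id) {
    seen <- character(0)
    frontier <- id
    while (length(frontier) > 0) {
      if (any(frontier %in% seen)) {
        rlang::abort("cyclic parentage detected in pedigree")
      }
      seen <- c(seen, frontier)
      frontier <- unlist(parent_of[intersect(frontier,
                                             names(parent_of))],
                         use.names = FALSE)
      frontier <- frontier[!is.na(frontier)]
    }
  }
  is_child <- !is.na(ped$father_id) | !is.na(ped$mother_id)
  is_father <- ped$individual_id %in% ped$father_id
  is_mother <- ped$individual_id %in% ped$mother_id
  parents <- ped$individual_id[is_father | is_mother]
  # grandmother: a mother whose child is itself a parent in the file
  gm <- ped$individual_id[is_mother] |>
    purrr::keep(function(id) {
      kids <- ped$individual_id[!is.na(ped$mother_id) & ped$mother_id == id]
      any(kids %in% parents)
    })
  role <- dplyr::case_when(
    ped$individual_id %in% gm ~ "grandmother",
    is_father ~ "father",
    is_mother ~ "mother",
    is_child & ped$affected ~ "proband",
    is_child ~ "sibling",
    ped$affected ~ "proband",
    TRUE ~ "other"
  )
  ped$role <- role
  fam_one_parent <- ped |>
    dplyr::filter(role == "proband") |>
    dplyr::group_by(family_id) |>
    dplyr::summarise(
      one_parent_family = any(xor(is.na(father_id), is.na(mother_id))),
      .groups = "drop"
    )
  ped |>
    dplyr::left_join(fam_one_parent, by = "family_id") |>
    dplyr::mutate(one_parent_family =
                    tidyr::replace_na(one_parent_family, FALSE)) |>
    tibble::as_tibble()
}

#' Write a pedigree tibble as a 6-column PED file
#' @param pedigree Tibble from [read_pedigree()] or [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- data.frame(
    pedigree$family_id, pedigree$individual_id,
    ifelse(is.na(pedigree$father_id), "0", pedigree$father_id),
    ifelse(is.na(pedigree$mother_id), "0", pedigree$mother_id),
    ifelse(pedigree$sex == "male", "1", "2"),
    ifelse(pedigree$affected, "2", "1")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

annotation_columns <- function() {
  c("chrom", "pos", "ref", "alt", "gene", "effect",
    "af_1000g", "af_gnomad", "af_gme", "af_exac",
    "sift_damaging", "polyphen_humvar_damaging",
    "vest", "cadd", "phylop", "alphamissense",
    "clinvar_significance", "gnomad_hom_carriers")
}

#' Read a per-variant annotation table
#'
#' Tab-separated, keyed by (chrom, pos, ref, alt). Frequency columns are the
#' `af_*` family (overall plus any sub-population columns such as
#' `af_gnomad_afr`); all must lie in \[0, 1\] or be absent. Duplicate keys
#' keep the last row with a warning.
#'
#' @param path Path to a TSV with at least the key columns plus `gene` and
#'   `effect`.
#' @return A tibble with one row per variant key and a `variant_key` column.
#' @export
read_annotation_table <- function(path) {
  ann <- read_tsv_quiet(path)
  validate_annotation(tibble::as_tibble(ann))
}

validate_annotation <- function(ann) {
  # columns that are all-NA in a TSV parse as logical; restore their types
  num_cols <- c(grep("^af_", names(ann), value = TRUE),
                intersect(c("vest", "cadd", "phylop", "alphamissense",
                            "gnomad_hom_carriers"), names(ann)))
  for (col in num_cols) {
    if (is.logical(ann[[col]])) ann[[col]] <- as.numeric(ann[[col]])
  }
  if ("clinvar_significance" %in% names(ann) &&
      is.logical(ann$clinvar_significance)) {
    ann$clinvar_significance <- as.character(ann$clinvar_significance)
  }
  need <- c("chrom", "pos", "ref", "alt", "gene", "effect")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    rlang::abort(paste("annotation table lacks columns:",
                       paste(missing, collapse = ", ")))
  }
  if (any(ann$pos < 1, na.rm = TRUE)) {
    rlang::abort("annotation table has non-positive coordinates")
  }
  bad_eff <- setdiff(unique(ann$effect), c(effect_levels(), NA))
  if (length(bad_eff) > 0) {
    rlang::abort(paste("unknown effect class:", paste(bad_eff, collapse = ", ")))
  }
  af_cols <- grep("^af_", names(ann), value = TRUE)
  for (col in af_cols) {
    v <- ann[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      rlang::abort(paste0("allele frequency outside [0,1] in column ", col))
    }
  }
  ann <- ann |>
    dplyr::mutate(variant_key = variant_key(chrom, pos, ref, alt))
  if (anyDuplicated(ann$variant_key) > 0) {
    rlang::warn("duplicate variant keys in annotation table; keeping last")
    ann <- ann |>
      dplyr::group_by(variant_key) |>
      dplyr::slice_tail(n = 1) |>
      dplyr::ungroup()
  }
  ann
}

#' Write an annotation table
#' @param annotation Tibble as returned by [read_annotation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotation, path) {
  write_tsv_plain(dplyr::select(annotation, -dplyr::any_of("variant_key")),
                  path)
}

#' Read a per-gene metadata table
#'
#' Columns: `symbol`, `sfari_score` (1/2/3/S or absent), `omim_neuro`
#' (logical), `pli`, `loeuf`, `z_score`, `coding_length_bp`,
#' `gnomad_missense_rate`.
#'
#' @param path Path to a TSV.
#' @return Tibble, one row per gene symbol.
#' @export
read_gene_metadata <- function(path) {
  gm <- read_tsv_quiet(path, col_types = readr::cols(
    sfari_score = readr::col_character()))
  gm <- tibble::as_tibble(gm)
  for (col in intersect(c("pli", "loeuf", "z_score", "coding_length_bp",
                          "gnomad_missense_rate"), names(gm))) {
    if (is.logical(gm[[col]])) gm[[col]] <- as.numeric(gm[[col]])
  }
  if ("pli" %in% names(gm) && any(gm$pli < 0 | gm$pli > 1, na.rm = TRUE)) {
    rlang::abort("pLI outside [0,1] in gene metadata")
  }
  if ("coding_length_bp" %in% names(gm) &&
      any(gm$coding_length_bp <= 0, na.rm = TRUE)) {
    rlang::abort("non-positive coding length in gene metadata")
  }
  gm
}

#' Write a gene metadata table
#' @param gene_metadata Tibble as returned by [read_gene_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_metadata <- function(gene_metadata, path) {
  write_tsv_plain(gene_metadata, path)
}

#' Read a CNVkit-style segment table
#'
#' Tab-separated with columns `sample_id`, `chrom`, `start`, `end` (0-based
#' half-open, the CNVkit convention), `log2_ratio`, `copy_number`, `p_value`.
#'
#' @param path Path to a TSV.
#' @return Tibble of segments.
#' @export
read_cnv_segments <- function(path) {
  seg <- tibble::as_tibble(read_tsv_quiet(path))
  if (any(seg$start < 0 | seg$end < 0)) {
    rlang::abort("negative coordinates in CNV segment table")
  }
  if (any(seg$start >= seg$end)) {
    rlang::abort("CNV segment with start >= end")
  }
  if (any(seg$p_value < 0 | seg$p_value > 1, na.rm = TRUE)) {
    rlang::abort("CNV p-value outside [0,1]")
  }
  if (any(seg$copy_number < 0, na.rm = TRUE)) {
    rlang::abort("negative copy number in CNV segment table")
  }
  seg
}

#' Write a CNV segment table
#' @param segments Tibble as returned by [read_cnv_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_segments <- function(segments, path) {
  write_tsv_plain(segments, path)
}

#' Read a BED-like known-CNV locus table
#'
#' Columns `locus_id`, `chrom`, `start`, `end` (0-based half-open).
#'
#' @param path Path to a TSV.
#' @return Tibble of loci.
#' @export
read_locus_table <- function(path) {
  loc <- tibble::as_tibble(read_tsv_quiet(path))
  if (any(loc$start < 0)) rlang::abort("negative coordinates in locus table")
  loc
}

#' Read a structural-variant frequency table
#'
#' Columns `sv_id`, `chrom`, `start`, `end` (0-based half-open), `sv_type`
#' ("DEL"/"DUP"), `frequency` in \[0, 1\].
#'
#' @param path Path to a TSV.
#' @return Tibble of SVs.
#' @export
read_sv_table <- function(path) {
  sv <- tibble::as_tibble(read_tsv_quiet(path))
  if (any(sv$frequency < 0 | sv$frequency > 1, na.rm = TRUE)) {
    rlang::abort("SV frequency outside [0,1]")
  }
  sv
}

#' Read a per-individual phenotype table
#'
#' Long TSV with columns `individual_id`, `condition`, `status` (one of
#' "present", "absent", "unknown"); exactly one row per (individual,
#' condition).
#'
#' @param path Path to a TSV.
#' @return Tibble of phenotype records.
#' @export
read_phenotypes <- function(path) {
  ph <- tibble::as_tibble(read_tsv_quiet(path))
  bad <- setdiff(unique(ph$status), c("present", "absent", "unknown"))
  if (length(bad) > 0) {
    rlang::abort(paste("unknown phenotype status:", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(ph[, c("individual_id", "condition")]) > 0) {
    rlang::abort("duplicate (individual, condition) rows in phenotype table")
  }
  ph
}

#' Write a phenotype table
#' @param phenotypes Tibble as returned by [read_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write_tsv_plain(phenotypes, path)
}
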