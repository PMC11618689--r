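# Construction of the planted-variant table for simulate_cohort().
# One row per (variant, family); rows sharing a site_id describe the same
# cohort site (used for the deliberate cross-family duplicate decoy).

plant_defaults <- function(n) {
  tibble::tibble(
    family_id = character(n), gene = character(n),
    ref = rep("C", n), alt = rep("T", n),
    effect = rep("other", n), sift_damaging = rep(NA, n),
    af_gnomad = rep(NA_real_, n),
    clinvar_significance = rep(NA_character_, n),
    gnomad_hom_carriers = rep(NA_real_, n),
    gt_father = rep(0L, n), gt_mother = rep(0L, n),
    gt_proband = rep(0L, n), gt_sibling = rep(0L, n),
    is_x = rep(FALSE, n),
    dp_ovr = rep(NA_integer_, n), gq_ovr = rep(NA_integer_, n),
    adr_ovr = rep(NA_integer_, n), ada_ovr = rep(NA_integer_, n),
    qual_ovr = rep(NA_real_, n),
    class = character(n), expected_mode = rep(NA_character_, n),
    expected_call = rep(FALSE, n), expected_prioritized = rep(FALSE, n),
    drop_stage = rep(NA_character_, n),
    share_tag = rep(NA_character_, n)
  )
}

build_plants <- function(fam, n_de_novo, n_de_novo_coding,
                         comp_het_gene_sizes, n_inherited_hom,
                         n_inherited_hom_coding, n_x_linked,
                         n_x_linked_coding, decoys) {
  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x

  for (i in seq_len(nrow(fam))) {
    fid <- fam$family_id[i]
    male <- fam$proband_sex[i] == "male"
    gcount <- 0L
    next_gene <- function() {
      gcount <<- gcount + 1L
      sprintf("PG_%s_%03d", fid, gcount)
    }
    # de novo: heterozygous private variant in the proband only
    if (n_de_novo > 0) {
      p <- plant_defaults(n_de_novo)
      coding <- seq_len(n_de_novo) <= n_de_novo_coding
      p$family_id <- fid
      p$gene <- vapply(seq_len(n_de_novo), function(k) next_gene(),
                       character(1))
      p$gt_proband <- 1L
      p$effect <- ifelse(coding, "nonsynonymous-SNV", "other")
      p$sift_damaging <- ifelse(coding, TRUE, NA)
      p$class <- ifelse(coding, "de_novo_coding", "de_novo_noncoding")
      p$expected_mode <- "de_novo"
      p$expected_call <- TRUE
      p$expected_prioritized <- coding
      p$drop_stage <- ifelse(coding, NA_character_, "not-damaging")
      add(p)
    }
    # compound het: trans pairs, one origin per parent, both parents needed
    if (fam$father_present[i] && length(comp_het_gene_sizes) > 0) {
      for (k in comp_het_gene_sizes) {
        if (k == 0) next
        g <- next_gene()
        p <- plant_defaults(2L * k)
        p$family_id <- fid
        p$gene <- g
        p$gt_proband <- 1L
        p$gt_father <- rep(c(1L, 0L), each = k)
        p$gt_mother <- rep(c(0L, 1L), each = k)
        p$effect <- "nonsynonymous-SNV"
        p$sift_damaging <- TRUE
        p$af_gnomad <- 0.002
        p$class <- "comp_het"
        p$expected_mode <- "compound_het"
        p$expected_call <- TRUE
        p$expected_prioritized <- TRUE
        add(p)
      }
    }
    # inherited homozygous: both parents het, proband hom, sibling not hom
    if (n_inherited_hom > 0) {
      p <- plant_defaults(n_inherited_hom)
      coding <- seq_len(n_inherited_hom) <= n_inherited_hom_coding
      p$family_id <- fid
      p$gene <- vapply(seq_len(n_inherited_hom), function(k) next_gene(),
                       character(1))
      p$gt_father <- 1L
      p$gt_mother <- 1L
      p$gt_proband <- 2L
      p$af_gnomad <- 0.002
      p$effect <- ifelse(coding, "nonsynonymous-SNV", "other")
      p$sift_damaging <- ifelse(coding, TRUE, NA)
      p$class <- ifelse(coding, "inherited_hom_coding",
                        "inherited_hom_noncoding")
      p$expected_mode <- "inherited_hom"
      p$expected_call <- TRUE
      p$expected_prioritized <- coding
      p$drop_stage <- ifelse(coding, NA_character_, "not-damaging")
      add(p)
    }
    # X-linked: male proband hemizygous, mother het, outside the PARs
    if (male && n_x_linked > 0) {
      p <- plant_defaults(n_x_linked)
      coding <- seq_len(n_x_linked) <= n_x_linked_coding
      p$family_id <- fid
      p$gene <- vapply(seq_len(n_x_linked), function(k) next_gene(),
                       character(1))
      p$gt_mother <- 1L
      p$gt_proband <- 2L
      p$is_x <- TRUE
      p$af_gnomad <- 0.002
      p$effect <- ifelse(coding, "nonsynonymous-SNV", "other")
      p$sift_damaging <- ifelse(coding, TRUE, NA)
      p$class <- ifelse(coding, "x_linked_coding", "x_linked_noncoding")
      p$expected_mode <- "x_linked"
      p$expected_call <- TRUE
      p$expected_prioritized <- coding
      p$drop_stage <- ifelse(coding, NA_character_, "not-damaging")
      add(p)
    }
    if (decoys && i <= 4) {
      add(build_family_decoys(fid, i, next_gene))
    }
  }
  out <- dplyr::bind_rows(rows)
  out$site_id <- ifelse(is.na(out$share_tag),
                        paste0("s", seq_len(nrow(out))), out$share_tag)
  out
}

# One decoy per filter rule, hosted in the first four families (all quads
# with both parents; families 1-2 male probands, family 3 female).
build_family_decoys <- function(fid, i, next_gene) {
  mk <- function(class, ..., n = 1L) {
    p <- plant_defaults(n)
    p$family_id <- fid
    p$class <- class
    dots <- list(...)
    for (nm in names(dots)) p[[nm]] <- dots[[nm]]
    p
  }
  rows <- list()
  if (i == 1L) {
    g <- next_gene()
    rows <- list(
      # both members inherited from the mother: cis, no trans pair
      mk("decoy_comp_het_cis", n = 2L, gene = g, gt_mother = 1L,
         gt_proband = 1L, effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         af_gnomad = 0.002, drop_stage = "segregation"),
      mk("decoy_hom_parent_hom", gene = next_gene(), gt_father = 1L,
         gt_mother = 2L, gt_proband = 2L, effect = "nonsynonymous-SNV",
         sift_damaging = TRUE, af_gnomad = 0.002,
         drop_stage = "segregation"),
      mk("decoy_hom_sibling_hom", gene = next_gene(), gt_father = 1L,
         gt_mother = 1L, gt_proband = 2L, gt_sibling = 2L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         af_gnomad = 0.002, drop_stage = "segregation"),
      mk("decoy_x_mother_hom", gene = next_gene(), gt_mother = 2L,
         gt_proband = 2L, is_x = TRUE, effect = "nonsynonymous-SNV",
         sift_damaging = TRUE, af_gnomad = 0.002,
         drop_stage = "segregation"),
      mk("decoy_cross_family", gene = "XFAMGENE", gt_father = 1L,
         gt_mother = 1L, gt_proband = 2L, effect = "nonsynonymous-SNV",
         sift_damaging = TRUE, af_gnomad = 0.002,
         expected_mode = "inherited_hom", expected_call = TRUE,
         drop_stage = "step1", share_tag = "xfam1")
    )
  } else if (i == 2L) {
    rows <- list(
      mk("decoy_cross_family", gene = "XFAMGENE", gt_father = 1L,
         gt_mother = 1L, gt_proband = 2L, effect = "nonsynonymous-SNV",
         sift_damaging = TRUE, af_gnomad = 0.002,
         expected_mode = "inherited_hom", expected_call = TRUE,
         drop_stage = "step1", share_tag = "xfam1"),
      # allele balance 10/50 = 0.2 with AD-Alt and AD-Ref both passing
      mk("decoy_dn_allele_balance", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         dp_ovr = 50L, adr_ovr = 40L, ada_ovr = 10L,
         drop_stage = "segregation"),
      mk("decoy_dn_low_gq", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE, gq_ovr = 50L,
         drop_stage = "segregation"),
      mk("decoy_dn_low_qual", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         qual_ovr = 500, drop_stage = "segregation"),
      mk("decoy_dn_long_allele", gene = next_gene(), gt_proband = 1L,
         ref = "C", alt = paste0("C", strrep("AG", 30)),
         effect = "nonframeshift-insertion", drop_stage = "segregation"),
      mk("decoy_dn_parent_carrier", gene = next_gene(), gt_father = 1L,
         gt_proband = 1L, effect = "nonsynonymous-SNV",
         sift_damaging = TRUE, drop_stage = "frequency"),
      mk("decoy_quality", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE, dp_ovr = 5L,
         drop_stage = "quality"),
      mk("decoy_common", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         af_gnomad = 0.02, drop_stage = "frequency"),
      mk("decoy_clinvar_benign", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         clinvar_significance = "Benign", expected_mode = "de_novo",
         expected_call = TRUE, drop_stage = "step6"),
      mk("decoy_gnomad_hom", gene = next_gene(), gt_proband = 1L,
         effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         gnomad_hom_carriers = 2, expected_mode = "de_novo",
         expected_call = TRUE, drop_stage = "step7"),
      mk("decoy_synonymous_dn", gene = next_gene(), gt_proband = 1L,
         effect = "synonymous-SNV", expected_mode = "de_novo",
         expected_call = TRUE, drop_stage = "not-damaging")
    )
  } else if (i == 3L) {
    rows <- list(
      mk("decoy_x_female", gene = next_gene(), gt_mother = 1L,
         gt_proband = 2L, is_x = TRUE, effect = "nonsynonymous-SNV",
         sift_damaging = TRUE, af_gnomad = 0.002,
         drop_stage = "segregation")
    )
  } else if (i == 4L) {
    rows <- list(
      # two TTN missense calls push the proband's per-bp missense rate
      # (2 / 108000) above the gnomAD reference rate
      mk("decoy_ttn", n = 2L, gene = "TTN", gt_father = 1L, gt_mother = 1L,
         gt_proband = 2L, effect = "nonsynonymous-SNV", sift_damaging = TRUE,
         af_gnomad = 0.002, expected_mode = "inherited_hom",
         expected_call = TRUE, drop_stage = "missense_rate")
    )
  }
  dplyr::bind_rows(rows)
}
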