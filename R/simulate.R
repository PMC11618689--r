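# Synthetic cohort generator with planted, labeled truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# nuclear families (trio/quad, optionally missing the father), a shared set
# of Mendelian-consistent background sites, and per-proband planted variants
# for every inheritance class plus one decoy per filter rule. Every planted
# record carries its expected fate through the pipeline in the truth table.
# Default planting rates follow the cohort's observed per-proband averages
# (4 de novo of which 2 coding; 10 compound-het variants across 3 genes;
# 16 X-linked of which 8 coding, in male probands); the inherited-homozygous
# default is 12 (3 coding), a desk-scale choice discussed in the vignette.

#' Simulate a family exome cohort with planted truth
#'
#' Generates genotypes, pedigree, annotation, gene metadata, and phenotypes
#' for `n_families` nuclear families, plus a truth table recording every
#' planted variant's intended inheritance class or decoy fate. Non-planted
#' (background) genotypes are Mendelian-consistent by construction. With
#' `noise = FALSE` (default) per-genotype DP/GQ/AD are deterministic values
#' that satisfy every quality criterion, so planted fates are exact; with
#' `noise = TRUE` they are drawn from a depth/allele-balance/GQ noise model.
#'
#' @param n_families Number of families (default 50).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param n_de_novo De novo variants planted per proband (default 4).
#' @param n_de_novo_coding How many of those are coding damaging (default 2).
#' @param comp_het_gene_sizes Integer vector: for each compound-het gene,
#'   the number of paternal-origin (= maternal-origin) variants planted
#'   (default `c(2, 2, 1)`, i.e. 10 variants in 3 genes).
#' @param n_inherited_hom Inherited homozygous variants per proband
#'   (default 12).
#' @param n_inherited_hom_coding Coding damaging subset (default 3).
#' @param n_x_linked X-linked variants per male proband (default 16).
#' @param n_x_linked_coding Coding damaging subset (default 8).
#' @param n_background Shared background sites (default 120).
#' @param frac_background_rare,frac_background_novel Fractions of background
#'   sites that are database-rare / database-absent (defaults 0.3, 0.1).
#' @param p_male_proband Probability a proband is male (default 162/222).
#' @param p_missing_father Probability the father is not genotyped
#'   (default 30/195).
#' @param p_sibling Probability of one unaffected sibling (default 174/195).
#' @param noise Draw DP/GQ/AD from the noise model (default FALSE).
#' @param depth_mean,gq_mean Noise model parameters (defaults 46, 85).
#' @param decoys Plant one decoy per filter rule (default TRUE).
#' @param x_encoding `"diploid"` (male chrX variants written as homozygous
#'   diploid calls, the default) or `"haploid"`.
#' @return A list of tibbles: `genotypes`, `pedigree`, `annotation`,
#'   `gene_metadata`, `phenotypes`, `truth`.
#' @export
simulate_cohort <- function(n_families = 50, seed = 1,
                            n_de_novo = 4, n_de_novo_coding = 2,
                            comp_het_gene_sizes = c(2, 2, 1),
                            n_inherited_hom = 12, n_inherited_hom_coding = 3,
                            n_x_linked = 16, n_x_linked_coding = 8,
                            n_background = 120,
                            frac_background_rare = 0.3,
                            frac_background_novel = 0.1,
                            p_male_proband = 162 / 222,
                            p_missing_father = 30 / 195,
                            p_sibling = 174 / 195,
                            noise = FALSE, depth_mean = 46, gq_mean = 85,
                            decoys = TRUE,
                            x_encoding = c("diploid", "haploid")) {
  x_encoding <- match.arg(x_encoding)
  counts <- c(n_de_novo, n_de_novo_coding, comp_het_gene_sizes,
              n_inherited_hom, n_inherited_hom_coding, n_x_linked,
              n_x_linked_coding, n_background)
  if (any(counts < 0)) rlang::abort("planting rates must be >= 0")
  if (n_de_novo_coding > n_de_novo ||
      n_inherited_hom_coding > n_inherited_hom ||
      n_x_linked_coding > n_x_linked) {
    rlang::abort("coding subset cannot exceed the planted count")
  }
  probs <- c(frac_background_rare, frac_background_novel, p_male_proband,
             p_missing_father, p_sibling)
  if (any(probs < 0 | probs > 1) ||
      frac_background_rare + frac_background_novel > 1) {
    rlang::abort("probabilities must lie in [0,1]")
  }
  if (n_families < 1) rlang::abort("need at least one family")
  set.seed(seed)

  # ---- families and samples -------------------------------------------
  fam <- tibble::tibble(
    idx = seq_len(n_families),
    family_id = sprintf("F%03d", seq_len(n_families)),
    proband_sex = ifelse(stats::runif(n_families) < p_male_proband,
                         "male", "female"),
    father_present = stats::runif(n_families) >= p_missing_father,
    has_sibling = stats::runif(n_families) < p_sibling,
    sibling_sex = ifelse(stats::runif(n_families) < 82 / 174,
                         "male", "female")
  )
  if (decoys) {
    # decoy hosts need fixed structure: quads with both parents, male
    # probands in families 1-2, a female proband in family 3
    force_n <- min(4L, n_families)
    fam$father_present[seq_len(force_n)] <- TRUE
    fam$has_sibling[seq_len(min(2L, n_families))] <- TRUE
    fam$proband_sex[seq_len(min(2L, n_families))] <- "male"
    if (n_families >= 3) fam$proband_sex[3] <- "female"
  }
  members <- tidyr::expand_grid(fam, member = c("F", "M", "P", "S")) |>
    dplyr::mutate(
      sample_id = paste0(family_id, "_", member),
      sex = dplyr::case_when(
        member == "F" ~ "male",
        member == "M" ~ "female",
        member == "P" ~ proband_sex,
        TRUE ~ sibling_sex
      ),
      affected = member == "P",
      genotyped = dplyr::case_when(
        member == "F" ~ father_present,
        member == "S" ~ has_sibling,
        TRUE ~ TRUE
      )
    )
  sample_ids <- members$sample_id   # includes internal (ungenotyped) members
  col_of <- stats::setNames(seq_along(sample_ids), sample_ids)

  pedigree <- members |>
    dplyr::filter(genotyped) |>
    dplyr::mutate(
      father_id = ifelse(member %in% c("P", "S") & father_present,
                         paste0(family_id, "_F"), NA_character_),
      mother_id = ifelse(member %in% c("P", "S"),
                         paste0(family_id, "_M"), NA_character_),
      paternal_age = ifelse(member %in% c("P", "S"),
                            round(stats::rnorm(dplyr::n(), 31.5, 5), 1), NA),
      maternal_age = ifelse(member %in% c("P", "S"),
                            round(stats::rnorm(dplyr::n(), 29, 5), 1), NA)
    ) |>
    dplyr::transmute(family_id, individual_id = sample_id, father_id,
                     mother_id, sex, affected, paternal_age, maternal_age) |>
    build_pedigree_sim()

  # ---- background sites (autosomal, Mendelian) ------------------------
  bg_class <- sample(c("common", "rare", "novel"), n_background,
                     replace = TRUE,
                     prob = c(1 - frac_background_rare - frac_background_novel,
                              frac_background_rare, frac_background_novel))
  bg_af <- dplyr::case_when(
    bg_class == "common" ~ stats::runif(n_background, 0.02, 0.3),
    bg_class == "rare" ~ stats::runif(n_background, 1e-4, 0.009),
    TRUE ~ stats::runif(n_background, 0.001, 0.01)
  )
  bg_sites <- tibble::tibble(
    site_id = paste0("bg", seq_len(n_background)),
    chrom = paste0("chr", 1 + (seq_len(n_background) - 1L) %% 22L),
    pos = 1000000L + seq_len(n_background) * 100L,
    ref = "A", alt = "G", qual = 1500,
    gene = sprintf("BGENE%04d", seq_len(n_background)),
    effect = "other",
    af_gnomad = ifelse(bg_class == "novel", NA_real_, bg_af),
    af_1000g = ifelse(bg_class == "novel", NA_real_,
                      pmin(1, bg_af * stats::runif(n_background, 0.5, 1.5))),
    af_gme = NA_real_, af_exac = NA_real_,
    sift_damaging = NA, polyphen_humvar_damaging = NA,
    vest = NA_real_, cadd = NA_real_, phylop = NA_real_,
    alphamissense = NA_real_,
    clinvar_significance = NA_character_, gnomad_hom_carriers = NA_real_
  )
  # founder genotypes, then Mendelian transmission to both children
  nb <- n_background
  nf <- n_families
  af_mat <- matrix(bg_af, nb, nf)
  gt_f <- matrix(stats::rbinom(nb * nf, 2L, af_mat), nb, nf)
  gt_m <- matrix(stats::rbinom(nb * nf, 2L, af_mat), nb, nf)
  # an ungenotyped father must not be the sole source of an allele seen
  # once in his child: zero his background genotypes before transmission
  gt_f[, !fam$father_present] <- 0L
  transmit <- function(parent) {
    matrix(stats::rbinom(nb * nf, 1L, parent / 2), nb, nf)
  }
  gt_p <- transmit(gt_f) + transmit(gt_m)
  gt_s <- transmit(gt_f) + transmit(gt_m)
  bg_dosage <- matrix(0L, nb, length(sample_ids))
  for (j in seq_len(nf)) {
    base <- (j - 1L) * 4L
    bg_dosage[, base + 1L] <- gt_f[, j]
    bg_dosage[, base + 2L] <- gt_m[, j]
    bg_dosage[, base + 3L] <- gt_p[, j]
    bg_dosage[, base + 4L] <- gt_s[, j]
  }

  # ---- planted variants ----------------------------------------------
  plants <- build_plants(fam, n_de_novo, n_de_novo_coding,
                         comp_het_gene_sizes, n_inherited_hom,
                         n_inherited_hom_coding, n_x_linked,
                         n_x_linked_coding, decoys && n_families >= 4)
  # assign coordinates: autosomes round-robin, chrX outside the PARs;
  # rows sharing a site_id (cross-family plant) share coordinates
  usites <- plants |>
    dplyr::distinct(site_id, .keep_all = TRUE) |>
    dplyr::mutate(
      aidx = cumsum(!is_x), xidx = cumsum(is_x),
      chrom = ifelse(is_x, "chrX", paste0("chr", 1 + (aidx - 1L) %% 22L)),
      pos = ifelse(is_x, 3000000L + xidx * 100L, 5000000L + aidx * 100L)
    ) |>
    dplyr::select(site_id, chrom, pos)
  plants <- dplyr::left_join(plants, usites, by = "site_id")

  plant_sites <- plants |>
    dplyr::distinct(site_id, .keep_all = TRUE) |>
    dplyr::mutate(
      qual = dplyr::coalesce(qual_ovr, 1500),
      af_1000g = NA_real_, af_gme = NA_real_, af_exac = NA_real_,
      polyphen_humvar_damaging = ifelse(is.na(sift_damaging), NA, FALSE),
      vest = ifelse(effect == "nonsynonymous-SNV",
                    round(stats::runif(dplyr::n(), 0.5, 1), 3), NA_real_),
      cadd = ifelse(effect == "nonsynonymous-SNV",
                    round(stats::runif(dplyr::n(), 20, 40), 1), NA_real_),
      phylop = ifelse(effect == "nonsynonymous-SNV",
                      round(stats::runif(dplyr::n(), 2, 9), 2), NA_real_),
      alphamissense = ifelse(effect == "nonsynonymous-SNV",
                             round(stats::runif(dplyr::n(), 0.1, 1), 3),
                             NA_real_)
    ) |>
    dplyr::select(site_id, chrom, pos, ref, alt, qual, gene, effect,
                  af_gnomad, af_1000g, af_gme, af_exac, sift_damaging,
                  polyphen_humvar_damaging, vest, cadd, phylop,
                  alphamissense, clinvar_significance, gnomad_hom_carriers)
  np <- nrow(plant_sites)
  plant_dosage <- matrix(0L, np, length(sample_ids))
  site_row <- stats::setNames(seq_len(np), plant_sites$site_id)
  for (i in seq_len(nrow(plants))) {
    r <- site_row[[plants$site_id[i]]]
    fid <- plants$family_id[i]
    plant_dosage[r, col_of[[paste0(fid, "_F")]]] <- plants$gt_father[i]
    plant_dosage[r, col_of[[paste0(fid, "_M")]]] <- plants$gt_mother[i]
    plant_dosage[r, col_of[[paste0(fid, "_P")]]] <- plants$gt_proband[i]
    plant_dosage[r, col_of[[paste0(fid, "_S")]]] <- plants$gt_sibling[i]
  }

  # ---- assemble long genotype table -----------------------------------
  sites <- dplyr::bind_rows(
    dplyr::select(bg_sites, -site_id) |>
      dplyr::mutate(site_id = bg_sites$site_id, .before = 1),
    plant_sites
  )
  dosage <- rbind(bg_dosage, plant_dosage)
  genotyped_ids <- members$sample_id[members$genotyped]
  keep_cols <- match(genotyped_ids, sample_ids)
  dosage <- dosage[, keep_cols, drop = FALSE]
  ns <- nrow(sites)
  nsam <- length(genotyped_ids)
  geno <- tibble::tibble(
    chrom = rep(sites$chrom, each = nsam),
    pos = rep(sites$pos, each = nsam),
    ref = rep(sites$ref, each = nsam),
    alt = rep(sites$alt, each = nsam),
    qual = rep(sites$qual, each = nsam),
    sample_id = rep(genotyped_ids, ns),
    gt = as.integer(t(dosage)),
    ploidy = 2L
  )
  if (noise) {
    n <- nrow(geno)
    geno$dp <- stats::rpois(n, depth_mean)
    ab <- dplyr::case_when(geno$gt == 1L ~ stats::rbeta(n, 20, 20),
                           geno$gt >= 2L ~ 0.98, TRUE ~ 0.01)
    geno$ad_alt <- stats::rbinom(n, geno$dp, ab)
    geno$ad_ref <- geno$dp - geno$ad_alt
    geno$gq <- pmax(0L, pmin(99L, as.integer(
      round(stats::rnorm(n, gq_mean, 15)))))
  } else {
    geno <- geno |>
      dplyr::mutate(
        dp = 40L,
        ad_alt = dplyr::case_when(gt == 1L ~ 20L, gt >= 2L ~ 40L,
                                  TRUE ~ 0L),
        ad_ref = dp - ad_alt,
        gq = 99L
      )
  }
  # proband-genotype overrides for quality decoys
  ovr <- plants |>
    dplyr::filter(!is.na(dp_ovr) | !is.na(gq_ovr) | !is.na(ada_ovr)) |>
    dplyr::transmute(chrom, pos, sample_id = paste0(family_id, "_P"),
                     dp_ovr, gq_ovr, adr_ovr, ada_ovr)
  if (nrow(ovr) > 0) {
    geno <- geno |>
      dplyr::left_join(ovr, by = c("chrom", "pos", "sample_id")) |>
      dplyr::mutate(
        dp = ifelse(!is.na(dp_ovr), dp_ovr, dp),
        gq = ifelse(!is.na(gq_ovr), gq_ovr, gq),
        ad_ref = ifelse(!is.na(adr_ovr), adr_ovr, ad_ref),
        ad_alt = ifelse(!is.na(ada_ovr), ada_ovr, ad_alt)
      ) |>
      dplyr::select(-dp_ovr, -gq_ovr, -adr_ovr, -ada_ovr)
  }
  if (x_encoding == "haploid") {
    male_ids <- members$sample_id[members$sex == "male"]
    on_x <- geno$chrom == "chrX" & geno$sample_id %in% male_ids
    geno$ploidy[on_x] <- 1L
    geno$gt[on_x] <- ifelse(geno$gt[on_x] >= 1L, 1L, 0L)
  }
  geno <- dplyr::select(geno, chrom, pos, ref, alt, qual, sample_id, gt,
                        ploidy, dp, gq, ad_ref, ad_alt)

  # ---- annotation & gene metadata -------------------------------------
  annotation <- sites |>
    dplyr::select(-site_id, -qual) |>
    dplyr::mutate(variant_key = variant_key(chrom, pos, ref, alt))
  genes <- unique(annotation$gene)
  gene_metadata <- tibble::tibble(
    symbol = genes,
    sfari_score = sample(c(NA, "1", "2", "3", "S"), length(genes),
                         replace = TRUE,
                         prob = c(0.9, 0.025, 0.025, 0.025, 0.025)),
    omim_neuro = stats::runif(length(genes)) < 0.05,
    pli = round(stats::runif(length(genes)), 4),
    loeuf = round(stats::runif(length(genes), 0, 1.5), 3),
    z_score = round(stats::rnorm(length(genes), 2, 2), 3),
    coding_length_bp = sample(1000:10000, length(genes), replace = TRUE),
    gnomad_missense_rate = NA_real_
  )
  if ("TTN" %in% genes) {
    gene_metadata <- gene_metadata |>
      dplyr::mutate(
        sfari_score = ifelse(symbol == "TTN", "2", sfari_score),
        omim_neuro = ifelse(symbol == "TTN", FALSE, omim_neuro),
        coding_length_bp = ifelse(symbol == "TTN", 108000L,
                                  coding_length_bp),
        gnomad_missense_rate = ifelse(symbol == "TTN", 1.23e-5,
                                      gnomad_missense_rate)
      )
  }

  phenotypes <- simulate_phenotypes(
    pedigree$individual_id[pedigree$role == "proband"])

  truth <- plants |>
    dplyr::transmute(
      variant_key = variant_key(chrom, pos, ref, alt),
      chrom, pos, ref, alt, proband_id = paste0(family_id, "_P"),
      family_id, class, expected_mode, expected_call, expected_prioritized,
      drop_stage
    )
  list(genotypes = geno, pedigree = pedigree, annotation = annotation,
       gene_metadata = gene_metadata, phenotypes = phenotypes, truth = truth)
}

# pedigree construction for simulated members (already well-formed)
build_pedigree_sim <- function(ped) {
  extra <- ped[, c("individual_id", "paternal_age", "maternal_age")]
  out <- build_pedigree(dplyr::select(ped, -paternal_age, -maternal_age))
  dplyr::left_join(out, extra, by = "individual_id")
}

# Phenotype states for probands at the cohort's reported testing and
# prevalence rates, with "unknown" mass for untested individuals.
simulate_phenotypes <- function(proband_ids) {
  spec <- tibble::tibble(
    condition = c("asd", "language_impairment", "developmental_delay",
                  "learning_disability", "behavioral_problems", "adhd",
                  "intellectual_disability", "seizures", "ocd"),
    p_tested = c(1, 145, 137, 122, 117, 111, 109, 102, 96) /
      c(1, rep(222, 8)),
    prevalence = c(1, 0.9172, 0.8321, 0.7131, 0.6581, 0.4955, 0.4954,
                   0.2745, 0.25)
  )
  tidyr::crossing(individual_id = proband_ids, spec) |>
    dplyr::mutate(
      tested = stats::runif(dplyr::n()) < p_tested,
      has_it = stats::runif(dplyr::n()) < prevalence,
      status = dplyr::case_when(
        !tested ~ "unknown",
        has_it ~ "present",
        TRUE ~ "absent"
      )
    ) |>
    dplyr::select(individual_id, condition, status)
}
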