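# Inheritance-mode calling: worked examples per caller, invariants, and
# equivalence with the brute-force evaluator on small random cohorts.

test_that("a textbook de novo call passes all six criteria", {
  ped <- quad_pedigree()
  g <- quad_variant(0L, 0L, 1L, 0L, qual = 1000)
  g$dp[g$sample_id == "FAM1_P"] <- 27L
  g$ad_ref[g$sample_id == "FAM1_P"] <- 15L
  g$ad_alt[g$sample_id == "FAM1_P"] <- 12L
  fc <- classify_frequency(apply_quality_filter(g), NULL)
  dn <- call_de_novo(g, ped, fc)
  expect_equal(nrow(dn), 1)
  expect_true(dn$called)
  expect_false(dn$one_parent_only)
  # 12/27 = 0.444 sits inside the allele-balance window
  expect_equal(dn$crit_allele_balance, "pass")
})

test_that("a parental carrier suppresses the de novo call", {
  ped <- quad_pedigree()
  g <- quad_variant(1L, 0L, 1L, 0L)
  fc <- classify_frequency(apply_quality_filter(g), NULL)
  dn <- call_de_novo(g, ped, fc)
  # two carriers: the variant is not private, so it is not even a candidate
  expect_equal(nrow(dn), 0)
})

test_that("allele balance outside [0.3, 0.7] fails criterion 4 with evidence", {
  ped <- quad_pedigree()
  g <- quad_variant(0L, 0L, 1L, 0L)
  idx <- g$sample_id == "FAM1_P"
  g$dp[idx] <- 50L
  g$ad_ref[idx] <- 40L
  g$ad_alt[idx] <- 10L   # ratio 10/50 = 0.2 < 0.3
  fc <- classify_frequency(apply_quality_filter(g), NULL)
  dn <- call_de_novo(g, ped, fc)
  expect_equal(nrow(dn), 1)
  expect_false(dn$called)
  expect_equal(dn$crit_allele_balance, "fail")
  expect_equal(dn$crit_gq, "pass")
})

test_that("an unknown relative genotype makes de novo not-evaluable", {
  ped <- quad_pedigree()
  g <- quad_variant(0L, NA, 1L, 0L)
  fc <- classify_frequency(apply_quality_filter(g), NULL)
  dn <- call_de_novo(g, ped, fc)
  expect_false(dn$called)
  expect_equal(dn$crit_absent_relatives, "not-evaluable")
})

test_that("one-parent families call de novo with the flag set", {
  ped <- quad_pedigree(with_father = FALSE)
  g <- quad_variant(NULL, 0L, 1L, 0L, qual = 1000)
  fc <- classify_frequency(apply_quality_filter(g), NULL)
  dn <- call_de_novo(g, ped, fc)
  expect_true(dn$called)
  expect_true(dn$one_parent_only)
})

test_that("compound het pairs multiply paternal by maternal candidates", {
  ped <- quad_pedigree()
  ann <- dplyr::bind_rows(lapply(1:5, function(p) {
    ann_row(pos = p, gene = "GENE1", af_gnomad = 0.002)
  }))
  # 3 paternal-origin and 2 maternal-origin qualifying variants
  g <- dplyr::bind_rows(
    quad_variant(1L, 0L, 1L, 0L, pos = 1L),
    quad_variant(1L, 0L, 1L, 0L, pos = 2L),
    quad_variant(1L, 0L, 1L, 0L, pos = 3L),
    quad_variant(0L, 1L, 1L, 0L, pos = 4L),
    quad_variant(0L, 1L, 1L, 0L, pos = 5L)
  )
  fc <- classify_frequency(apply_quality_filter(g), ann)
  ch <- call_compound_het(g, ped, fc, ann)
  expect_equal(nrow(ch), 3 * 2)
  expect_true(all(ch$gene == "GENE1"))
})

test_that("cis configuration and missing parents yield no pairs", {
  ped <- quad_pedigree()
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, gene = "GENE1", af_gnomad = 0.002),
    ann_row(pos = 2L, gene = "GENE1", af_gnomad = 0.002)
  )
  g <- dplyr::bind_rows(
    quad_variant(0L, 1L, 1L, 0L, pos = 1L),
    quad_variant(0L, 1L, 1L, 0L, pos = 2L)   # both maternal: cis
  )
  fc <- classify_frequency(apply_quality_filter(g), ann)
  expect_equal(nrow(call_compound_het(g, ped, fc, ann)), 0)
  # with a missing father the mode is not possible at all
  ped1 <- quad_pedigree(with_father = FALSE)
  g1 <- dplyr::bind_rows(
    quad_variant(NULL, 1L, 1L, 0L, pos = 1L),
    quad_variant(NULL, 0L, 1L, 0L, pos = 2L)
  )
  fc1 <- classify_frequency(apply_quality_filter(g1), ann)
  expect_equal(nrow(call_compound_het(g1, ped1, fc1, ann)), 0)
})

test_that("inherited homozygous requires het parents, no hom relatives", {
  ped <- quad_pedigree()
  ann <- ann_row(af_gnomad = 0.002)
  run <- function(fa, mo, p, s) {
    g <- quad_variant(fa, mo, p, s)
    fc <- classify_frequency(apply_quality_filter(g), ann)
    call_inherited_homozygous(g, ped, fc)
  }
  expect_equal(nrow(run(1L, 1L, 2L, 1L)), 1)   # textbook call
  expect_equal(nrow(run(1L, 2L, 2L, 0L)), 0)   # mother homozygous
  expect_equal(nrow(run(1L, 1L, 2L, 2L)), 0)   # unaffected sib homozygous
  # one parent missing: available parent must be het, flag set
  ped1 <- quad_pedigree(with_father = FALSE)
  g1 <- quad_variant(NULL, 1L, 2L, 0L)
  fc1 <- classify_frequency(apply_quality_filter(g1), ann)
  ih <- call_inherited_homozygous(g1, ped1, fc1)
  expect_equal(nrow(ih), 1)
  expect_true(ih$one_parent_only)
})

test_that("X-linked calls need a male hemizygous proband and a het mother", {
  ann <- ann_row(chrom = "chrX", pos = 3000000L, af_gnomad = 0.002)
  run <- function(proband_sex, gt_mo, gt_p, ...) {
    ped <- quad_pedigree(proband_sex = proband_sex)
    g <- quad_variant(0L, gt_mo, gt_p, 0L, chrom = "chrX", pos = 3000000L)
    fc <- classify_frequency(apply_quality_filter(g), ann)
    call_x_linked(g, ped, fc, ...)
  }
  expect_equal(nrow(run("male", 1L, 2L)), 1)        # textbook call
  expect_equal(nrow(run("female", 1L, 2L)), 0)      # female proband
  expect_equal(nrow(run("male", 2L, 2L)), 0)        # mother homozygous
  # the female-carrier escape hatch is explicit opt-in
  expect_equal(nrow(run("female", 1L, 2L, allow_female_probands = TRUE)), 1)
})

test_that("haploid male X encoding is accepted as hemizygous", {
  ped <- quad_pedigree()
  ann <- ann_row(chrom = "chrX", pos = 3000000L, af_gnomad = 0.002)
  g <- dplyr::bind_rows(
    geno_row("FAM1_FA", 0L, chrom = "chrX", pos = 3000000L, ploidy = 1L,
             ad_alt = 0L),
    geno_row("FAM1_MO", 1L, chrom = "chrX", pos = 3000000L),
    geno_row("FAM1_P", 1L, chrom = "chrX", pos = 3000000L, ploidy = 1L,
             ad_alt = 40L),
    geno_row("FAM1_S", 0L, chrom = "chrX", pos = 3000000L)
  )
  fc <- classify_frequency(apply_quality_filter(g), ann)
  expect_equal(nrow(call_x_linked(g, ped, fc)), 1)
})

test_that("pseudoautosomal positions are excluded from X-linked calling", {
  ped <- quad_pedigree()
  ann <- ann_row(chrom = "chrX", pos = 1000000L, af_gnomad = 0.002)  # PAR1
  g <- quad_variant(0L, 1L, 2L, 0L, chrom = "chrX", pos = 1000000L)
  fc <- classify_frequency(apply_quality_filter(g), ann)
  expect_equal(nrow(call_x_linked(g, ped, fc)), 0)
  expect_equal(nrow(call_x_linked(g, ped, fc, exclude_par = FALSE)), 1)
})

test_that("segregate_all assigns disjoint modes per variant", {
  sim <- simulate_cohort(n_families = 10, seed = 31)
  g <- apply_quality_filter(sim$genotypes)
  fc <- classify_frequency(g, sim$annotation)
  calls <- segregate_all(g, sim$pedigree, fc, sim$annotation)
  dup_modes <- calls |>
    dplyr::distinct(proband_id, variant_key, mode) |>
    dplyr::count(proband_id, variant_key) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup_modes), 0)
})

test_that("no false de novo calls arise on Mendelian-consistent noise-free data", {
  sim <- simulate_cohort(n_families = 15, seed = 32)
  g <- apply_quality_filter(sim$genotypes)
  fc <- classify_frequency(g, sim$annotation)
  dn <- call_de_novo(g, sim$pedigree, fc) |> dplyr::filter(called)
  planted <- sim$truth |>
    dplyr::filter(expected_call, expected_mode == "de_novo")
  expect_setequal(paste(dn$proband_id, dn$variant_key),
                  paste(planted$proband_id, planted$variant_key))
})

test_that("compound-het counts equal the paternal x maternal product per gene", {
  sim <- simulate_cohort(n_families = 8, seed = 33)
  g <- apply_quality_filter(sim$genotypes)
  fc <- classify_frequency(g, sim$annotation)
  ch <- call_compound_het(g, sim$pedigree, fc, sim$annotation)
  # brute-force: recount qualifying variants per origin per (proband, gene)
  oracle <- oracle_segregate(g, sim$pedigree, sim$annotation) |>
    dplyr::filter(mode == "compound_het")
  expect_equal(nrow(ch), nrow(oracle))
})

test_that("the rule engine matches the brute-force evaluator on small cohorts", {
  for (seed in 101:140) {
    rc <- random_cohort(seed)
    g <- apply_quality_filter(rc$genotypes)
    fc <- classify_frequency(g, rc$annotation)
    engine <- segregate_all(g, rc$pedigree, fc, rc$annotation)
    oracle <- oracle_segregate(g, rc$pedigree, rc$annotation)
    for (m in c("de_novo", "inherited_hom", "x_linked")) {
      e <- engine |> dplyr::filter(mode == m)
      o <- oracle |> dplyr::filter(mode == m)
      expect_setequal(paste(e$proband_id, e$variant_key),
                      paste(o$proband_id, o$variant_key))
    }
    e_pairs <- engine |>
      dplyr::filter(mode == "compound_het", !is.na(partner_variant_key)) |>
      dplyr::mutate(pr = pmin(variant_key, partner_variant_key),
                    ps = pmax(variant_key, partner_variant_key)) |>
      dplyr::distinct(proband_id, pr, ps)
    o_pairs <- oracle |>
      dplyr::filter(mode == "compound_het") |>
      dplyr::mutate(pr = pmin(variant_key, partner_variant_key),
                    ps = pmax(variant_key, partner_variant_key)) |>
      dplyr::distinct(proband_id, pr, ps)
    expect_setequal(paste(e_pairs$proband_id, e_pairs$pr, e_pairs$ps),
                    paste(o_pairs$proband_id, o_pairs$pr, o_pairs$ps))
  }
})

test_that("one-parent families run three modes and skip compound het", {
  sim <- simulate_cohort(n_families = 12, seed = 34, p_missing_father = 1,
                         decoys = FALSE)
  g <- apply_quality_filter(sim$genotypes)
  fc <- classify_frequency(g, sim$annotation)
  calls <- segregate_all(g, sim$pedigree, fc, sim$annotation)
  expect_equal(sum(calls$mode == "compound_het"), 0)
  expect_true(all(calls$one_parent_only))
  expect_true(all(c("de_novo", "inherited_hom", "x_linked") %in% calls$mode))
})
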