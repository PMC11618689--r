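# Burden comparison, prevalence, demographics, parental-age analyses, and
# Fisher/BH enrichment.

test_that("burden categories follow the stated definitions and partition", {
  g <- dplyr::bind_rows(lapply(1:6, function(p) {
    dplyr::bind_rows(geno_row("S1", 1L, pos = p), geno_row("S2", 0L, pos = p))
  }))
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, effect = "synonymous-SNV"),
    ann_row(pos = 2L, effect = "nonframeshift-deletion"),
    ann_row(pos = 3L, effect = "frameshift-insertion"),
    ann_row(pos = 4L, effect = "splice-site"),
    ann_row(pos = 5L, effect = "nonsynonymous-SNV", sift_damaging = TRUE),
    ann_row(pos = 6L, effect = "other")
  )
  ann$af_gnomad <- 0.001
  gq <- apply_quality_filter(g)
  fc <- classify_frequency(gq, ann)
  counts <- count_burden_categories(gq, fc, ann)
  s1 <- counts |> dplyr::filter(sample_id == "S1") |>
    tidyr::pivot_wider(names_from = category, values_from = n)
  expect_equal(s1$total_coding, 5L)        # everything but "other"
  expect_equal(s1$nondisrupting, 2L)       # synonymous + nonframeshift
  expect_equal(s1$lof, 2L)                 # frameshift + splice site
  expect_equal(s1$missense_damaging, 1L)
  # nondisrupting and LoF are disjoint; missense-damaging within coding
  expect_equal(s1$nondisrupting + s1$lof + s1$missense_damaging,
               5L - 1L + 1L)  # categories cover coding minus none here
})

test_that("identical group count multisets give permutation p of 1", {
  counts <- tibble::tibble(
    sample_id = paste0("S", 1:6),
    category = "total_coding",
    n = c(3L, 5L, 7L, 3L, 5L, 7L)
  )
  aff <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                         paste0("S", 1:6))
  set.seed(1)
  b <- burden_test(counts, aff, n_perm = 500)
  expect_equal(b$p_permutation, 1)
  expect_equal(b$mean_affected, b$mean_unaffected)
})

test_that("extreme separation attains the minimal permutation p", {
  counts <- tibble::tibble(
    sample_id = paste0("S", 1:6), category = "lof",
    n = c(0L, 0L, 0L, 10L, 10L, 10L)
  )
  aff <- stats::setNames(rep(c(TRUE, FALSE), each = 3), paste0("S", 1:6))
  # exhaustive enumeration: 20 assignments of 3 labels among 6 samples,
  # only the observed one and its mirror reach |diff| = 10, so p = 0.1
  combos <- utils::combn(6, 3)
  diffs <- apply(combos, 2, function(idx) {
    mean(counts$n[idx]) - mean(counts$n[-idx])
  })
  exact_p <- mean(abs(diffs) >= 10)
  expect_equal(exact_p, 2 / 20)
  set.seed(2)
  b <- burden_test(counts, aff, n_perm = 4000)
  expect_lt(abs(b$p_permutation - exact_p), 0.02)
})

test_that("burden errors on an empty group or unknown sample", {
  counts <- tibble::tibble(sample_id = c("S1", "S2"),
                           category = "lof", n = c(1L, 2L))
  expect_error(burden_test(counts, c(S1 = TRUE, S2 = TRUE)), "non-empty")
  expect_error(burden_test(counts, c(S1 = TRUE)), "affected flag")
})

test_that("tidy and glance methods expose the burden result", {
  counts <- tidyr::crossing(sample_id = paste0("S", 1:6),
                            category = c("lof", "total_coding")) |>
    dplyr::mutate(n = c(1L, 9L, 2L, 8L, 1L, 11L, 2L, 10L, 1L, 9L, 3L, 8L))
  aff <- stats::setNames(rep(c(TRUE, FALSE), 3), paste0("S", 1:6))
  set.seed(3)
  b <- burden_test(counts, aff, n_perm = 100)
  td <- tidy(b)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  gl <- glance(b)
  expect_equal(gl$n_affected, 3)
  expect_equal(gl$n_categories, 2)
  expect_s3_class(autoplot(b), "ggplot")
})

test_that("phenotype prevalence reproduces printed percentages", {
  mk <- function(cond, tested, with) {
    tibble::tibble(
      individual_id = paste0("P", seq_len(tested + 5)),
      condition = cond,
      status = c(rep("present", with), rep("absent", tested - with),
                 rep("unknown", 5))
    )
  }
  ph <- dplyr::bind_rows(
    mk("language_impairment", 145, 133),
    mk("seizures", 102, 28),
    mk("never_seen", 100, 0)
  )
  prev <- phenotype_prevalence(ph) |> dplyr::arrange(condition)
  expect_equal(prev$percent[prev$condition == "language_impairment"], 91.72)
  expect_equal(prev$percent[prev$condition == "seizures"], 27.45)
  expect_equal(prev$percent[prev$condition == "never_seen"], 0)
  expect_equal(prev$n_tested[prev$condition == "language_impairment"], 145L)
  # untested condition is flagged undefined
  ph0 <- tibble::tibble(individual_id = "P1", condition = "x",
                        status = "unknown")
  p0 <- phenotype_prevalence(ph0)
  expect_true(p0$undefined)
  expect_true(is.na(p0$percent))
})

test_that("demographics summarize roles and the proband sex ratio", {
  ped <- dplyr::bind_rows(
    quad_pedigree("FAM1", proband_sex = "male"),
    quad_pedigree("FAM2", proband_sex = "male"),
    quad_pedigree("FAM3", proband_sex = "female")
  )
  d <- cohort_demographics(ped)
  expect_equal(d$n_probands, 3)
  expect_equal(d$n_fathers, 3)
  expect_equal(d$n_unaffected, 9)
  expect_equal(d$male_female_ratio, 2.0)
  # equal sexes give ratio 1.0
  ped2 <- dplyr::bind_rows(
    quad_pedigree("FAMA", proband_sex = "male"),
    quad_pedigree("FAMB", proband_sex = "female")
  )
  expect_equal(cohort_demographics(ped2)$male_female_ratio, 1.0)
})

test_that("parental-age comparison and correlations behave at the edges", {
  off <- tibble::tibble(
    individual_id = paste0("O", 1:8),
    affected = rep(c(TRUE, FALSE), each = 4),
    paternal_age = c(30, 32, 34, 36, 30, 32, 34, 36),
    maternal_age = c(28, 29, 30, 31, 28, 29, 30, 31),
    de_novo_count = c(1, 2, 3, 4, NA, NA, NA, NA)
  )
  res <- parental_age_analyses(off)
  cmp <- res |> dplyr::filter(analysis == "paternal_age_affected_vs_unaffected")
  expect_equal(cmp$p_value, 1)   # identical age vectors
  cor_p <- res |> dplyr::filter(analysis == "de_novo_vs_paternal_age")
  expect_equal(cor_p$estimate, 1)  # counts strictly increase with age
  # rank-arithmetic oracle on six hand-made pairs
  toy <- tibble::tibble(
    individual_id = paste0("T", 1:6), affected = TRUE,
    paternal_age = c(25, 31, 28, 40, 35, 22),
    maternal_age = NA_real_,
    de_novo_count = c(2, 5, 1, 6, 3, 2)
  )
  rx <- rank(toy$paternal_age)
  ry <- rank(toy$de_novo_count)
  rho_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- parental_age_analyses(toy) |>
    dplyr::filter(analysis == "de_novo_vs_paternal_age")
  expect_equal(got$estimate, rho_oracle, tolerance = 1e-10)
  # fewer than 3 pairs: no correlation
  tiny <- toy[1:2, ]
  tiny_res <- parental_age_analyses(tiny) |>
    dplyr::filter(analysis == "de_novo_vs_paternal_age")
  expect_true(is.na(tiny_res$estimate))
})

test_that("enrichment q equals p for a single set and finds a planted set", {
  bg <- paste0("G", 1:40)
  sets <- tibble::tibble(set_id = "only", gene = paste0("G", 1:5))
  res <- sea_enrichment(paste0("G", 1:5), sets, bg)
  expect_equal(res$q_value, res$p_value)
  # candidate set identical to the gene set: p is the extreme tail
  expect_equal(res$p_value,
               oracle_fisher_greater(5, 0, 0, 35), tolerance = 1e-12)
  expect_true(res$significant)
})

test_that("candidates outside the background are dropped with a warning", {
  bg <- paste0("G", 1:10)
  sets <- tibble::tibble(set_id = "s", gene = c("G1", "G2"))
  expect_warning(res <- sea_enrichment(c("G1", "ZZZ"), sets, bg), "ZZZ")
  expect_equal(res$in_set_candidate, 1L)
  expect_equal(res$out_set_candidate, 0L)
})

test_that("Fisher p equals the hypergeometric tail sum across margins", {
  # exhaustive over small margins
  for (m in 1:6) for (k in 1:6) for (a in 0:min(m, k)) {
    n_bg <- 12
    b <- k - a
    c <- m - a
    d <- n_bg - m - b
    if (c < 0 || d < 0) next
    p_impl <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                 alternative = "greater")$p.value
    expect_equal(p_impl, oracle_fisher_greater(a, b, c, d),
                 tolerance = 1e-10)
  }
  # random tables with margins up to 30
  set.seed(11)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    p_impl <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                 alternative = "greater")$p.value
    expect_equal(p_impl, oracle_fisher_greater(a, b, c, d),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up reference on random vectors", {
  set.seed(12)
  for (i in 1:50) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), oracle_bh(p),
                 tolerance = 1e-12)
  }
  # q is never below p and respects the BH ordering
  p <- stats::runif(30)
  q <- oracle_bh(p)
  expect_true(all(q >= p - 1e-12))
})

test_that("uniformly drawn candidates rarely reach q < 0.05", {
  set.seed(13)
  bg <- paste0("G", 1:200)
  sets <- purrr::map_dfr(1:8, function(s) {
    tibble::tibble(set_id = paste0("set", s),
                   gene = sample(bg, 30))
  })
  fp <- vapply(1:40, function(i) {
    cand <- sample(bg, 25)
    res <- suppressWarnings(sea_enrichment(cand, sets, bg))
    any(res$significant)
  }, logical(1))
  expect_lte(mean(fp), 0.10)
})

test_that("sea results support tidy, glance, and autoplot", {
  bg <- paste0("G", 1:30)
  sets <- tibble::tibble(set_id = rep(c("a", "b"), each = 5),
                         gene = paste0("G", c(1:5, 6:10)))
  res <- sea_enrichment(paste0("G", 1:5), sets, bg)
  expect_equal(nrow(tidy(res)), 2)
  expect_equal(glance(res)$n_sets, 2)
  expect_s3_class(autoplot(res), "ggplot")
})
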