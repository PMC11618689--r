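# Damaging classification, gene tiering, the seven-step ladder, the
# oversized-gene missense-rate filter, and within-proband ranking.

mk_call <- function(proband, family, key, mode = "de_novo") {
  parts <- strsplit(key, ":")[[1]]
  tibble::tibble(
    proband_id = proband, family_id = family, mode = mode,
    chrom = parts[1], pos = as.integer(parts[2]), ref = parts[3],
    alt = parts[4], variant_key = key, pair_id = NA_character_,
    partner_variant_key = NA_character_, one_parent_only = FALSE
  )
}

gm_row <- function(symbol, sfari = NA_character_, omim = FALSE, pli = NA,
                   loeuf = NA, len = NA, mis_rate = NA) {
  tibble::tibble(symbol = symbol, sfari_score = sfari, omim_neuro = omim,
                 pli = pli, loeuf = loeuf, z_score = NA_real_,
                 coding_length_bp = len, gnomad_missense_rate = mis_rate)
}

test_that("damaging classification covers the three bases", {
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, effect = "stopgain", sift_damaging = NA),
    ann_row(pos = 2L, effect = "nonsynonymous-SNV", sift_damaging = FALSE,
            polyphen_humvar_damaging = TRUE),
    ann_row(pos = 3L, effect = "synonymous-SNV", sift_damaging = NA),
    ann_row(pos = 4L, effect = "splice-site", sift_damaging = NA),
    ann_row(pos = 5L, effect = "nonsynonymous-SNV", sift_damaging = FALSE,
            polyphen_humvar_damaging = FALSE),
    ann_row(pos = 6L, effect = "nonsynonymous-SNV", sift_damaging = NA,
            polyphen_humvar_damaging = NA)
  )
  d <- classify_damaging(ann) |> dplyr::arrange(pos)
  expect_equal(d$is_possibly_damaging, c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                         FALSE))
  expect_equal(d$damaging_basis[1], "protein-truncating-or-indel-or-unknown")
  expect_equal(d$damaging_basis[2], "missense-predicted")
  expect_equal(d$damaging_basis[4], "splice-site")
})

test_that("gene tiering follows SFARI 1/2/S or OMIM-neurological", {
  gm <- dplyr::bind_rows(
    gm_row("A", sfari = "1"),
    gm_row("B", sfari = "3"),
    gm_row("C", omim = TRUE),
    gm_row("D", sfari = "S"),
    gm_row("E")
  )
  t <- tier_gene(gm)
  expect_equal(t$tier, c("known", "novel", "known", "known", "novel"))
})

test_that("hard ladder steps drop cross-family duplicates, benign, hom carriers", {
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, gene = "G1"),
    ann_row(pos = 2L, gene = "G2", clinvar_significance = "Benign"),
    ann_row(pos = 3L, gene = "G3",
            clinvar_significance = "Benign/Likely_benign"),
    ann_row(pos = 4L, gene = "G4", gnomad_hom_carriers = 2),
    ann_row(pos = 5L, gene = "G5",
            clinvar_significance = "Conflicting; Benign"),
    ann_row(pos = 6L, gene = "G6")
  )
  calls <- dplyr::bind_rows(
    mk_call("P1", "F1", "chr1:1:A:G"),   # same variant, two families
    mk_call("P2", "F2", "chr1:1:A:G"),
    mk_call("P1", "F1", "chr1:2:A:G"),   # benign
    mk_call("P1", "F1", "chr1:3:A:G"),   # composite benign-only
    mk_call("P1", "F1", "chr1:4:A:G"),   # gnomAD hom carrier
    mk_call("P1", "F1", "chr1:5:A:G"),   # mixed label: not benign-only
    mk_call("P3", "F1", "chr1:6:A:G"),   # within-family duplicate allowed
    mk_call("P1", "F1", "chr1:6:A:G")
  )
  gm <- gm_row("G1")
  p <- prioritize_candidates(calls, ann, gm)
  by_key <- function(k) p |> dplyr::filter(variant_key == k)
  expect_true(all(by_key("chr1:1:A:G")$dropped_step == 1))
  expect_equal(by_key("chr1:2:A:G")$dropped_step, 6)
  expect_equal(by_key("chr1:3:A:G")$dropped_step, 6)
  expect_equal(by_key("chr1:4:A:G")$dropped_step, 7)
  expect_true(by_key("chr1:5:A:G")$kept)
  expect_true(all(by_key("chr1:6:A:G")$kept))   # same family: retained
})

test_that("steps 3-5 rank but never drop; conservation holds", {
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, gene = "HIGHPLI"),
    ann_row(pos = 2L, gene = "LOWPLI")
  )
  calls <- dplyr::bind_rows(
    mk_call("P1", "F1", "chr1:1:A:G"),
    mk_call("P1", "F1", "chr1:2:A:G")
  )
  gm <- dplyr::bind_rows(
    gm_row("HIGHPLI", pli = 0.99, loeuf = 0.1),
    gm_row("LOWPLI", pli = 0.01, loeuf = 1.2)
  )
  p <- prioritize_candidates(calls, ann, gm)
  expect_true(all(p$kept))  # constraint is a priority, not a filter
  expect_equal(p$constraint_priority[p$gene == "HIGHPLI"], TRUE)
  expect_equal(p$constraint_priority[p$gene == "LOWPLI"], FALSE)
  ranked <- rank_proband_variants(p |> dplyr::mutate(
    mode = "de_novo", effect = "nonsynonymous-SNV"))
  expect_equal(ranked$gene[1], "HIGHPLI")
  # conservation: inputs = kept + dropped + not-entered
  expect_equal(nrow(p), sum(p$kept) + sum(!is.na(p$dropped_step)) +
                 sum(!p$entered))
})

test_that("oversized-gene missense rates reproduce the published arithmetic", {
  gm <- gm_row("TTN", sfari = "2", len = 108000L, mis_rate = 1.23e-5)
  # the five printed per-proband rates correspond to 17/27/30/36/40
  # missense bp over the 108 kb coding sequence
  bp <- c(17L, 27L, 30L, 36L, 40L)
  vars <- purrr::map_dfr(seq_along(bp), function(i) {
    tibble::tibble(
      proband_id = paste0("P", i), gene = "TTN",
      effect = "nonsynonymous-SNV", ref = strrep("A", 1),
      variant_key = paste0("chr2:", seq_len(bp[i]) + i * 1000, ":A:G"))
  })
  rates <- gene_missense_rate(vars, gm)
  expect_equal(round(rates$rate, 6),
               round(c(1.574074e-4, 2.5e-4, 2.777778e-4, 3.333333e-4,
                       3.703704e-4), 6))
  expect_equal(signif(rates$rate, 3),
               c(1.57e-4, 2.50e-4, 2.78e-4, 3.33e-4, 3.70e-4))
  expect_true(all(rates$exceeds))   # every proband exceeds 1.23e-5
  # zero missense bp gives rate zero and is kept
  none <- gene_missense_rate(
    tibble::tibble(proband_id = "P9", gene = "OTHER",
                   effect = "synonymous-SNV", ref = "A",
                   variant_key = "chr1:1:A:G"),
    gm)
  expect_equal(nrow(none), 0)
  # two missense over 108 kb: 1.85e-5 exceeds the 1.23e-5 reference
  two <- gene_missense_rate(
    tibble::tibble(proband_id = "P9", gene = "TTN",
                   effect = "nonsynonymous-SNV", ref = c("A", "A"),
                   variant_key = c("chr2:1:A:G", "chr2:2:A:G")),
    gm)
  expect_equal(two$rate, 2 / 108000)
  expect_true(two$exceeds)
})

test_that("the missense-rate filter drops a proband's oversized-gene variants", {
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, gene = "TTN"),
    ann_row(pos = 2L, gene = "TTN"),
    ann_row(pos = 3L, gene = "OTHER")
  )
  calls <- dplyr::bind_rows(
    mk_call("P1", "F1", "chr1:1:A:G", mode = "inherited_hom"),
    mk_call("P1", "F1", "chr1:2:A:G", mode = "inherited_hom"),
    mk_call("P1", "F1", "chr1:3:A:G")
  )
  gm <- dplyr::bind_rows(
    gm_row("TTN", sfari = "2", len = 108000L, mis_rate = 1.23e-5),
    gm_row("OTHER")
  )
  p <- prioritize_candidates(calls, ann, gm) |>
    apply_gene_missense_rate_filter(gm)
  expect_equal(sum(p$kept), 1)
  expect_equal(p$gene[p$kept], "OTHER")
  expect_true(all(p$dropped_step[p$gene == "TTN"] == 8))
})

test_that("ranking follows tier, effect severity, mode, then AlphaMissense", {
  ann <- dplyr::bind_rows(
    ann_row(pos = 1L, gene = "KNOWN", alphamissense = 0.2),
    ann_row(pos = 2L, gene = "NOVEL", alphamissense = 0.99),
    ann_row(pos = 3L, gene = "NOVEL2", effect = "stopgain",
            sift_damaging = NA),
    ann_row(pos = 4L, gene = "NOVEL3", alphamissense = 0.9),
    ann_row(pos = 5L, gene = "NOVEL4", alphamissense = 0.4)
  )
  calls <- dplyr::bind_rows(
    mk_call("P1", "F1", "chr1:1:A:G", mode = "x_linked"),
    mk_call("P1", "F1", "chr1:2:A:G", mode = "de_novo"),
    mk_call("P1", "F1", "chr1:3:A:G", mode = "inherited_hom"),
    mk_call("P1", "F1", "chr1:4:A:G", mode = "inherited_hom"),
    mk_call("P1", "F1", "chr1:5:A:G", mode = "inherited_hom")
  )
  gm <- dplyr::bind_rows(
    gm_row("KNOWN", sfari = "1"), gm_row("NOVEL"), gm_row("NOVEL2"),
    gm_row("NOVEL3"), gm_row("NOVEL4")
  )
  ranked <- prioritize_candidates(calls, ann, gm) |> rank_proband_variants()
  expect_equal(ranked$gene, c("KNOWN",    # known beats all novel
                              "NOVEL2",   # truncating beats missense
                              "NOVEL",    # de novo beats inherited
                              "NOVEL3",   # higher AlphaMissense first
                              "NOVEL4"))
  expect_equal(ranked$rank, 1:5)
})

test_that("ranking is a deterministic total order", {
  set.seed(77)
  ann <- purrr::map_dfr(1:20, function(i) {
    ann_row(pos = i, gene = paste0("G", i),
            effect = sample(c("nonsynonymous-SNV", "stopgain"), 1),
            alphamissense = sample(c(NA, runif(1)), 1))
  })
  calls <- purrr::map_dfr(1:20, function(i) {
    mk_call("P1", "F1", paste0("chr1:", i, ":A:G"),
            mode = sample(c("de_novo", "inherited_hom"), 1))
  })
  gm <- purrr::map_dfr(1:20, function(i) {
    gm_row(paste0("G", i), sfari = sample(c(NA, "1"), 1))
  })
  p <- prioritize_candidates(calls, ann, gm)
  r1 <- rank_proband_variants(p)
  r2 <- rank_proband_variants(p[sample(nrow(p)), ])
  expect_equal(r1$variant_key, r2$variant_key)   # order invariant to input
  expect_equal(r1$rank, seq_len(nrow(r1)))       # a strict total order
})

test_that("the ladder matches a straight-line reference on random cohorts", {
  for (seed in 201:220) {
    set.seed(seed)
    n <- sample(20:50, 1)
    ann <- purrr::map_dfr(seq_len(n), function(i) {
      ann_row(pos = i,
              gene = sample(c(paste0("G", 1:8), "TTN"), 1),
              effect = sample(c("nonsynonymous-SNV", "synonymous-SNV",
                                "stopgain", "splice-site"), 1),
              sift_damaging = sample(c(TRUE, FALSE, NA), 1),
              polyphen_humvar_damaging = sample(c(TRUE, FALSE, NA), 1),
              clinvar_significance = sample(
                c(NA, "Benign", "Likely_benign", "Pathogenic",
                  "Benign/Likely benign"), 1),
              gnomad_hom_carriers = sample(c(NA, 0, 1, 3), 1))
    })
    calls <- purrr::map_dfr(seq_len(n), function(i) {
      mk_call(sample(paste0("P", 1:6), 1),
              sample(paste0("F", 1:3), 1),
              paste0("chr1:", sample(seq_len(n), 1), ":A:G"),
              mode = sample(c("de_novo", "inherited_hom", "x_linked"), 1))
    })
    calls$family_id <- sub("P([12])", "F1",
                           sub("P([34])", "F2",
                               sub("P([56])", "F3", calls$proband_id)))
    gm <- dplyr::bind_rows(
      purrr::map_dfr(1:8, function(i) gm_row(paste0("G", i))),
      gm_row("TTN", sfari = "2", len = 108000L, mis_rate = 1.23e-5)
    )
    p <- prioritize_candidates(calls, ann, gm) |>
      apply_gene_missense_rate_filter(gm)
    engine_kept <- p |>
      dplyr::filter(kept) |>
      dplyr::mutate(k = paste(proband_id, variant_key)) |>
      dplyr::pull(k) |>
      unique()
    oracle_kept <- oracle_prioritize(calls, ann, gm)
    expect_setequal(engine_kept, oracle_kept)
  }
})
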