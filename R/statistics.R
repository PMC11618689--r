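# Stage 5: burden comparison, phenotype prevalence, demographics,
# parental-age analyses, and Fisher/BH specific-expression enrichment.

#' Per-sample rare-variant burden category counts
#'
#' Counts each sample's quality-retained rare carried variants in four
#' categories: `total_coding` (any exonic or splice-site effect),
#' `nondisrupting` (exonic synonymous SNVs or nonframeshift indels), `lof`
#' (frameshift indel, stopgain/stoploss, or splice site), and
#' `missense_damaging` (nonsynonymous SNVs predicted damaging by at least
#' one of SIFT and PolyPhen-2 HumVar). Categories are evaluated
#' independently; nondisrupting and LoF are disjoint by construction.
#'
#' @param genotypes Quality-annotated genotype tibble.
#' @param freq_class Output of [classify_frequency()].
#' @param annotation Annotation tibble.
#' @return Tibble with `sample_id`, `category`, `n`.
#' @export
count_burden_categories <- function(genotypes, freq_class, annotation) {
  if (!"qc_pass" %in% names(genotypes)) {
    genotypes <- apply_quality_filter(genotypes)
  }
  if (!"variant_key" %in% names(annotation)) {
    annotation <- dplyr::mutate(
      annotation, variant_key = variant_key(chrom, pos, ref, alt))
  }
  lof_eff <- c("frameshift-insertion", "frameshift-deletion", "stopgain",
               "stoploss", "splice-site")
  nondis_eff <- c("synonymous-SNV", "nonframeshift-insertion",
                  "nonframeshift-deletion")
  g <- genotypes |>
    dplyr::mutate(variant_key = variant_key(chrom, pos, ref, alt)) |>
    dplyr::filter(qc_pass, !is.na(gt), gt >= 1L) |>
    dplyr::inner_join(
      dplyr::select(freq_class, variant_key, is_rare), by = "variant_key") |>
    dplyr::filter(is_rare) |>
    dplyr::left_join(
      dplyr::select(annotation, variant_key, effect,
                    dplyr::any_of(c("sift_damaging",
                                    "polyphen_humvar_damaging"))),
      by = "variant_key") |>
    dplyr::mutate(
      total_coding = !is.na(effect) & effect != "other",
      nondisrupting = !is.na(effect) & effect %in% nondis_eff,
      lof = !is.na(effect) & effect %in% lof_eff,
      missense_damaging = !is.na(effect) & effect == "nonsynonymous-SNV" &
        (dplyr::coalesce(sift_damaging, FALSE) |
           dplyr::coalesce(polyphen_humvar_damaging, FALSE))
    )
  g |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(dplyr::across(c(total_coding, nondisrupting, lof,
                                     missense_damaging), sum),
                     .groups = "drop") |>
    tidyr::pivot_longer(-sample_id, names_to = "category", values_to = "n") |>
    tidyr::complete(sample_id = unique(genotypes$sample_id),
                    category = c("total_coding", "nondisrupting", "lof",
                                 "missense_damaging"),
                    fill = list(n = 0L))
}

#' Rare-variant burden comparison between affected and unaffected samples
#'
#' Compares per-sample counts between groups per category. The default test
#' is the two-sided Mann-Whitney (Wilcoxon rank-sum); a label-permutation
#' p-value on the difference of group means is reported alongside when
#' `n_perm > 0`.
#'
#' @param counts Tibble with `sample_id`, `category`, `n` (e.g. from
#'   [count_burden_categories()]).
#' @param affected Named logical vector (names = sample ids) or a tibble
#'   with `sample_id` and `affected`.
#' @param n_perm Number of label permutations (default 1000; 0 disables).
#' @param alpha Decision level (default 0.05).
#' @return An object of class `"raretrio_burden"`: a tibble with one row per
#'   category (group means, Wilcoxon p, permutation p, decision), with group
#'   sizes in attributes. Supports [tidy()] and [glance()].
#' @export
burden_test <- function(counts, affected, n_perm = 1000, alpha = 0.05) {
  if (is.data.frame(affected)) {
    affected <- stats::setNames(affected$affected, affected$sample_id)
  }
  counts <- counts |>
    dplyr::mutate(affected = unname(affected[sample_id]))
  if (any(is.na(counts$affected))) {
    rlang::abort("samples in counts without an affected flag")
  }
  n_aff <- dplyr::n_distinct(counts$sample_id[counts$affected])
  n_unaff <- dplyr::n_distinct(counts$sample_id[!counts$affected])
  if (n_aff == 0 || n_unaff == 0) {
    rlang::abort("burden comparison requires both groups non-empty")
  }
  res <- counts |>
    dplyr::group_by(category) |>
    dplyr::group_modify(function(d, key) {
      x <- d$n[d$affected]
      y <- d$n[!d$affected]
      if (stats::sd(d$n) == 0) {
        # identical counts everywhere: no evidence of a difference
        w <- list(statistic = NA_real_, p.value = 1)
      } else {
        w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      }
      p_perm <- if (n_perm > 0) {
        obs <- mean(x) - mean(y)
        all_n <- d$n
        lab <- d$affected
        perms <- vapply(seq_len(n_perm), function(i) {
          sl <- sample(lab)
          mean(all_n[sl]) - mean(all_n[!sl])
        }, numeric(1))
        (1 + sum(abs(perms) >= abs(obs))) / (n_perm + 1)
      } else NA_real_
      tibble::tibble(
        mean_affected = mean(x), mean_unaffected = mean(y),
        statistic = unname(w$statistic), p_wilcoxon = w$p.value,
        p_permutation = p_perm
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = p_wilcoxon < alpha)
  structure(res, class = c("raretrio_burden", class(res)),
            n_affected = n_aff, n_unaffected = n_unaff, alpha = alpha,
            n_perm = n_perm)
}

#' Phenotype prevalence among probands
#'
#' For each condition, the denominator is the number of individuals with
#' known status (unknowns excluded) and the numerator those with the
#' phenotype present; the percentage is reported to two decimals.
#'
#' @param phenotypes Phenotype tibble ([read_phenotypes()]).
#' @param individuals Optional character vector restricting to a set of
#'   individuals (e.g. probands).
#' @param conditions Optional conditions to report (default all).
#' @return Tibble `condition`, `n_tested`, `n_with`, `percent` (`NA` with
#'   `undefined = TRUE` when nobody was tested).
#' @export
phenotype_prevalence <- function(phenotypes, individuals = NULL,
                                 conditions = NULL) {
  ph <- phenotypes
  if (!is.null(individuals)) {
    ph <- ph |> dplyr::filter(individual_id %in% individuals)
  }
  if (!is.null(conditions)) {
    ph <- ph |> dplyr::filter(condition %in% conditions)
  }
  ph |>
    dplyr::group_by(condition) |>
    dplyr::summarise(
      n_tested = sum(status != "unknown"),
      n_with = sum(status == "present"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      percent = ifelse(n_tested > 0, round(100 * n_with / n_tested, 2),
                       NA_real_),
      undefined = n_tested == 0
    )
}

#' Cohort demographic summary
#'
#' Role counts, affected/unaffected totals, and the male-to-female ratio
#' among probands (to one decimal).
#'
#' @param pedigree Pedigree tibble.
#' @return One-row tibble: `n_individuals`, `n_probands`, `n_fathers`,
#'   `n_mothers`, `n_grandmothers`, `n_siblings`, `n_unaffected`,
#'   `n_male_probands`, `n_female_probands`, `male_female_ratio`.
#' @export
cohort_demographics <- function(pedigree) {
  pro <- pedigree |> dplyr::filter(role == "proband")
  tibble::tibble(
    n_individuals = nrow(pedigree),
    n_probands = nrow(pro),
    n_fathers = sum(pedigree$role == "father"),
    n_mothers = sum(pedigree$role == "mother"),
    n_grandmothers = sum(pedigree$role == "grandmother"),
    n_siblings = sum(pedigree$role == "sibling"),
    n_unaffected = sum(!pedigree$affected),
    n_male_probands = sum(pro$sex == "male"),
    n_female_probands = sum(pro$sex == "female"),
    male_female_ratio = round(sum(pro$sex == "male") /
                                sum(pro$sex == "female"), 1)
  )
}

#' Parental-age comparisons and de novo count correlations
#'
#' Compares parental ages at birth between affected and unaffected offspring
#' (two-sided Mann-Whitney) and correlates per-proband de novo counts with
#' each parent's age (Spearman by default; Pearson by flag). Correlations
#' with fewer than 3 complete pairs are not computed.
#'
#' @param offspring Tibble with one row per offspring: `individual_id`,
#'   `affected` (logical), `paternal_age`, `maternal_age`, and optionally
#'   `de_novo_count` for affected offspring.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @return Tibble with one row per analysis: `analysis`, `estimate`
#'   (difference of means or correlation), `p_value`, `n`.
#' @export
parental_age_analyses <- function(offspring, method = "spearman") {
  cmp <- function(col) {
    x <- offspring[[col]][offspring$affected]
    y <- offspring[[col]][!offspring$affected]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      return(tibble::tibble(
        analysis = paste0(col, "_affected_vs_unaffected"),
        estimate = NA_real_, p_value = NA_real_,
        n = length(x) + length(y)))
    }
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    tibble::tibble(
      analysis = paste0(col, "_affected_vs_unaffected"),
      estimate = mean(x) - mean(y), p_value = w$p.value,
      n = length(x) + length(y))
  }
  cors <- function(col) {
    d <- offspring |>
      dplyr::filter(affected, !is.na(de_novo_count), !is.na(.data[[col]]))
    if (nrow(d) < 3) {
      return(tibble::tibble(
        analysis = paste0("de_novo_vs_", col),
        estimate = NA_real_, p_value = NA_real_, n = nrow(d)))
    }
    ct <- suppressWarnings(
      stats::cor.test(d$de_novo_count, d[[col]], method = method))
    tibble::tibble(analysis = paste0("de_novo_vs_", col),
                   estimate = unname(ct$estimate), p_value = ct$p.value,
                   n = nrow(d))
  }
  out <- dplyr::bind_rows(cmp("paternal_age"), cmp("maternal_age"))
  if ("de_novo_count" %in% names(offspring)) {
    out <- dplyr::bind_rows(out, cors("paternal_age"), cors("maternal_age"))
  }
  out
}

#' Specific-expression enrichment over pre-thresholded gene sets
#'
#' For each gene set (a brain region by developmental window, membership
#' already thresholded upstream at pSI < 0.05), builds the 2x2 table of
#' candidate vs background genes inside vs outside the set, computes the
#' one-sided Fisher exact (hypergeometric) p-value, and adjusts across all
#' sets with Benjamini-Hochberg. Candidate genes absent from the background
#' universe are dropped with a warning.
#'
#' @param candidate_genes Character vector of candidate gene symbols.
#' @param gene_sets Tibble with `set_id` and `gene`.
#' @param background Character vector: the gene universe.
#' @param alpha Q-value significance level (default 0.05).
#' @return Object of class `"sea_enrichment"`: tibble with one row per set
#'   (`set_id`, contingency counts, `p_value`, `q_value`, `significant`).
#'   Supports [tidy()], [glance()], and [autoplot()].
#' @export
sea_enrichment <- function(candidate_genes, gene_sets, background,
                           alpha = 0.05) {
  candidate_genes <- unique(candidate_genes)
  background <- unique(background)
  missing <- setdiff(candidate_genes, background)
  if (length(missing) > 0) {
    rlang::warn(paste("candidate genes absent from background dropped:",
                      paste(missing, collapse = ", ")))
    candidate_genes <- intersect(candidate_genes, background)
  }
  non_cand <- setdiff(background, candidate_genes)
  res <- gene_sets |>
    dplyr::distinct(set_id, gene) |>
    dplyr::group_by(set_id) |>
    dplyr::group_modify(function(d, key) {
      set_genes <- intersect(d$gene, background)
      a <- length(intersect(candidate_genes, set_genes))
      b <- length(candidate_genes) - a
      c <- length(intersect(non_cand, set_genes))
      dd <- length(non_cand) - c
      p <- stats::fisher.test(matrix(c(a, b, c, dd), nrow = 2,
                                     byrow = TRUE),
                              alternative = "greater")$p.value
      tibble::tibble(in_set_candidate = a, out_set_candidate = b,
                     in_set_background = c, out_set_background = dd,
                     p_value = p)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      q_value = stats::p.adjust(p_value, method = "BH"),
      significant = q_value < alpha
    )
  structure(res, class = c("sea_enrichment", class(res)), alpha = alpha)
}
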