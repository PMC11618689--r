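# Independent brute-force oracles. These re-derive expected results by
# direct looping over the stated definitions and stay independent of the
# package's vectorized implementations.

# quality retention by direct comparison
oracle_retained <- function(dp, gq) {
  !is.na(dp) & !is.na(gq) & dp >= 10 & gq >= 30
}

# per-cohort brute-force segregation over a long genotype tibble.
# Returns a tibble of calls (proband_id, mode, variant_key, pair partner).
oracle_segregate <- function(geno, pedigree, annotation) {
  geno$key <- paste(geno$chrom, geno$pos, geno$ref, geno$alt, sep = ":")
  ann_gene <- stats::setNames(annotation$gene,
                              paste(annotation$chrom, annotation$pos,
                                    annotation$ref, annotation$alt,
                                    sep = ":"))
  af_cols <- grep("^af_", names(annotation), value = TRUE)
  ann_key <- paste(annotation$chrom, annotation$pos, annotation$ref,
                   annotation$alt, sep = ":")
  keys <- unique(geno$key)
  samples <- unique(geno$sample_id)

  gt_at <- function(s, k) {
    row <- geno[geno$sample_id == s & geno$key == k, ]
    if (nrow(row) == 0) return(list(gt = NA, obs = FALSE, row = NULL))
    ok <- oracle_retained(row$dp[1], row$gq[1]) && !is.na(row$gt[1])
    list(gt = if (ok) row$gt[1] else NA, obs = ok, row = row[1, ])
  }
  carriers_of <- function(k) {
    n <- 0L
    for (s in samples) {
      g <- gt_at(s, k)
      if (g$obs && g$gt >= 1) n <- n + 1L
    }
    n
  }
  is_rare <- function(k) {
    i <- match(k, ann_key)
    if (is.na(i)) return(TRUE)
    vals <- unlist(annotation[i, af_cols])
    all(is.na(vals) | vals < 0.01)
  }
  is_novel <- function(k) {
    i <- match(k, ann_key)
    if (is.na(i)) return(TRUE)
    vals <- unlist(annotation[i, af_cols])
    all(is.na(vals))
  }
  is_private <- function(k) is_novel(k) && carriers_of(k) == 1L

  in_par <- function(chrom, pos) {
    chrom == "chrX" &&
      ((pos >= 10001 && pos <= 2781479) ||
         (pos >= 155701383 && pos <= 156030895))
  }

  out <- list()
  emit <- function(p, mode, k, partner = NA_character_) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      proband_id = p, mode = mode, variant_key = k,
      partner_variant_key = partner)
  }
  probands <- pedigree[pedigree$role == "proband", ]
  for (pi in seq_len(nrow(probands))) {
    p <- probands$individual_id[pi]
    fam <- probands$family_id[pi]
    fa <- probands$father_id[pi]
    mo <- probands$mother_id[pi]
    if (!is.na(fa) && !fa %in% samples) fa <- NA
    if (!is.na(mo) && !mo %in% samples) mo <- NA
    sibs <- pedigree$individual_id[pedigree$family_id == fam &
                                     pedigree$role == "sibling"]
    sibs <- sibs[sibs %in% samples]
    rels <- c(fa, mo, sibs)
    rels <- rels[!is.na(rels)]
    male <- probands$sex[pi] == "male"
    for (k in keys) {
      g <- gt_at(p, k)
      if (!g$obs) next
      row <- g$row
      # de novo
      if (g$gt == 1 && is_private(k) && (!is.na(fa) || !is.na(mo))) {
        rel_states <- vapply(rels, function(s) {
          r <- gt_at(s, k)
          if (!r$obs) "unknown" else if (r$gt >= 1) "carrier" else "clear"
        }, character(1))
        crit <- !is.na(row$gq) && row$gq >= 99 &&
          !is.na(row$ad_alt) && row$ad_alt >= 10 &&
          !is.na(row$ad_ref) && row$ad_ref >= 10 &&
          !is.na(row$dp) && row$dp > 0 &&
          row$ad_alt / row$dp >= 0.3 && row$ad_alt / row$dp <= 0.7 &&
          !is.na(row$qual) && row$qual >= 999 &&
          nchar(row$ref) <= 50 && nchar(row$alt) <= 50
        if (crit && length(rel_states) > 0 &&
            all(rel_states == "clear")) {
          emit(p, "de_novo", k)
        } else if (crit && length(rel_states) == 0) {
          emit(p, "de_novo", k)
        }
      }
      # inherited homozygous (chrX male calls are hemizygous, excluded)
      if (g$gt == 2 && is_rare(k) &&
          !(row$chrom == "chrX" && male) &&
          (!is.na(fa) || !is.na(mo))) {
        ok <- TRUE
        if (!is.na(fa)) {
          r <- gt_at(fa, k)
          if (!(r$obs && r$gt == 1)) ok <- FALSE
        }
        if (!is.na(mo)) {
          r <- gt_at(mo, k)
          if (!(r$obs && r$gt == 1)) ok <- FALSE
        }
        for (s in sibs) {
          r <- gt_at(s, k)
          if (r$obs && r$gt >= 2) ok <- FALSE
        }
        if (ok) emit(p, "inherited_hom", k)
      }
      # X-linked
      if (row$chrom == "chrX" && !in_par(row$chrom, row$pos) &&
          is_rare(k) && male && !is.na(mo)) {
        hemi <- (row$ploidy == 1 && g$gt == 1) || g$gt == 2
        if (hemi) {
          r <- gt_at(mo, k)
          if (r$obs && r$gt == 1) emit(p, "x_linked", k)
        }
      }
    }
    # compound het: both parents required
    if (!is.na(fa) && !is.na(mo)) {
      genes <- unique(stats::na.omit(unname(ann_gene[keys])))
      for (gn in genes) {
        gkeys <- keys[!is.na(ann_gene[keys]) & ann_gene[keys] == gn]
        pat <- character(0)
        mat <- character(0)
        for (k in gkeys) {
          g <- gt_at(p, k)
          if (!g$obs || g$gt != 1 || !is_rare(k)) next
          row <- g$row
          adok <- !is.na(row$ad_alt) && row$ad_alt >= 10 &&
            !is.na(row$ad_ref) && row$ad_ref >= 10 &&
            !is.na(row$dp) && row$dp > 0 &&
            row$ad_alt / row$dp >= 0.3 && row$ad_alt / row$dp <= 0.7
          if (!adok) next
          rf <- gt_at(fa, k)
          rm_ <- gt_at(mo, k)
          if (rf$obs && rf$gt == 1 && rm_$obs && rm_$gt == 0) {
            pat <- c(pat, k)
          } else if (rm_$obs && rm_$gt == 1 && rf$obs && rf$gt == 0) {
            mat <- c(mat, k)
          }
        }
        for (k1 in pat) for (k2 in mat) {
          emit(p, "compound_het", k1, k2)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(proband_id = character(0), mode = character(0),
                          variant_key = character(0),
                          partner_variant_key = character(0)))
  }
  dplyr::bind_rows(out)
}

# straight-line reference for the prioritization ladder's hard filters:
# entry (possibly damaging), step 1 dedup, step 6 ClinVar, step 7 gnomAD
# homozygotes, plus the oversized-gene missense-rate rule. Returns the set
# of surviving (proband_id, variant_key) strings.
oracle_prioritize <- function(calls, annotation, gene_metadata,
                              oversized = "TTN") {
  ann_key <- paste(annotation$chrom, annotation$pos, annotation$ref,
                   annotation$alt, sep = ":")
  survivors <- character(0)
  rec <- list()
  for (i in seq_len(nrow(calls))) {
    k <- calls$variant_key[i]
    j <- match(k, ann_key)
    if (is.na(j)) next
    eff <- annotation$effect[j]
    damaging <- FALSE
    if (!is.na(eff)) {
      if (eff == "splice-site") damaging <- TRUE
      if (eff %in% c("frameshift-insertion", "frameshift-deletion",
                     "nonframeshift-insertion", "nonframeshift-deletion",
                     "stopgain", "stoploss", "unknown")) damaging <- TRUE
      if (eff == "nonsynonymous-SNV") {
        s <- annotation$sift_damaging[j]
        pp <- annotation$polyphen_humvar_damaging[j]
        damaging <- isTRUE(s) || isTRUE(pp)
      }
    }
    if (!damaging) next
    rec[[length(rec) + 1L]] <- list(
      proband = calls$proband_id[i], family = calls$family_id[i],
      key = k, gene = annotation$gene[j], effect = eff,
      clinvar = annotation$clinvar_significance[j],
      hom = annotation$gnomad_hom_carriers[j])
  }
  if (length(rec) == 0) return(character(0))
  # step 1: same key in > 1 family
  key_fams <- list()
  for (r in rec) {
    key_fams[[r$key]] <- union(key_fams[[r$key]], r$family)
  }
  benign <- function(x) {
    if (is.na(x)) return(FALSE)
    toks <- trimws(strsplit(tolower(gsub("_", " ", x)), "[/;,|]")[[1]])
    toks <- toks[toks != ""]
    length(toks) > 0 && all(toks %in% c("benign", "likely benign"))
  }
  kept <- list()
  for (r in rec) {
    if (length(key_fams[[r$key]]) > 1) next
    if (benign(r$clinvar)) next
    if (!is.na(r$hom) && r$hom >= 1) next
    kept[[length(kept) + 1L]] <- r
  }
  # oversized-gene missense rate per proband
  final <- character(0)
  for (r in kept) {
    drop <- FALSE
    if (r$gene %in% oversized && r$effect == "nonsynonymous-SNV") {
      gm <- gene_metadata[gene_metadata$symbol == r$gene, ]
      if (nrow(gm) == 1 && !is.na(gm$coding_length_bp) &&
          !is.na(gm$gnomad_missense_rate)) {
        n_mis <- 0
        seen <- character(0)
        for (r2 in kept) {
          if (r2$proband == r$proband && r2$gene == r$gene &&
              r2$effect == "nonsynonymous-SNV" && !r2$key %in% seen) {
            seen <- c(seen, r2$key)
            n_mis <- n_mis + 1
          }
        }
        if (n_mis / gm$coding_length_bp > gm$gnomad_missense_rate) {
          drop <- TRUE
        }
      }
    }
    if (!drop) final <- c(final, paste(r$proband, r$key))
  }
  unique(final)
}

# Benjamini-Hochberg step-up by the textbook recursion
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  if (m > 1) {
    for (i in (m - 1):1) {
      q[o[i]] <- min(q[o[i + 1]], p[o[i]] * m / i)
    }
  }
  pmin(q, 1)
}

# one-sided Fisher p as an explicit hypergeometric tail sum for the table
# rbind(c(a, b), c(c, d)) with alternative = "greater"
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + c          # white balls (in set)
  n <- b + d          # black balls
  k <- a + b          # drawn (candidates)
  xs <- a:min(m, k)
  sum(stats::dhyper(xs, m, n, k))
}

# random small family cohorts for the equivalence suite
random_cohort <- function(seed) {
  set.seed(seed)
  n_fam <- sample(1:2, 1)
  geno <- list()
  ped <- list()
  n_var <- sample(2:6, 1)
  vars <- tibble::tibble(
    chrom = sample(c("chr1", "chrX"), n_var, replace = TRUE),
    pos = sample(3000000:4000000, n_var),
    ref = "A", alt = "T",
    qual = sample(c(500, 999, 1500), n_var, replace = TRUE),
    gene = sample(c("G1", "G2"), n_var, replace = TRUE)
  )
  af_pick <- sample(c(NA, 0.001, 0.02), n_var, replace = TRUE)
  annotation <- vars |>
    dplyr::mutate(
      effect = sample(c("nonsynonymous-SNV", "synonymous-SNV", "stopgain"),
                      n_var, replace = TRUE),
      af_gnomad = af_pick,
      sift_damaging = sample(c(TRUE, FALSE, NA), n_var, replace = TRUE),
      polyphen_humvar_damaging = NA,
      clinvar_significance = NA_character_,
      gnomad_hom_carriers = NA_real_
    )
  for (f in seq_len(n_fam)) {
    fid <- paste0("FAM", f)
    members <- c("P")
    if (stats::runif(1) < 0.8) members <- c(members, "FA")
    if (stats::runif(1) < 0.9) members <- c(members, "MO")
    if (stats::runif(1) < 0.6) members <- c(members, "S1")
    if (stats::runif(1) < 0.2 && length(members) < 5) {
      members <- c(members, "S2")
    }
    p_sex <- sample(c("male", "female"), 1)
    for (m in members) {
      ped[[length(ped) + 1L]] <- tibble::tibble(
        family_id = fid, individual_id = paste0(fid, "_", m),
        father_id = if (m %in% c("P", "S1", "S2") && "FA" %in% members)
          paste0(fid, "_FA") else NA_character_,
        mother_id = if (m %in% c("P", "S1", "S2") && "MO" %in% members)
          paste0(fid, "_MO") else NA_character_,
        sex = dplyr::case_when(m == "FA" ~ "male", m == "MO" ~ "female",
                               m == "P" ~ p_sex,
                               TRUE ~ sample(c("male", "female"), 1)),
        affected = m == "P"
      )
      for (v in seq_len(n_var)) {
        gt <- sample(c(0L, 1L, 2L, NA), 1, prob = c(0.5, 0.25, 0.15, 0.1))
        dp <- sample(c(5L, 10L, 40L, 50L), 1)
        ad_alt <- if (is.na(gt)) NA_integer_ else
          as.integer(round(dp * c(0.02, 0.5, 0.98)[gt + 1L]))
        geno[[length(geno) + 1L]] <- tibble::tibble(
          chrom = vars$chrom[v], pos = vars$pos[v], ref = vars$ref[v],
          alt = vars$alt[v], qual = vars$qual[v],
          sample_id = paste0(fid, "_", m), gt = gt, ploidy = 2L,
          dp = dp, gq = sample(c(20L, 30L, 99L), 1),
          ad_ref = dp - ad_alt, ad_alt = ad_alt)
      }
    }
  }
  list(
    genotypes = dplyr::bind_rows(geno),
    pedigree = build_ped_from_rows(dplyr::bind_rows(ped)),
    annotation = dplyr::bind_rows(annotation)
  )
}

# assemble a pedigree tibble with inferred roles via the package reader,
# by round-tripping through a PED file (exercises the same inference path
# the pipeline uses on real input)
build_ped_from_rows <- function(rows) {
  f <- tempfile(fileext = ".ped")
  on.exit(unlink(f))
  utils::write.table(
    data.frame(rows$family_id, rows$individual_id,
               ifelse(is.na(rows$father_id), "0", rows$father_id),
               ifelse(is.na(rows$mother_id), "0", rows$mother_id),
               ifelse(rows$sex == "male", "1", "2"),
               ifelse(rows$affected, "2", "1")),
    f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  read_pedigree(f)
}
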