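---
title: "Rare-variant segregation and prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant segregation and prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`raretrio` implements a family-based rare-variant discovery pipeline for
exome cohorts ascertained through an affected child (the proband). The
working currency is a long tibble with one row per sample per biallelic
site (`chrom`, `pos`, `ref`, `alt`, `qual`, `sample_id`, `gt`, `ploidy`,
`dp`, `gq`, `ad_ref`, `ad_alt`). Multiallelic VCF records are split per ALT
allele at read time — the genotype dosage and AD of each row refer to one
allele — and alleles are minimally normalized (shared suffix then prefix
trimmed, position advanced), because every downstream rule is per-allele.
VCF positions stay 1-based; CNV intervals are 0-based half-open (the
CNVkit convention); conversion happens once at the interval-overlap
boundary.

Two conventions matter everywhere:

* **A missing or quality-failed genotype is unknown, never homozygous
  reference.** Segregation treats an unknown genotype in a relative as
  not-evaluable rather than as evidence of absence, so sequencing dropout
  cannot manufacture de novo calls.
* **Privacy is person-level.** A variant shared by a proband and a parent
  is not private, which is what makes the de novo definition (private het,
  absent in relatives) internally consistent.

# The filtration and segregation rules

Quality filtering retains a genotype iff DP ≥ 10 and GQ ≥ 30; both
thresholds are inclusive and the filter is per genotype. Rarity requires
every available database frequency — overall and sub-population `af_*`
columns alike — to be strictly below 1%; absent frequencies do not veto
rarity. Novel means absent from all databases; private means novel with
exactly one carrier among quality-retained genotypes.

The four segregation callers implement the rules stated in the README. Two
boundary decisions deserve justification:

* **Male chromosome-X homozygous-style calls are hemizygous.** They are
  eligible only for the X-linked caller, not the autosomal recessive one.
  Without this, a male proband's chrX variant in a family with a missing
  father would satisfy the one-parent homozygous rule (mother het) *and*
  the X-linked rule and be double-called.
* **Pseudoautosomal regions (GRCh38 PAR1/PAR2) are excluded from X-linked
  calling** and treated as autosomal, with a flag to disable; PAR loci
  recombine with chrY and do not follow hemizygous inheritance.

The X-linked caller accepts both common pVCF encodings of male chrX calls
(diploid homozygous-style `1/1` and haploid `1`); the generator defaults to
the diploid encoding with a switch to emit haploid calls.

Affected female carriers of X-linked variants are excluded by default —
the rule as stated applies to male offspring — but
`allow_female_probands = TRUE` permits them, with the deviation flagged in
the output. Compound-het pairs are not pruned when an unaffected sibling
carries both members in trans; no such rule is part of the stated method,
and a stricter mode can be layered on the pair table by the user.

# The prioritization ladder

Only possibly-damaging calls enter: splice-site variants; exonic variants
with frameshift/nonframeshift indel, stopgain/stoploss, or unknown effect;
and nonsynonymous SNVs called damaging by at least one of SIFT and
PolyPhen-2 HumVar (absent predictions count as benign for this basis).

Steps 1, 6, and 7 are hard filters (cross-family identical variant;
ClinVar benign/likely-benign; ≥ 1 gnomAD homozygote). Steps 3–5 — gene
recurrence, deleteriousness scoring, and constraint (pLI > 0.5 and
LOEUF < 0.5) — are encoded as ranking components rather than filters: the
published survivor tables include genes with pLI near zero, so treating
them as filters would not reproduce the published structure. "Unrelated
person" in step 1 means a different family; within-family sharing (e.g.
affected sibling pairs) is retained.

Numerical choices the method statement leaves open:

* Step-4 deleteriousness beyond SIFT/PolyPhen counts VEST ≥ 0.5,
  CADD ≥ 20, and phyloP ≥ 2 as supporting evidence. These are the tools'
  conventional operating points; all three are arguments.
* ClinVar matching is case-insensitive and tokenizes composite labels on
  `/;,|`; a label drops a variant only if *every* assertion it contains is
  benign or likely benign.
* Ranking uses the tuple (tier, truncating-vs-missense, de novo vs
  inherited, descending AlphaMissense, recurrence, deleteriousness count,
  constraint, variant key). Absent AlphaMissense sorts last among
  missense; the final variant-key tie-break makes the order a
  deterministic total order, which the property tests verify.

The oversized-gene filter divides the number of base pairs carrying
missense variants in the gene in one proband by the gene's coding length
and drops the gene's variants for that proband iff the quotient exceeds
the gnomAD missense rate per bp. It defaults to TTN (108,000 bp coding,
reference rate 1.23 × 10⁻⁵) and takes any gene list with metadata; a gene
lacking a coding length is skipped with a warning.

# CNV post-processing

Order of operations: outlier-sample exclusion, then the
significance/copy-number/log2 filter, then cross-family exact dedup, then
locus annotation, then the common-SV containment filter. Each segment ends
with exactly one fate (`dropped_reason`, `"none"` = kept), and the tests
assert conservation (inputs = kept + dropped per reason).

* Outlier exclusion removes samples whose raw segment count exceeds
  median + 3·MAD. The published removal was a manual judgment; an explicit
  bound makes it reproducible, and `k` is an argument.
* "Overlaps a known locus" means ≥ 1 bp of intersection; the overlap bp
  and fraction are reported so stricter reciprocal-overlap policies can be
  applied downstream. Overlap never drops a call.
* "Completely overlapped" by a structural variant is interpreted as
  containment of the call interval within the SV interval, with the SV
  type required to match the call direction (DEL vs deletion, DUP vs
  duplication). Type matching is a documented choice (`match_type =
  FALSE` disables it): a deletion sitting inside a common duplication is
  not explained by the duplication.
* Dedup compares intervals exactly (same chrom/start/end/direction in
  probands of different families). A tolerance could be added, but exact
  matching is the conservative reading and is what the truth tests pin.

# Cohort statistics

The burden comparison defaults to a two-sided Mann–Whitney test with a
label-permutation p-value (difference of group means, `n_perm`
permutations) reported alongside; no specific test is prescribed by the
method, and the claim being checked is only the absence of a difference.
When a category's counts are identical across all samples the test reports
p = 1. Parental-age comparisons use the same rank-based default;
correlations of de novo counts with parental age default to Spearman
(counts are non-normal), with Pearson by flag, and are not computed below
3 complete pairs.

Specific-expression enrichment consumes pre-thresholded pSI < 0.05 gene
sets (deriving pSI from expression data is upstream of this package). Each
set yields a 2×2 table of candidate/background × in/out-of-set, a
one-sided Fisher exact p (equal to the hypergeometric tail sum, which the
tests verify exhaustively for small margins), and Benjamini–Hochberg q
across all sets tested in one run; significance is q < 0.05. Candidates
absent from the background are dropped with a warning rather than
silently shrinking the universe.

# What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates nuclear families (proband, mother, father
present with probability 1 − 30/195, one unaffected sibling with
probability 174/195), proband sex male with probability 162/222, and
phenotype states drawn at the cohort's reported testing and prevalence
rates. Background sites are Mendelian by construction: founder genotypes
are drawn from an allele frequency, children inherit one allele per
parent. An ungenotyped father's background genotypes are zeroed before
transmission so that a singleton in his child cannot masquerade as de
novo — the generator must not plant false positives it did not label.

Planted per proband: 4 de novo variants (2 coding damaging), 10
compound-het variants in 3 genes (pair structure 2/2/1 per parent of
origin, so the engine's pair count per proband is 2² + 2² + 1 = 9), and 16
X-linked variants (8 coding) in male probands — these follow the cohort's
reported per-proband averages. Inherited homozygous defaults to 12 per
proband (3 coding, preserving the reported coding fraction) rather than
the reported 155: the rule under test is identical at any multiplicity,
and 12 keeps the 50-family acceptance cohort around 2,000 sites ×
190 samples, which the whole pipeline processes in seconds. The background
defaults to 120 shared sites (30% database-rare, 10% novel); raw per-exome
variant counts at sequencing scale are not emulated.

With `decoys = TRUE` (and ≥ 4 families) one decoy is planted per filter
rule — quality failure, common allele, non-private inherited het, each de
novo criterion, cis compound-het, parental/sibling homozygote, maternal
X homozygote, female X carrier, cross-family duplicate, ClinVar benign,
gnomAD homozygote, synonymous de novo, and the TTN missense pair — each
with its expected fate recorded in the truth table. The CNV generator
plants the analogous set for the segment filters, plus an outlier sample
carrying 174 extra segments and two survivors expected to resist the SV
filter (type mismatch; rare SV).

Noise (`noise = TRUE`) draws DP from Poisson(46) — the cohort's reported
mean depth — GQ from a clipped normal, and het allele balance from
Beta(20, 20). It is off by default: logic tests and truth-recovery
acceptance run noise-free so planted fates are exact, while the noise mode
exists for stochastic robustness checks. The stated distributional forms
are engineering choices; only the depth mean is taken from the cohort
description.

What passing the truth-recovery tests shows is that every stated rule is
implemented exactly as stated, including its boundary cases. What it does
not show: performance on real data with linkage structure, population
stratification, batch effects, annotation errors, or realistic
site-frequency spectra — none of which the generator attempts.

# Problem sizes and determinism

The acceptance suite uses a 50-family noise-free cohort (~190 samples,
~2,000 sites) for truth recovery, 30 random small cohorts (≤ 5 members,
≤ 6 variants) for the segregation brute-force equivalence, 15 random
cohorts of ≤ 50 variants for the prioritization reference, 200 random
2×2 tables plus 1,000 random p-vectors for the Fisher/BH oracles, and 100
null replicates × 1,000 permutations for burden calibration. All
randomness flows from fixed seeds; a fixed configuration and seed yield
byte-identical simulated files, which the tests assert by re-generating
and comparing.

# Known limitations

* No statistical de novo calling (joint likelihoods, mosaicism); the
  criteria are deterministic genotype filters, faithful to the method but
  blind to borderline evidence.
* Storage is in-memory tibbles; an SQL backend would be needed at
  biobank scale.
* The annotation consumer trusts its input: effect classes outside the
  declared vocabulary are rejected rather than re-derived from transcripts.
* Multi-generation pedigrees are read and role-inferred (grandmothers are
  recognized and treated as unaffected relatives), but segregation only
  consults parents and siblings of the proband.
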