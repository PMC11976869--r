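---
title: "In silico protease digestion and proteome complexity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico protease digestion and proteome complexity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteasim)
```

## The digestion model

A protease is modelled as a cleavage rule: a set of recognized residues
and a terminus. A C-terminal rule cuts immediately after each matched
residue, an N-terminal rule immediately before it. Cut positions are
represented internally as 0-based inter-residue offsets (a cut at
offset *i* separates residues *i* and *i + 1*); reported peptide
coordinates are 1-based inclusive, the convention of proteomics tools.
A matched residue at the protein terminus produces no cut — it would
coincide with the terminus and create a zero-length product.

Digestion is *fully specific*: a peptide's boundaries are cleavage
sites or protein termini, never intermediate positions. Given the cut
offsets `0 < s_1 < … < s_m < n`, the zero-missed fragments are the
`m + 1` intervals between consecutive boundaries, and a peptide
spanning fragments *i*…*j* carries `j − i` missed cleavages. With a
missed-cleavage cap `k`, a protein with `s` internal sites yields

```
sum_{j = 0}^{min(k, s)} (s + 1 − j)
```

fully specific peptides before length filtering (`count_unfiltered()`),
a closed form the engine is tested against, alongside a brute-force
substring-enumeration oracle and the reconstruction identity (the
zero-missed unfiltered fragments concatenate back to the protein).

Two conventions are worth making explicit:

* **Peptides are positional occurrences.** Identical sequences at
  different coordinates (or in different proteins) are distinct rows;
  de-duplication to distinct sequences happens only in the
  proteome-level aggregation, which reports both tallies
  (`total_peptides` and `distinct_sequences`). Occurrence counting is
  the conservative reading of "number of peptides", and exposing both
  resolves the ambiguity without guessing.
* **Nonstandard residues** (X, U, B, Z, O) are tolerated in sequences
  but never match a rule unless explicitly listed: an unknown residue
  should not create a cut.

Default criteria are ≤ 2 missed cleavages and lengths 6–60 residues —
the window commonly used to enumerate plausibly observable peptides; a
search-engine-style alternative (7–30) is one constructor call away
(`digest_config(2, 7, 30)`). The proline-block flag exists because
search engines offer it, but defaults to off: the specificities
simulated here are bare residue rules.

The `gluc` preset deserves a note. GluC's conventional specificity is
glutamate (E), and that is what `gluc` compiles to; a
`gluc_paper` preset with the set {F, Y, W, I} is also shipped because
that rule appears in print under the GluC label in some published
simulations. The package takes no position; both are available and the
grammar (`"E@C"`, `"FYWI@C"`, `"K@N"`, …) expresses any other variant.

## Complexity relative to a reference

`digest_proteome()` aggregates a digest proteome-wide;
`relative_complexity()` expresses one digest against a reference
(conventionally trypsin) as

* `peptide_ratio` — total passing occurrences over the reference total;
* `median_per_protein_ratio` — ratio of median peptides per protein,
  medians over **all** proteins with zeros included (no exclusion rule
  is implied by "median peptides per protein", and the per-protein
  vectors are retained so the zero-excluding convention can be
  recomputed);
* `coverage_pct` — the percentage of proteins yielding at least one
  passing peptide. Coverage here is protein-level presence, not
  residue-level sequence coverage.

`residue_scan()` runs all 40 single-residue rules (20 residues × C/N)
plus the presets, sorted by peptide ratio, which reproduces the
characteristic picture: single-residue proteases at human-like site
densities keep near-complete protein coverage at roughly half the
tryptic peptide load.

## Identification statistics

The comparison layer consumes a long-format identification table
(protein, peptide, condition, replicate, abundance, q-value), the shape
of a search-engine export after protein grouping (grouping itself is
out of scope). Conventions:

* **Confidence filtering** keeps rows with q strictly below the
  threshold (default 0.01, "high confidence").
* **CVs** are `100 · sd / mean` on raw abundances with the sample
  (n − 1) standard deviation, per protein (replicate abundance = sum of
  its peptides) or per peptide; a log-scale option exists. No bias
  correction is applied — the estimator is the field's plain CV. At
  three replicates this estimator is noticeably biased low: the sample
  standard deviation has expectation `c4(3) ≈ 0.886` of the truth, and
  the *median* sample CV for log-normal noise at a true 15% CV is about
  12.4%. Parameter-recovery checks therefore need either more
  replicates (at six, the median recovers within ±2 points) or a
  bias-aware expectation; this is a property of the estimator, not of
  the generator.
* **Proportion quantified** is the fraction of identified entities with
  a non-missing abundance in *every* replicate of the condition — the
  strictest reproducible reading of "quantified", and configurable by
  entity level.
* **Rank-abundance** tables order proteins by decreasing mean abundance
  with lexicographic tie-breaking, so outputs are deterministic.
* **Exclusive intersections** classify each protein of the union by its
  exact membership signature; counts over all signatures partition the
  union (the invariant every report checks).

Two readings of a "KS test on unique proteins" are both provided and
labelled: `ks_rank_uniformity()` (are the ranks of proteins unique to a
condition uniform over the condition's rank table? mid-rank fractions
`(r − 0.5)/n` against U(0,1)) and `two_sample_ks()` (do unique-protein
abundances share the full distribution?). The one-sample p-value uses
the exact small-sample computation up to n = 10 by default and the
asymptotic Kolmogorov distribution beyond; both switches are exposed.

`wilcoxon_rank_sum()` is exact (full enumeration) when both samples
have at most 10 observations and no ties — on the canonical worked case
(1,2,3) vs (4,5,6) it returns the exact two-sided p = 0.1 = 2/20 — and
otherwise uses the tie-corrected normal approximation with continuity
correction, which also handles tied data (identical multisets give
p = 1 by symmetry). `two_sample_t()` is Welch's unequal-variance test.
Note that Welch's test is *conservative* at very small samples: at
n = 3 vs 3 its true size at α = 0.05 is ≈ 0.035, so type-I calibration
experiments here use sizes where the operating characteristic is close
to nominal (exact Wilcoxon at 8 vs 8 has attainable size 0.0499; Welch
at 10 vs 10 ≈ 0.047). No multiple-testing correction is applied by
default; p-values are reported raw with the number of tests logged.

## The synthetic-data generator

The generator exists so the full pipeline is testable without
downloads. It emulates, in order:

1. **Proteome** — protein lengths log-normal with median 375 residues
   and log-sd 0.65 (the scale and spread of human proteins), residues
   i.i.d. from a human-average composition table (K ≈ 5.7%, R ≈ 5.6%,
   L ≈ 10%). Both are configurable.
2. **Abundances** — log10-normal. The normal scale is calibrated from
   the Blom approximation to the expected range of *n* standard-normal
   draws, `σ = orders / (2 · Φ⁻¹((n − 0.375)/(n + 0.25)))`, so that the
   realized `log10(max/min)` is close to the target dynamic range
   (default 6 orders of magnitude, the within-cell scale).
3. **Observation** — each protein's parent abundance is split equally
   among its zero-missed peptides, missed-cleavage products are
   down-weighted by a configurable factor (default 0.5 per missed
   site); each (peptide, condition, replicate) is detected
   independently with probability given by a logistic curve in log10
   parent abundance (midpoint defaulting to the proteome median — an
   explicit *stand-in* for DDA stochastic sampling, since no
   quantitative acquisition model is claimed); detected rows receive
   multiplicative log-normal noise with `sdlog = sqrt(log(1 + cv²))`,
   so the true CV equals the requested `replicate_cv`; q-values come
   from a two-component uniform mixture around the confidence
   threshold rather than a decoy model, because the pipeline only
   consumes thresholded q-values.

All three stages are seeded and byte-reproducible; `cmd_simulate()`
writes a manifest JSON with every parameter and seed.

**What the generator does not emulate — and what passing tests
therefore do not show.** Residues are i.i.d. within and across
proteins, so per-protein composition is far more homogeneous than in a
real database. This matters quantitatively: with i.i.d. sequences the
LysC:trypsin site-density ratio is ≈ 0.50 and the 6–60 filter trims
short tryptic fragments and over-long LysC missed products roughly in
balance, leaving a peptide ratio of ≈ 0.47–0.48. On a real human
database, lysine-poor proteins lose LysC products to the 60-residue cap
while trypsin still cleaves them at arginine, which pushes the LysC
ratio below 0.40. The package reports ≈ 0.48 on its synthetic stand-in
— consistent with the "< 50%" characterization of monosubstrate
proteases but not with the stricter < 40% figure, which requires the
real database (supply it as a FASTA to the same functions). Likewise
the generator has no retention-time structure, no isobaric labelling,
no peptide-detectability model beyond parent abundance, and no decoy
statistics.

## Numerical choices and degenerate inputs

* Sanitization uppercases, strips a trailing stop codon `*`, and
  rejects whitespace, digits and internal `*`; it is idempotent. A
  skip policy drops invalid records with a logged count instead of
  failing.
* A protein whose every candidate peptide fails the length window
  contributes zero occurrences but stays in the per-protein table
  (coverage denominator unchanged).
* `relative_complexity()` refuses mismatched protein universes and a
  zero-peptide reference; a zero reference median yields `NA` with a
  warning rather than infinity.
* Empty rank lists, empty samples and sub-2 sample sizes in the test
  layer raise immediate errors with the offending quantity named.
* Ties in rank-abundance break lexicographically; signatures in the
  intersection table are emitted for *every* non-empty combination,
  zeros included, so the partition invariant is checkable.

## Problem sizes

The shipped checks use a 2,000-protein synthetic proteome for the
complexity claims (ratios stabilize well below that size: 500 proteins
give the same first two decimals), 200 random sequences against the
enumeration oracle, 1,000 null replicates per type-I calibration, and
500 proteins × 3 or 6 replicates for CV recovery. These sizes were
chosen so each property is measured with comfortable statistical margin
while the whole suite stays interactive.

## Known limitations

* Digestion is fully specific only; semi- and non-specific products,
  PTMs and peptide masses are out of scope.
* Protein grouping/parsimony, FDR estimation and spectrum-level
  simulation are not modelled; the identification table is taken as
  already grouped and scored.
* The DDA detection curve is a logistic stand-in, labelled as such in
  simulation manifests.
* The i.i.d. residue model understates compositional heterogeneity
  (see above); conclusions about real databases should be drawn by
  running the real FASTA through the same pipeline.
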