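---
title: "Methods: scoring and deriving a paediatric T-cell-infiltration signature"
author: "ipass package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and deriving a paediatric T-cell-infiltration signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipass)
```

## The problem and the score

Most expression-based tools for reading the tumour immune microenvironment
out of bulk RNA-seq were trained on adult cancers. Paediatric high-risk
tumours carry far fewer mutations, express little PD-L1, and their immune
infiltrates are sparse enough that deconvolution algorithms struggle to
resolve individual cell types. The Immune Paediatric Signature Score
(IPASS) takes a different route: it anchors a transcriptional score to a
pathologist's ground truth, the immunohistochemistry (IHC) classification
of CD4/CD8 staining into *hot* (widespread intratumoural T-cells),
*altered* (moderate or peripherally restricted T-cells) and *cold* (few or
absent T-cells).

For a sample with TPM values $x_g$ over the signature genes $G$
(|G| = 15), the raw score is

$$ S_\text{raw} = \frac{1}{|G|} \sum_{g \in G} \log_2(x_g + 1), $$

which is min–max normalised onto $[-1, 1]$ using cohort extremes
$(m, M)$:

$$ S_\text{norm} = 2\,\frac{S_\text{raw} - m}{M - m} - 1. $$

A sample is called **T-cell infiltrated** when $S_\text{norm} \ge -0.25$
(boundary inclusive), which under the shipped calibration corresponds to a
raw threshold of $0.83$; otherwise it is called **cold**.

Two readings of "average sum of log-transformed TPM" are possible (mean
or sum). The package implements the arithmetic mean of
$\log_2(\mathrm{TPM}+1)$: a 15-gene *sum* would live on a scale where a
raw threshold of 0.83 is unreachable for any realistically expressed
immune gene set, so the mean is the only self-consistent reading. Base 2
with pseudocount 1 is the transcriptomics convention; both are recorded in
the `ScoreCalibration` object so a score is always reproducible from one
artefact, and both are configurable.

### The shipped signature and calibration are surrogates

The cohort behind the published signature is controlled-access, so two
components of the shipped default cannot be exact:

* The calibration extremes (`rawMin` 0.2, `rawMax` 1.88) are chosen to
  reproduce the published threshold pair exactly
  ($-0.25 \leftrightarrow 0.83$); they are **not** the original cohort's
  extremes. Any pair $(m, M)$ with $2(0.83-m)/(M-m)-1 = -0.25$ would do;
  this one keeps the raw range inside values typical of mean
  log2(TPM+1) immune-gene expression.
* Fourteen of the fifteen member genes are publicly documented by symbol
  (NFATC3, TNFRSF18, NFKB1, CD27, CTLA4, FPR2, SERPING1, CXCL9, CXCL11,
  LAMP3, THBD, SBNO2, CD276, LIF). The fifteenth slot is filled with
  CXCL10 — an interferon-γ-inducible chemokine sibling of CXCL9/CXCL11 —
  as a clearly flagged surrogate. Users holding the definitive list
  should serialise their own instance with `writeSignature()`.

Nothing in the package's tests or reported numbers depends on the
surrogate choices: threshold consistency is a property of the calibration
arithmetic, and derivation-based results use synthetic cohorts with known
planted truth.

## Gene identifiers

Immune genes are habitually referred to by protein names (GITR for
TNFRSF18, CD141/BDCA-3 for THBD, B7-H3 for CD276, DC-LAMP for LAMP3,
C1-inhibitor for SERPING1, ...). All readers canonicalise symbols through
an alias table (`defaultAliasMap()`, editable TSV under `extdata`);
canonicalisation is idempotent by construction and a collision after
canonicalisation (e.g. a matrix containing both GITR and TNFRSF18 rows)
is an error rather than a silent merge.

## Deriving a signature

`deriveIPASS()` reproduces the derivation procedure as a pure function of
(matrix, annotations, parameters, seed):

1. **Label merge.** Hot and altered are pooled into one *inflamed* group —
   both contain T-cells, and the altered class contributes genes of
   immune exclusion alongside the hot class's activation markers.
   Indeterminate samples are dropped with a logged count.
2. **Panel filter.** The matrix is restricted to an immune gene panel
   (in the original design a 766-gene immune profiling panel; here a
   user-supplied list, since the exact membership is a configurable
   input).
3. **Stratified split.** Half the cohort trains, half tests, with class
   proportions preserved. The train set receives
   $\lfloor f N \rfloor$ samples (an odd cohort puts the extra sample in
   the test set); per-class counts are class floors topped up by largest
   remainder. For 69 samples (25 inflamed / 44 cold) at $f = 0.5$ this
   yields the 34/35 split with 12/13 inflamed and 22/22 cold.
4. **Forest training.** A random forest with Gini impurity is fitted on
   the training samples only. Hyperparameters follow the conventional
   defaults of the R randomForest implementation: 500 trees,
   $\sqrt{p}$ features per split, unlimited depth; all are configurable
   and echoed in the report. No hyperparameter tuning is performed — the
   selection statistic is Gini importance, which needs a fitted forest,
   not a tuned one; this is a deliberate simplification relative to
   tuning-framework-driven training, and it keeps the derivation
   deterministic given the seed.
5. **Extraction.** The top *k* genes (default 15) by mean decrease in
   Gini, ties broken lexicographically for reproducibility.
6. **Calibration and evaluation.** The signature scores every supplied
   sample; the min–max calibration is fitted on all of them (mirroring
   calibration on an entire cohort rather than the labelled subset —
   whether the original calibration preceded or followed test-set
   evaluation is not documented; calibrating on the full cohort is the
   reading most consistent with a cohort-wide score range, and
   `calibrateOn = "train"` is available). Test-set samples never
   influence training or importance computation, which the test suite
   verifies by corrupting test-sample expression and asserting an
   identical signature.

Class imbalance is handled by stratification only; no resampling or
class weights are applied, as none are part of the procedure being
modelled.

## Evaluation statistics

* Diagnostic metrics are the standard ratios of the 2×2 confusion matrix
  with *inflamed* as the positive class; a zero denominator yields `NA`
  plus an explicit flag, never a silent 0. `wholePercent()` rounds
  half-up, matching how such metrics are conventionally printed.
* Fisher's exact test (association between IHC class and score
  designation) uses the two-sided probability-mass convention (sum of
  hypergeometric probabilities ≤ the observed table's), i.e. R's
  `fisher.test` rule; the doubling rule would differ on asymmetric
  tables. The test suite checks it against full enumeration with explicit
  binomial coefficients for every table with margins ≤ 8.
* `twoGroupCompare()` implements the parametric-or-rank decision flow:
  Shapiro–Wilk on each group and an F-test for variance equality at
  α = 0.05; any rejection routes to the Wilcoxon rank-sum test, otherwise
  a pooled-variance t-test. (The flow is stated in the source procedure
  with an apparent negation typo — "used when normally distributed or
  equal variances were not observed" — and is implemented here as the
  standard flow: non-normality *or* unequal variance selects Wilcoxon.)
  Note the t-branch fires with probability $0.95^3 \approx 0.86$ under
  ideal Gaussian input, since three α = 0.05 gates must all pass.
* `clusterGenesVsScore()` implements "which immune-gene grouping tracks
  the score": per-gene z-scores of log2(TPM+1) are clustered with plain
  k-means (seeded initialisation, 10 restarts) and each cluster's mean
  Pearson correlation with the per-sample score is reported. The phrase
  "hierarchical K-means" conflates two algorithms; plain k-means is
  implemented and the hierarchical reading is deliberately not guessed.
  `k = `number of genes degenerates to singleton clusters (the identity
  partition) rather than an error, so the max-correlation "cluster" is
  then the single best-correlated gene.

## Biomarker rules

* **Neoantigens.** An epitope passes when mutant IC50 < 500 nM, wild-type
  IC50 > 500 nM and gene expression > 1 TPM — all three strict, matching
  the printed inequality directions. A mutation with any passing epitope
  counts once, regardless of how many epitopes or HLA contexts pass.
  Whether the expression filter is gene- or transcript-level is not
  specified upstream; gene-level TPM is implemented. HLA typing and
  binding prediction are upstream tools whose output table is consumed.
* **PD-L1.** IHC-positive means ≥ 1% of cells with *membranous* staining
  (cytoplasmic-only staining is negative and must not be counted into the
  input percentage). RNA-high uses a strict > 3 TPM cut, exposed as a
  parameter because it is descriptive, not a validated threshold.
* **Archetypes.** Each archetype score is the mean cohort z-score of
  log2(TPM+1) over the set's genes present in the matrix; a sample is
  assigned the argmax archetype, ties broken alphabetically and flagged.
  This follows the published scoring approach conceptually
  (cohort-standardised mean expression); exact parity with the external
  reference implementation is not claimed, and the 12 real gene sets are
  a user-supplied input — the file shipped under `extdata` is a synthetic
  format example. Cohort standardisation makes assignments invariant to
  global log-space shifts but means scores are only comparable within a
  cohort, and at least two samples are required.
* **TCR clonotypes.** Per-sample clone count, total reads and read
  proportions (which sum to 1 by construction); empty samples return
  zeros with an explicit flag.

## The synthetic cohort generator

`simulateCohort()` generates the study conditions every pipeline stage is
tested under, since the real cohorts cannot be redistributed. Per-gene
baselines are Normal(3, 1) on the log2 scale (median TPM ≈ 7, spanning
roughly 1–60 TPM within ±2 SD — typical of moderately expressed immune
genes); inflamed samples add a class effect on the planted informative
genes (hot +2.0 log2 units, altered +1.2, cold 0) plus Normal(0, 0.5)
observation noise; TPM is $2^{\ell} - 1$ floored at zero, so the −1
offset mirrors the scoring pseudocount and planted log2 effects translate
directly into score separation. Default class counts are 45 cold / 20
altered / 5 hot: a 70-sample labelled cohort with ~36% inflamed, matching
the proportions seen when high-risk paediatric tumours are read out by
CD8 IHC. The altered effect sits between hot and cold because that class
pools moderate and peripherally restricted infiltration.

What the generator does **not** emulate: tumour-type-specific expression
programmes, gene–gene correlation structure (genes are conditionally
independent), library-size or batch artefacts, and the compositional
nature of TPM. Passing recovery tests therefore demonstrates that the
pipeline is correct and sensitive at realistic effect sizes, not that it
would achieve the same accuracy on real tumours, where correlated
co-expression makes feature selection both easier (modules) and harder
(redundancy).

`simulateEpitopes()` plants an exactly known neoantigen count:
`round(passFraction * nMutations)` mutations receive at least one epitope
satisfying all three cut-offs, every other epitope violates at least one
(always the mutant-IC50 cut, sometimes also expression), so the filter's
output can be compared to ground truth without tolerance.

## Numerical choices and degenerate inputs

* Scores outside a frozen calibration's range (prospective samples) are
  clipped into $[-1, 1]$ with a warning rather than re-fitted, keeping
  classification stable for validation use. Inside the range,
  normalise∘invert round-trips to < 1e-12.
* A constant score vector cannot be calibrated (degenerate min–max) and
  errors; a constant group errors in `twoGroupCompare()`; an
  all-constant cohort errors in archetype scoring.
* The calibration validity check ties `rawThreshold` to `normThreshold`
  at 1e-9, so a hand-edited signature file with inconsistent thresholds
  is refused at load time.
* Importance ties are broken lexicographically; k-means determinism comes
  from a seeded initialisation with a fixed restart count.
* Percentages are rounded half-up (`floor(x * 100 + 0.5)`) to match how
  whole-percent metrics are conventionally reported.

## Problem sizes in the test suite

The suite exercises the full derivation at the cohort scale the method
targets: 70 labelled samples over a 766-gene panel with 15 planted
informative genes at a 1.5-log2-unit effect, repeated over 10 seeds
(recovery of ≥ 12/15 planted genes and held-out accuracy ≥ 0.85 in ≥ 8/10
seeds — at these conditions all 10 seeds pass with full recovery).
Class-conditional calibration of the generator itself is checked at 500
samples per class against a 3-standard-error band. Exact-test equivalence
is exhaustive for all 2×2 tables with margins ≤ 8 and a 10,000-row
brute-force scan for the neoantigen filter. These sizes were chosen as
the smallest that exercise each property at the study's own scale.

## Known limitations

* The shipped default signature/calibration are surrogates (above); exact
  reproduction of the published gene ranking would require the
  controlled-access cohorts.
* Derivation trains a single forest at fixed hyperparameters; no internal
  cross-validation or tuning.
* No survival or outcome modelling on score strata, no multiple-testing
  machinery (the downstream analyses consume unadjusted tests), and no
  upstream quantification — TPM in, scores out.
* The archetype scorer is a conceptual re-implementation; parity with the
  external reference scorer is explicitly not guaranteed.
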