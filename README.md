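# ipass

Scoring and derivation of the **Immune Paediatric Signature Score
(IPASS)** — a 15-gene bulk-RNA-seq signature that classifies high-risk
paediatric tumours as **T-cell infiltrated** or **immune cold**, anchored
to pathologist CD4/CD8 immunohistochemistry (IHC) rather than to
adult-cancer deconvolution references.

For a sample with TPM values *x<sub>g</sub>* over the signature genes *G*
(|*G*| = 15):

- raw score: `S_raw = mean over G of log2(x_g + 1)`
- normalised score: `S_norm = 2 * (S_raw - m) / (M - m) - 1`, with cohort
  extremes `(m, M)` frozen in a `ScoreCalibration`
- classification: **T-cell infiltrated** iff `S_norm >= -0.25`
  (equivalently `S_raw >= 0.83` under the shipped calibration).

The package is aimed at computational immuno-oncology: it provides
single-sample scoring against a frozen calibration, derivation of new
signatures from IHC-labelled cohorts (random-forest Gini importance over
an immune gene panel), diagnostic metrics and the accompanying
statistical decision flow, ancillary biomarker rules (neoantigen IC50
filtering, PD-L1 IHC/RNA concordance, immune-archetype assignment, TCR
clonotype summaries), and a seeded synthetic cohort generator so the
entire pipeline is testable without controlled-access patient data. The
methods vignette (`vignettes/ipass-methods.Rmd`) documents every design
decision, including why the shipped signature instance and calibration
extremes are surrogates.

## Worked example

Simulate an IHC-labelled cohort with 15 planted informative genes, derive
a signature, and score the cohort:

```r
library(ipass)

coh    <- simulateCohort(seed = 42)                  # 45 cold / 20 altered / 5 hot
report <- deriveIPASS(coh, panel = S4Vectors::metadata(coh)$panel, seed = 42)
report
#> DerivationReport: 15-gene signature from 35 train / 35 test samples
#> GeneSignature 'derived' with 15 genes
#>   genes: GENE0321, GENE0561, GENE0356, GENE0024, GENE0601, GENE0634, GENE0622, GENE0049 ...
#>   rank scores: 0.6237 .. 0.1684
#> ScoreCalibration
#>   raw range     : [2.222, 4.76]
#>   threshold     : -0.25 (normalised) / 3.174 (raw)
#>   log transform : log2(TPM + 1)
#>   test metrics  : accuracy 1.000, sensitivity 1.000, specificity 1.000

res <- scoreSamples(coh, derivedSignature(report), calibration(report))
head(res, 3)
#>   sample_id raw_score norm_score label
#> 1      S001  2.709175 -0.6163294  cold
#> 2      S002  2.460672 -0.8121516  cold
#> 3      S003  2.306418 -0.9337046  cold
table(res$label)
#>               cold t_cell_infiltrated
#>                 45                 25
```

The report's signature recovers 14 of the 15 planted informative genes at
this seed and classifies the held-out test half perfectly: the planted
hot/altered effects (+2.0 / +1.2 log2 units) are comfortably above the
0.5-SD observation noise. The normalised scores run from −1 (cohort
minimum) to +1 (maximum); every inflamed sample sits at or above the
−0.25 threshold.

Scoring a new matrix against the shipped default instance:

```r
m <- matrix(1, nrow = 15, ncol = 1,
            dimnames = list(signatureGenes(ipassSignature()), "sample1"))
scoreSamples(m, ipassSignature(), ipassCalibration())
#>   sample_id raw_score norm_score  label
#> 1   sample1         1 -0.047619 t_cell_infiltrated
```

A thin command-line front end (`inst/cli/ipass`) exposes `simulate`,
`derive`, `score`, `evaluate`, `archetype` and `neoantigen-filter`
subcommands over the same functions; stochastic commands require an
explicit `--seed`.

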