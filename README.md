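# fgfr2axis

Integrated copy-number, promoter-methylation and splice-isoform expression
analysis of **FGFR2** and its splicing regulator **ESRP1** in gastric
cancer, as a tested, reusable R pipeline.

## The problem

*FGFR2* encodes two mutually exclusive isoforms — the epithelial IIIb and
the mesenchymal IIIc — whose balance is controlled by the splicing factor
ESRP1. In gastric tumours both genes are recurrently amplified and their
promoters predominantly demethylated; tumours carrying amplified *ESRP1*
with normal *FGFR2* copy number and FGFR2-IIIc expression above the level
of normal stomach (the ESRP1^amp^–FGFR2^norm^–FGFR2-IIIc^high^ axis) are of
particular clinical interest, because among diffuse-histotype tumours high
IIIc expression marks worse overall survival. The package is aimed at
cancer genomics analysts who want these calls, the integrated per-tumour
states, and the downstream association/survival layer as auditable,
reproducible functions.

## What it computes

* **Copy number** — per-gene calls from SEG-like segment-mean files
  (amplified above +0.1, deleted below −0.1, normal in between; overlapping
  segments must be concordant, otherwise the sample is flagged
  `discordant`), or from gene-level GISTIC integer tables (≥ 1 amplified,
  ≤ −1 deleted). A grid-scan `derive_segmean_cutoff()` derives the cutoff
  from normal-sample segment means.
* **Promoter methylation** — mean beta-value of promoter probes classified
  at ≤ 0.33 (demethylated) / ≥ 0.66 (methylated); paired tumour/normal RRBS
  methylated-CpG-count ratios classified at ≥ 1.5 (hyper) / ≤ 0.66 (hypo).
* **Isoform expression** — FGFR2-IIIb via exon 8 of NM_022970, FGFR2-IIIc
  via exon 6 of NM_001144916 (RPKM), total FGFR2/ESRP1 FPKM; dichotomized
  against normal-sample medians; qRT-PCR 2^−ΔΔCt with T/N ratio categories
  (≥ 1.50 up, < 0.67 down).
* **Integration** — per-tumour state join across modalities with the axis
  flag (`ESRP1` amplified ∧ `FGFR2` normal ∧ IIIc above) and state
  frequency tables.
* **Association & survival** — chi-square (Yates for 2×2) contingency
  tests, Wilcoxon rank-sum, Student's t, Kaplan–Meier curves and log-rank
  tests.
* **Synthetic cohorts** — `simulate_cohort()` writes a full paired
  multi-omic cohort (segment, GISTIC, beta matrix, RRBS counts, expression,
  clinical and latent-truth tables) at the observed study frequencies, so
  the entire pipeline runs and is testable offline.

## Worked example

```r
library(fgfr2axis)

# association layer on a printed cross-tabulation
tab <- matrix(c(28, 21, 24, 110, 4, 11), nrow = 3, byrow = TRUE,
              dimnames = list(c("diffuse", "intestinal", "mixed"),
                              c("above", "below")))
contingency_test(tab)
#> <Pearson chi-square> statistic = 27.25, df = 2, p = 1.21e-06

# synthetic cohort through the full pipeline
cfg <- sim_config(n_pairs = 20, n_unpaired_tumors = 200, seed = 42)
cohort <- simulate_cohort(cfg)
res <- run_pipeline(cohort, thresholds = config_normal_medians(cfg))
head(res$states[, c("sample_id", "fgfr2_cn", "esrp1_cn", "iiic_cat", "axis_flag")], 4)
#>   sample_id fgfr2_cn esrp1_cn iiic_cat axis_flag
#> 1     N0001   normal   normal    above     FALSE
#> 2     N0002   normal   normal    above     FALSE
#> 3     N0003   normal   normal    above     FALSE
#> 4     N0004   normal   normal    below     FALSE

head(state_frequencies(res$states, c("fgfr2_cn", "esrp1_cn")), 4)
#>    fgfr2_cn  esrp1_cn count  proportion
#> 1 amplified amplified    21 0.087500000
#> 2 amplified   deleted     1 0.004166667
#> 3 amplified    normal    12 0.050000000
#> 4   deleted amplified    25 0.104166667

recover_truth(cohort, cn_calls = res$cn_calls)$cn$accuracy
#> [1] 1
res$survival   # log-rank: diffuse tumours split by IIIc category
#> <log-rank> statistic = 0.4188, df = 1, p = 0.518
```

The chi-square p-value of 1.21×10⁻⁶ is the diffuse-versus-intestinal
enrichment of IIIc-high tumours; the state-frequency table shows the joint
copy-number landscape of the simulated cohort (proportions over complete
samples); recovery accuracy 1 means every latent copy-number state was
called back correctly from the written segment file; the log-rank line
tests the survival contrast between IIIc-above and IIIc-below diffuse
tumours in this (small) simulated cohort.

## Documentation

The methods vignette (`vignettes/fgfr2-esrp1-pipeline.Rmd`) describes the
classification rules and their boundary conventions, the integration and
statistics layer, the generative model of the synthetic cohorts, and the
limits of what synthetic testing demonstrates.
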