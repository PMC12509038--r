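# gutbraintools

Statistical pipeline for preclinical **gut–brain axis** studies built on the
dextran sulfate sodium (DSS) colitis mouse model. Colonic inflammation in
this model is tracked with a composite disease activity index, and its
central consequences are probed through circadian clock-gene expression,
gadolinium tracer transport through CSF/glymphatic routes, evoked
neurotransmitter release from isolated nerve terminals, and CSF proteomics.
`gutbraintools` implements the quantitative analysis behind each of those
readouts, plus the statistical toolbox tying them together, with seeded
synthetic-data generators so everything is testable without animal data.

## What it computes

* **Disease activity index (DAI)** — daily rubric scoring of weight loss,
  stool consistency and bleeding;
  `DAI = (weight loss score + stool score + bleeding score) / 3`.
* **Cosinor rhythmometry** — phase/period estimation of clock-gene
  2^−ΔΔCt series by exhaustive least-squares scan, then the
  trend + amplitude linear model
  `y = β₀ + β₁(t − t̄) + β₂ cos(2π(t − φ)/P) + ε`
  per gene and condition, with circular phase-divergence summaries between
  conditions.
* **Tracer kinetics** — percentage signal enhancement `SE = (S/S_b)·100`
  per ROI against non-injected baselines, repeated-measures
  condition × time mixed-effects ANOVA (random intercept per animal,
  Satterthwaite F) with Bonferroni per-time post hocs, and
  condition × hemisphere ANOVA of lateral-ventricle volumes.
* **Evoked overflow** — fractional release percentages from four-fraction
  superfusion runs; overflow = (f2 + f3) − (f1 + f4), optionally as a
  percentage over basal release; Student-t condition comparisons.
* **CSF proteomics** — peptide-concentration normalization,
  quantification filtering, per-protein t tests on log2 intensities with
  Benjamini–Hochberg FDR, the strict |log2FC| > 1 & adjusted p < 0.05
  significance filter, volcano tables, and offline Fisher exact gene-set
  enrichment (GMT input).
* **Statistics toolbox** — normality-gated Student/Welch/Mann–Whitney
  tests, η² = t²/(t² + df) effect sizes, Bonferroni and BH adjustments,
  and exact noncentral-t **sensitivity power analysis** (minimal
  detectable Cohen's d).

## Worked example

Simulate a DSS vs control cohort, score it, and compare evoked release:

```r
library(gutbraintools)

obs <- gen_dai_observations(seed = 42)        # 8 animals/condition, 8 days
rec <- dai_timecourse(obs)
tail(dai_group_summary(rec), 4)
#>    condition day n mean_dai   sem_dai
#> 10       DSS   4 8 1.625000 0.3299681
#> 12       DSS   5 8 1.916667 0.2159328
#> 14       DSS   6 8 2.166667 0.1889822
#> 16       DSS   7 8 2.333333 0.2519763
```

DSS animals climb to a mean DAI above 2 by the end of exposure (controls
stay near 0). Release assays: each run's overflow is the stimulated-fraction
excess over basal, here generated with a 3% (CTR) vs 1.5% (DSS) evoked
increment — so expected overflows of 6% and 3%:

```r
runs <- gen_superfusion_runs(seed = 42)
compare_release(runs[runs$condition == "CTR", ],
                runs[runs$condition == "DSS", ])
#> Two-sample test (student)
#>   statistic = 14.52, df = 10, p = 4.79e-08
#>   mean difference 3.642, 95% CI [3.083, 4.201]
#>   eta-squared = 0.9547
```

Tracer kinetics with a repeated-measures mixed-model ANOVA per ROI:

```r
tc <- gen_tracer_timecourses(seed = 42)
se <- build_se_table(tc$scans, baseline_reference(tc$baselines))
rm_anova_condition_time(se, roi = "amygdala")$effects
#>        effect        F df1      df2            p
#> 1   condition 284.6351   1 10.01902 1.097876e-08
#> 2        time 101.8229   9 83.02063 4.949956e-41
#> 3 interaction  10.4689   9 83.02063 1.193091e-10
```

The minimal detectable effect size for a 10-vs-15 behavioral comparison at
α = 0.05 (two-tailed) and power 0.95:

```r
sensitivity_cohen_d(10, 15)
#> [1] 1.537566
```

An end-to-end run of all five stages from one seed, with checksummed
outputs:

```r
run_pipeline(out_dir = "demo_out", seed = 1)
```

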