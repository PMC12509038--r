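---
title: "Statistical methods for DSS-colitis gut-brain studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for DSS-colitis gut-brain studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutbraintools)
```

## Scope

`gutbraintools` packages the quantitative backbone of a preclinical
gut-brain-axis study built on the dextran sulfate sodium (DSS) colitis mouse
model: disease-activity scoring, circadian rhythmometry of clock-gene
expression, gadolinium tracer kinetics as a probe of glymphatic/CSF
transport, KCl-evoked neurotransmitter overflow from superfused synaptosomes
and gliosomes, label-free CSF proteomics, and the surrounding statistical
toolbox (normality-gated two-sample tests, eta-squared effect sizes,
multiplicity adjustments, and noncentral-t sensitivity power analysis).
Every stage consumes already-quantified tabular data; image processing,
spectral fitting and raw mass-spectrum processing are out of scope. Seeded
generators emulate each input structure so the whole pipeline can be
exercised and tested without animal data.

## Disease activity index

The DAI is the mean of three rubric scores assessed daily: weight loss
(0: none; 1: (0,5]%; 2: (5,10]%; 3: (10,20]%; 4: >20%), stool consistency
(0: normal; 2: loose; 4: diarrhea) and fecal bleeding (0: none;
1: hemoccult positive; 2: hemoccult plus visible pellet blood; 4: gross
bleeding). The weight-loss bin edges are conventionally printed with
overlapping endpoints ("1%-5%", "5%-10%"); we resolve them as half-open
intervals $(a, b]$ so every percentage maps to exactly one score — a
percentage of exactly 5% scores 1, not 2. Weight loss is referenced to each
animal's first recorded day, and weight gain scores 0. Each day is scored on
its own weight-loss percentage (not the running maximum), which is the
natural reading of a daily composite index.

## Cosinor rhythmometry

Clock-gene expression is measured as $2^{-\Delta\Delta Ct}$ at zeitgeber
times ZT 0, 4, 8, 12, 16, 20 with about three animals per time. For one gene
and condition we model

$$y_i = \beta_0 + \beta_1\,(t_i - \bar t) + \beta_2 \cos\!\big(2\pi (t_i - \phi)/P\big) + \varepsilon_i,$$

an ordinary least-squares fit with a centered linear trend and a cosine of
acrophase $\phi$ and period $P$. $(\phi, P)$ are chosen by exhaustive
least-squares scan over a grid (default $P \in [20, 28]$ h in 0.5 h steps,
$\phi$ in 0.25 h steps), minimizing the residual sum of squares of the
three-parameter fit at each grid point. Ties are broken toward the period
closest to 24 h, then the smallest phase. We deliberately do not
re-implement a multi-method rhythm detector (JTK-style rank tests,
Lomb-Scargle, autoregressive spectral estimation): the downstream linear
model only needs a phase and period, and the grid scan is transparent and
directly checkable against a brute-force oracle. Consequently the package
reports no rhythmicity p-values; that is a stated non-goal.

Numerical choices worth knowing:

* The cosine regressor is sign-ambiguous across half a period
  ($\cos(2\pi(t-\phi)/P) = -\cos(2\pi(t-\phi-P/2)/P)$), so the scan
  normalizes to the acrophase: the reported phase always carries a
  non-negative amplitude coefficient and lies in $[0, P)$.
* Replicates enter as independent rows; no pre-averaging across animals.
* A constant series is flagged arrhythmic instead of being assigned an
  arbitrary phase.
* Condition divergence is summarized as the circular phase difference in
  $(-P/2, P/2]$, the amplitude ratio $|\beta_2^{(b)}|/|\beta_2^{(a)}|$, and
  the mesor ratio. A zero reference amplitude flags the ratio as undefined.

At the study's sampling scale (6 times $\times$ 3 replicates, Gaussian
noise at 20% of the amplitude), the test suite verifies a median absolute
phase error of at most 1.5 h over 200 simulations; noiseless recovery is
exact to the grid resolution.

## Tracer signal-enhancement kinetics

Post-injection mean ROI intensity $S$ is expressed against the mean
intensity $S_b$ of the same ROI in non-injected baseline animals:
$\mathrm{SE} = (S/S_b) \times 100$. Baseline animals are pooled across
conditions into one $S_b$ per ROI by default — the study design (three
control and one DSS baseline animals) cannot support per-condition
baselines, though a per-condition mode exists. Rows are emitted only for
acquired samples; missing scans are never imputed.

Condition effects per ROI are tested with a repeated-measures two-way
mixed-effects ANOVA: `se_pct ~ condition * time + (1 | animal)` fit by REML
(lme4), with Satterthwaite-approximated F tests (lmerTest) and type-III sums
of squares under sum contrasts. The per-animal random intercept is the
standard minimal formulation that uses all available rows under missingness.
On complete balanced data this reproduces the classical repeated-measures
F tests, which the test suite asserts against an explicit sums-of-squares
oracle to 1e-6. Post hoc per-time condition contrasts (emmeans) are
Bonferroni-multiplied by the number of time points — the contrast family is
the set of time points within one ROI. Lateral-ventricle volumes are
analyzed per hemisphere with a fixed-effects condition $\times$ hemisphere
two-way ANOVA and Bonferroni per-hemisphere contrasts.

## Superfusion evoked overflow

Four sequential 3-minute superfusate fractions are collected around a 90 s
KCl pulse; fractions 2-3 contain the stimulated release. Each fraction is
expressed as a percentage of total radioactivity (four fractions plus the
particles remaining on the filter), making runs comparable regardless of
loading. The evoked overflow is
$(\mathrm{pct}_2 + \mathrm{pct}_3) - (\mathrm{pct}_1 + \mathrm{pct}_4)$;
negative overflow is reported, not clipped, because reduced exocytosis is a
meaningful outcome. The "overflow over basal" ratio divides by the summed
flanking basal fractions ($\mathrm{pct}_1 + \mathrm{pct}_4$); the
denominator convention is not fixed by the assay description, so the
mean-basal alternative (exactly twice the ratio) is available behind a
flag. Conditions are compared by a direct two-tailed unpaired Student t test
on the per-run measure, matching standard practice for these assays.

## CSF proteomics

The pipeline starts at the proteins $\times$ samples intensity matrix
(default cohort structure 8 treated vs 8 control). Stages:

1. **Normalization** — intensities are divided by each sample's measured
   peptide concentration and rescaled by the mean concentration, preserving
   the overall scale. Missing stays missing.
2. **Quantification filter** — a protein is "quantified" when it has at
   least `min_per_group` (default 2) non-missing values in *each* group.
   The identified/quantified distinction is reported but the underlying
   criterion is a package default, exposed as an argument.
3. **Differential test** — per protein, log2 fold change is the difference
   of group means of log2 intensities over available values, with a
   two-sided two-sample Student t test (Welch optional). No moderated
   (empirical-Bayes) variance model is used: the choice is a plain t test,
   kept deliberately simple and oracle-checkable. No imputation; per-protein
   group sizes are recorded. Benjamini-Hochberg FDR is applied across all
   tested proteins.
4. **Significance filter** — strictly $|\log_2 FC| > 1$ *and* adjusted
   $p < 0.05$; a protein at exactly 1.0 is excluded.
5. **Enrichment** — offline one-sided Fisher exact tests of the significant
   set against user-supplied gene sets (GMT), BH-adjusted across terms,
   with the sample odds ratio of the 2x2 table. Hosted-database "combined
   scores" (rank-permutation z-scores) are not reproduced; they require the
   hosting service's precomputed rank distributions.

On the default generator the suite verifies ≥80% recovery of spiked
proteins with true $|\log_2 FC| \ge 2$ and an empirical FDR ≤ 0.10 among
calls, pooled over 50 seeds.

## Statistics toolbox

Two-sample comparisons follow the study's menu: a Shapiro-Wilk (or
Lilliefors-corrected Kolmogorov-Smirnov) normality gate at $\alpha = 0.05$
on each group; if either group rejects, Mann-Whitney, otherwise Student's t,
switching to Welch when the variance ratio exceeds 4. Mann-Whitney is exact
(enumeration) up to a combined n of 16 without ties and uses the
tie-corrected normal approximation beyond. Degenerate zero-variance inputs
follow explicit conventions (equal means: $p = 1$; different means:
unbounded statistic, flagged) instead of erroring mid-pipeline.

Effect sizes are $\eta^2 = t^2/(t^2 + \mathrm{df})$, valid for both Student
and Welch (fractional df) statistics. The sensitivity power analysis solves
for the smallest Cohen's $d$ such that a two-sample t test with
noncentrality $\delta = d\sqrt{n_1 n_2/(n_1+n_2)}$ and
$\mathrm{df} = n_1 + n_2 - 2$ attains the target power, by root-finding on
the exact noncentral t distribution (both rejection tails included for the
two-tailed test; bisection tolerance well below 1e-8 in power).
$\alpha = 0.05$ (two-tailed) and power 0.95 are the package defaults for
this computation; they are consistent with all four published minimal
detectable d values for the behavioral cohorts (1.54, 1.56, 1.59, 1.66 for
group sizes (10,15), (10,14), (10,13), (10,11)), which the acceptance
checks recompute.

```{r sensitivity}
sapply(c(15, 14, 13, 11), function(n2) round(sensitivity_cohen_d(10, n2), 2))
```

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated:

* **Clock series** — cosinor mean structure with additive Gaussian noise,
  truncated at zero because relative expression cannot be negative. The
  truncation introduces a small positive bias when `noise_sd` is large
  relative to the mesor; at the defaults the bias is negligible, and the
  closed-form-mean tests use configurations where it vanishes.
* **Tracer time courses** — signal $S_b (1 + E\,g(t))(1 + \delta)$ with a
  gamma-variate uptake/washout curve $g$ normalized to unit peak (default
  peak at 30 min inside the 25-79 min window, ten acquisitions every
  6 min), multiplicative Gaussian noise (CV), and per-animal-time dropout.
  Any unimodal response would serve; the shape parameters are exposed.
* **Superfusion runs** — basal fraction percentages with the evoked
  increment added to fractions 2-3 and Gaussian noise per fraction; the
  expected overflow is exactly twice the increment, which the tests use.
* **Proteome** — log-normal intensities, protein-level abundance spread,
  spiked true fold changes with $|\log_2 FC|$ drawn in [1.2, 3], per-sample
  peptide-concentration factors, missing completely at random (default 5%).
* **DAI observations** — deterministic per-condition daily weight drift
  plus measurement noise, and categorical stool/bleeding draws.

The defaults mirror the study's sampling scales (6 zeitgeber times x 3
replicates; ten tracer time points; 8 vs 8 proteome). Noise magnitudes are
not reported for any assay, so the defaults are chosen at magnitudes a
practitioner would call realistic for each readout (qPCR scatter at 10-20%
of mesor, MRI intensity CV of 5%, fraction noise well below the evoked
increment, 0.4 log2-units of proteomic scatter); stage-level significance
patterns under these defaults resemble the published ones. What the
generators do **not** emulate: informative (intensity-dependent)
missingness, between-batch effects, autocorrelated within-animal noise,
heavy-tailed outliers, or compositional constraints. Green tests therefore
demonstrate correctness of the computations and calibration under the
stated models, not robustness to every pathology of real data.

All generators are deterministic given a seed, derive per-generator
sub-streams from the global seed, and restore the caller's RNG state.

## Pipeline reproducibility

`run_pipeline()` executes any subset of the five stages from one config
(list or YAML) and one seed, writing tidy CSVs, a JSON sidecar per stage
recording config and seed, and an md5 checksum manifest. Identical config
and seed reproduce identical checksums; this is asserted in the tests. The
test suite and the demonstration configs use reduced problem sizes (tens of
proteins, three to five animals) chosen to keep the full suite comfortably
fast while still exercising every code path; the calibration checks use the
sizes stated above (1000 mixed-model null simulations, 10,000 t-test nulls,
50 proteome seeds, 200 cosinor recoveries).

## Known limitations

* The phase/period grid scan inherits grid-resolution quantization; phases
  are identifiable only up to the period, and near-arrhythmic series yield
  unstable phases (flagged when the series is exactly constant, but a
  near-flat noisy series still returns its least-squares phase).
* The mixed-model ANOVA assumes a single random intercept per animal;
  within-animal serial correlation beyond that (e.g. AR(1) over scan times)
  is not modeled.
* The proteomics t test does not share variance information across
  proteins; with very small per-group counts a moderated test would be more
  powerful.
* Enrichment assumes the user-supplied gene sets and universe use matching
  identifiers; no identifier mapping is attempted.
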