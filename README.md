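# flemark

Multimodal neurocognitive markers of frontal lobe epilepsy (FLE).

Frontal lobe epilepsy damages motor-related brain networks, and embodied
language theory predicts a very specific behavioral signature: a selective
deficit in understanding *action verbs* in naturalistic discourse, sparing
other text comprehension. `flemark` implements, as a reusable and fully
tested R pipeline, the analysis that links that behavioral signature to its
structural and functional substrates and asks whether the combined markers
identify individual patients:

- **wSDM connectivity** — a from-scratch implementation of the weighted
  Symbolic Dependence Metric for resting-state functional connectivity:
  `wSDM(x, y) = sw(X̂, Ŷ) · Φ²(x, y)`, the product of Hoeffding's
  phi-square (the normalized squared L² distance between the empirical
  copula of the two series and the independence copula, `Φ² = 90·∬(C −
  uv)² du dv`, estimated on the rank grid) and a symbolic weight (one minus
  the normalized Hamming distance between the series' increase/decrease
  symbol strings). The metric is rank-invariant, captures nonlinear
  dependence that Pearson's r misses, and is sensitive to the sign of
  coupling.
- **Behavioral scoring** of 20-item text-comprehension questionnaires
  (verb-related vs circumstantial items) and the mixed-design
  Group × Information ANOVA with MoCA/IFS covariates, Tukey HSD post-hocs,
  partial η² and Cohen's d.
- **Tract FA comparisons** over the 10 JHU white-matter tracts: one-tailed
  Welch t tests with BH-FDR, plus max-statistic permutation FWE control.
- **Brain–behavior correlation screen** — per group, Pearson correlations
  of the four condition scores with tract FA and network-level wSDM
  summaries, Shapiro–Wilk checks, BH-FDR within configurable families.
- **Classification** — Bayesian-tuned (Gaussian-process + expected
  improvement) XGBoost on 17 multimodal features with stratified 80/20
  splits, ROC/AUC/confusion reporting, gain-based feature importance, and
  ablation analyses (neuro-only and cognitive-extended feature sets).
- **Synthetic cohorts** — a generator that plants the study's effect
  structure (19/19/20 groups, FLE-selective AT-verb deficit d = 0.9,
  bilateral-ATR FA reduction d = 0.8, M1–left-parietal hypoconnectivity,
  within-FLE neuro-behavior correlation ρ = 0.75) through a single latent
  integrity factor, so the whole pipeline is testable without patient data.

## Worked example

```r
library(flemark)
cfg <- run_config(cohort = cohort_config(), master_seed = 1,
                  n_perm = 1000, n_bayes_iter = 10)
res <- run_all(cfg)
res
#> flemark pipeline run (outputs in /tmp/.../demo)
#>   AT Group x Information (adjusted): F(2,55) = 12.19, p = 0.0000
#>   ATR FA (CTL vs FLE): t = 2.50, FDR p = 0.0859, d = 0.81
#>   M1 map peak (CTL vs FLE): ParOp-L, t = 4.58, FDR p = 0.0004
#>   FLE-vs-CTL: mean accuracy 0.875, mean AUC 0.969 (1 seed(s))
#>   PCE-vs-CTL: mean accuracy 0.500, mean AUC 0.250 (1 seed(s))
#>   FLE-vs-PCE: mean accuracy 0.875, mean AUC 0.750 (1 seed(s))
```

Reading the output: the synthetic FLE group shows the planted
Group × Information interaction (action-verb scores selectively lower,
F(2,55) = 12.19 after covariate adjustment), a reduced ATR fractional
anisotropy (d = 0.81, near the planted 0.8; on this draw it misses the
10-tract FDR threshold — expected at these sample sizes), and
hypoconnectivity between the M1 seeds and the left parietal operculum
(the planted peak target, FDR p < 0.001). The classifiers separate FLE
from both controls and PCE patients while the null PCE-vs-CTL contrast
stays at chance. The correlation screen ranks the two planted couplings
first:

```r
head(as.data.frame(res$screen), 2)
#>   group condition modality measure         r            p        p_fdr
#> 1   FLE      AT-V     rsFC      MN 0.8462919 4.950131e-06 5.940157e-05
#> 2   FLE      AT-V       FA     ATR 0.7424242 2.723257e-04 1.089303e-02
```

Single-seed classification numbers are split-lottery noisy at n ≈ 39 per
task; pass several `ml_seeds` to `run_config()` to see multi-seed means.

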