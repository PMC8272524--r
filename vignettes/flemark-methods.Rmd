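---
title: "Multimodal markers of frontal lobe epilepsy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal markers of frontal lobe epilepsy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flemark)
```

## The scientific problem

Frontal lobe epilepsy (FLE) damages motor-related cortical networks. A body
of embodied-cognition work predicts that such damage should produce a
*selective* deficit in understanding action language — verbs describing
bodily movement — while leaving other discourse comprehension intact.
`flemark` implements a complete analysis pipeline for testing that
hypothesis with multimodal data: naturalistic text-comprehension scores,
white-matter integrity (fractional anisotropy, FA, from diffusion imaging),
resting-state functional connectivity (rsFC), their cross-modal
correlations, and a machine-learning stage that asks whether these markers
identify individual patients.

Three groups are contrasted throughout: FLE patients, healthy controls
(CTL), and a posterior-cortex-epilepsy group (PCE) that serves as a
lesion-location control — posterior damage should *not* produce action-verb
deficits, so every FLE-selective finding is expected to be null in PCE.

## The connectivity statistic: weighted Symbolic Dependence Metric

The core estimator is the weighted Symbolic Dependence Metric (wSDM)
between two time series $x, y$:

$$\mathrm{wSDM}(x,y) \;=\; sw(\hat X, \hat Y)\cdot I(x,y),$$

a product of two rank/shape-based factors.

**Copula factor.** By Sklar's theorem the joint distribution of $(x,y)$
factors into its marginals and a copula $C$ on the unit square; $x$ and $y$
are independent iff $C$ equals the product copula $\Pi(u,v)=uv$. The
normalized squared $L^2$ distance between $C$ and $\Pi$ is Hoeffding's
phi-square,

$$\Phi^2 = h_2 \int\!\!\int_{[0,1]^2} \left(C(u,v)-uv\right)^2\,du\,dv,
\qquad h_2 = 90,$$

which is 0 under independence and 1 under perfect monotone dependence of
either sign. The constant $h_2$ is the inverse of the comonotone integral
$\int\!\!\int(\min(u,v)-uv)^2 = 1/90$; the package exports it as `H2` and
the test suite re-derives it by independent quadrature. The empirical
estimator evaluates the empirical copula (a step function of the
pseudo-observations, i.e. tie-averaged ranks over $n$) on the $n \times n$
grid:

$$\hat\Phi^2 = \frac{90}{n^2}\sum_{i=1}^n\sum_{j=1}^n
\left[\hat C\!\left(\tfrac{i}{n},\tfrac{j}{n}\right)-
\tfrac{i}{n}\tfrac{j}{n}\right]^2 .$$

This grid double-sum is the package's reference definition, computed
exactly (in compiled code) via a two-dimensional cumulative count; the unit
tests compare it against a literal brute-force double loop at $n \le 50$ to
$10^{-10}$. Because it uses only ranks, the estimator is *exactly*
invariant under strictly increasing marginal transforms, and it inherits a
positive $O(1/n)$ bias under independence (empirically $\approx 2.5/n$) and
a matching $O(1/n)$ overshoot above 1 in the comonotone limit — which is
why the self-dependence convention for connectivity-matrix diagonals is the
exact value 1.

**Symbolic factor.** Each series is reduced to its increase/decrease
symbol string ($n-1$ binary symbols; a tie, i.e. no change, codes as
"decrease" — the choice is arbitrary but fixed, and any fixed rule
preserves determinism). The symbolic weight $sw$ is one minus the
normalized Hamming distance between the two strings: 1 for identical local
shape, 0 for opposite shape. Multiplying $\hat\Phi^2$ by $sw$ makes the
metric sensitive to the *sign* of coupling: perfectly anticorrelated series
have $\hat\Phi^2\approx 1$ but $sw = 0$, hence wSDM 0.

Two design points were genuinely open. First, the dependence factor
$I(x,y)$ could be read as $\Phi^2$ or its square root; the package defaults
to $\Phi^2$ (the quantity the closed-form estimator actually produces) and
exposes `factor = "phi"` as a switch. Second, the symbol alphabet could use
$m$-length ordinal motifs; single increase/decrease differences are used
because no motif length is specified anywhere, and the binary alphabet is
the minimal choice consistent with "increase and decrease".

## Behavioral scoring and the mixed-design ANOVA

Each of four audio texts (two action texts, AT; two neutral texts, NT)
comes with a 20-item questionnaire: 10 verb-related and 10 circumstantial
items, one point per correct answer, zero for errors and "I don't
remember". Scores are summed over the two texts of each type, yielding four
condition scores in 0–20 (AT-V, AT-C, NT-V, NT-C).

Each text type is analyzed with a mixed-design (split-plot) ANOVA: Group
(FLE/CTL/PCE) between subjects, Information type (verb/circumstantial)
within subjects, the subject as the repeated unit, with and without MoCA
and IFS covariates entered as continuous between-subject regressors. The
package reports $F$, degrees of freedom, $p$, and partial
$\eta^2 = SS_\mathrm{eff}/(SS_\mathrm{eff}+SS_\mathrm{err})$ per effect,
Tukey HSD over the six cells (studentized range on the pooled within-cell
mean square, harmonic-mean cell size for unbalanced designs), and Cohen's
$d$ on the pooled SD. "Mixed effects models" admits a random-intercept
likelihood reading; the split-plot ANOVA was chosen because it reproduces
the $F(\mathrm{df}_1,\mathrm{df}_2)$ reporting style of the field and is
exactly calibrated under the null (verified at 500 replicates in the
acceptance suite). Note the reported within-subject df reflect summed
condition scores (one observation per subject per information type);
analyses that enter the two texts as separate repeated observations will
print larger df.

## Tract FA and seed-map group comparisons

Tract-level FA is the mean over elements labeled with each of the 10 JHU
atlas tracts. Group comparisons are Welch (unequal-variance) two-sample
t-tests — the variance assumption is unstated in the source protocol, and
Welch is the safer default — one-tailed in the hypothesized direction
(patients lower), BH-FDR corrected across the 10 tracts.

Voxelwise TFCE inference belongs to the original imaging toolchain and is
out of scope; the package instead controls family-wise error at
parcel/tract level with a max-statistic permutation test: each feature's
adjusted $p$ is the proportion of relabelings whose *maximum* |Welch t|
across features reaches the observed one. Random mode includes the
observed labeling (so $p \ge 1/(n_\mathrm{perm}+1)$); `exact = TRUE`
enumerates all labelings and is tested against an independent enumeration
oracle for 4-vs-4 designs.

Seed maps apply wSDM from each seed parcel to a fixed target set; the
motor (MN), multimodal-semantic (SemN) and visual (VN) networks are defined
as seed lists (symbolic parcel names — the original seed coordinates live
in supplementary material not reproduced here). Group map comparisons are
per-target Welch t with BH-FDR across the targets of one seed-set analysis,
reporting the peak target. Network summaries are subject-level means of a
network's seed maps, the quantities used by the correlation screen and as
classifier features.

## The correlation screen

Per group, the four condition scores are Pearson-correlated with the 10
tract FAs and the 3 network summaries (52 records per group, 156 total),
after Shapiro–Wilk normality checks (run per variable; the pooled-vs-per-
variable reading is ambiguous in the source, and per-variable is the
stricter, reported choice). BH-FDR is applied within a configurable family;
the default — per group per modality — matches how the findings are
reported (an FA correlation family and an rsFC correlation family within
each group). Pearson on raw integer scores (no jitter) is intentional:
the restricted range is a property of the instrument.

## Classification

Features are the 17 standard columns (4 behavioral + 10 FA + 3 network
summaries), extendable by 10 cognitive subtest scores (5 MoCA-like, 5
IFS-like). Three pairwise tasks are run: FLE-vs-CTL, PCE-vs-CTL,
FLE-vs-PCE, the patient group being the positive class. The split is
80/20; it is stratified by class — a deliberate tightening of plain random
division, since at ~39 subjects per task an unstratified draw can produce a
single-class test set. Features are standardized with training-set
statistics only, and `evaluate()` refuses any train/test subject overlap.

The classifier is XGBoost tuned by Bayesian optimization of the mean
k-fold (default $k=5$, stratified) cross-validated AUC: a Latin-hypercube
warm-up followed by a squared-exponential Gaussian-process surrogate with
expected-improvement acquisition, over learning rate 0.01–0.3 (log), depth
2–6, rounds 50–500 (log), row/column subsampling 0.5–1, and L1/L2 weights
0–5. The GP-EI optimiser is implemented in the package (closed-form GP
posterior, fixed length-scale 0.3 on the unit cube, EI maximized over 256
random candidates per step); the default budget is 25 objective
evaluations. Reports carry accuracy, ROC AUC, sensitivity, specificity,
the confusion matrix, and gain-based feature importance. The ablation
suite reruns each task on identical splits with the neuro-only (13) and
extended (27) feature sets. Accuracies are reported as multi-seed means
with dispersion, since a single 80/20 split of ~39 subjects is dominated
by split luck.

## The synthetic cohort generator

No patient data ship with the package; every downstream stage is exercised
on synthetic cohorts whose *planted* effect structure mirrors the study's
findings. Defaults are the study conditions: groups of 19/19/20, series of
200 time points, an FLE AT-verb deficit of $d = 0.9$, an FLE ATR-FA
reduction of $d = 0.8$, a within-FLE neuro-behavior correlation
$\rho = 0.75$, and an M1-to-left-parietal coupling reduction of 0.15
variance share (a value chosen once, at design time, to give a realized
wSDM group effect of the same order as the reported peak effect,
$d \approx 0.9$–1.3).

The generative model is a single latent "integrity" factor
$f_i \sim N(0,1)$ per FLE subject that simultaneously (a) lowers AT-verb
scores, (b) lowers ATR FA, and (c) lowers M1–parietal coupling; CTL and
PCE draw from the null model, and NT scores and non-ATR tracts carry no
group effect anywhere. This single-factor structure is one of many joint
distributions consistent with the reported pairwise correlations; it is
the simplest one that induces all of them at once.

Two calibrations are solved analytically inside the generator (numeric
integration plus root-finding, not simulation): the FLE logit shift is
chosen so the planted behavioral difference equals `d_behavior` on the
pooled-SD scale despite the logistic link and the binomial noise of
20-item scores, and the latent loadings are chosen so the *observed*
ATR-FA x AT-verb correlation targets `rho_neuro_behavior` after binomial
attenuation (the score side of the correlation is capped near 0.9 by item
noise; when $\sqrt\rho$ exceeds that cap the FA side absorbs the
difference).

BOLD-like series are stationary AR(1) latent network signals
($\varphi = 0.3$, mimicking smooth resting-state autocorrelation — no
generative model is given in the source) mixed into parcels as variance
shares, plus a weak global signal (5%) and white parcel noise. Behavioral
items are Bernoulli draws with a logistic link, so condition totals are
integers in 0–20. Covariates (MoCA-like, IFS-like, and their ten subtests)
are drawn group-matched with no planted differences, mirroring the matched
neuropsychological profile; the subtests are deliberately uninformative so
the extended classifier's importance rankings can be checked against the
"negligible contribution" expectation.

What the generator does *not* emulate: raw MRI volumes and their
preprocessing, spatial structure within tracts, demographic confounding,
non-stationarity or physiological artifacts in BOLD signals, and
item-level difficulty structure in the questionnaires. Passing tests
therefore demonstrate that the *pipeline* is correct and calibrated — not
that real data would yield these effect sizes.

## Numerical choices and degenerate inputs

- Ties: tie-averaged ranks in pseudo-observations; difference ties code as
  "decrease" in symbolization; importance ties break by column order.
- Connectivity diagonals are set to exactly 1; finite-sample estimates of
  self-dependence overshoot 1 by $O(1/n)$ and tests allow that slack.
- Degenerate inputs error early with informative messages: series shorter
  than 8 points, constant samples (undefined W / zero pooled variance),
  single-class folds or test sets, subjects missing from a source table
  (named in the error).
- All stochastic stages take explicit integer seeds; `run_all()` derives
  every stage seed from one master seed, and identical seeds reproduce
  byte-identical outputs (single-threaded XGBoost).

## Problem sizes used by the test suite

The suite exercises the study-condition defaults but chooses economical
problem sizes where a quantity does not depend on the expensive dimension:
null-calibration replicates (500) use 8–40 time points because type-I
error of score/FA/correlation tests does not involve series length;
planted-effect recovery of the connectivity contrast uses the full 200
time points (100 replicates, the two M1 seeds only); classification checks
use 20 seeds with a reduced tuning budget (6–10 evaluations). The
acceptance suite completes in about six minutes on one CPU.

## Known limitations

- The split-plot ANOVA backend does not fit a full random-effects
  likelihood model; with the summed-score design the two coincide for the
  reported effects.
- The Tukey post-hoc treats the six cells as independent samples; the
  repeated-measures covariance is accounted for only through the pooled
  MSE, not a Satterthwaite correction.
- The GP-EI tuner uses fixed surrogate hyperparameters; for the small
  budgets used here this is adequate, but it is not a general-purpose BO
  library.
- Under the default conditions ($d_{ATR} = 0.8$, $n = 19/19$), the
  one-tailed ATR test has ~0.79 power uncorrected but only ~0.41 power to
  survive BH-FDR across 10 tracts; a majority-of-replicates FDR detection
  is therefore not attainable at these sample sizes, and the corresponding
  acceptance expectation documents this as a statistical fact about the
  design rather than a software defect.

## A worked example

```{r example, eval = FALSE}
library(flemark)
cfg <- run_config(cohort = cohort_config(), master_seed = 1,
                  n_perm = 1000, n_bayes_iter = 10)
res <- run_all(cfg)
res          # prints the headline statistics of every stage
res$screen   # the 156-record correlation screen
```
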