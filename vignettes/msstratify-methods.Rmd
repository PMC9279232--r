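---
title: "Subtyping and staging relapsing-remitting MS from volumetric MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtyping and staging relapsing-remitting MS from volumetric MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msstratify)
```

# The problem

Regional gray-matter (GM) atrophy and demyelinating lesion load are objective
markers of disease burden in relapsing-remitting multiple sclerosis (RRMS),
but their variance across patients — part phenotypic heterogeneity, part
temporal heterogeneity — frustrates absolute cut-offs. msstratify implements
an unsupervised stratification of patients from a *single* MRI visit: it
expresses volumetric biomarkers as direction-corrected z-scores against
reference populations, selects the most altered regions by effect size, and
fits a z-score event-based subtype-and-stage mixture model that places each
patient on one of a small number of progression trajectories, at a discrete
stage along it. Longitudinal visits and long-term clinical outcomes then
serve to validate, not to train.

# Normalization and feature selection

Each raw volume $x$ is mapped to $z = s\,(x - \mu)/\sigma$, where $\mu$ and
$\sigma$ are the sample mean and SD (denominator $n-1$) of a reference
population and $s \in \{+1, -1\}$ is a direction flip so that larger $z$
always means worse disease: $s = -1$ for GM volumes (atrophy is loss),
$s = +1$ for total lesion volume (TLV). GM volumes are referenced to healthy
controls; TLV, which has no meaningful healthy-control distribution, is
referenced to an external RRMS population.

Candidate regions enter the model only if the patient-versus-control
difference carries a moderate-to-large effect size, Cohen's
$f = \sqrt{\eta^2_p / (1 - \eta^2_p)} > 0.25$, with strict inequality at the
boundary. `cohens_f()` computes $f$ from a linear model and optionally
adjusts for covariates (age, sex, intracranial volume); the unadjusted
comparison is the default because the selection stage of the analysis this
package operationalizes does not fix an adjustment set, and both modes are
exposed. Lesion volume is always included regardless of its effect size
(`always_include`).

# The subtype-and-stage model

## Events, sequences, trajectories

For each selected biomarker, abnormality levels $z = 1, 2, 3$ (mild,
moderate, severe) define candidate *events*: the biomarker crossing that
level. A level is kept only if at least 5% of baseline subjects reach it
(`build_event_grid()`, `min_fraction = 0.05`; the exclusion applies to
events reached by *fewer than* 5%). The retained events, $N$ in total, are
ordered by a *sequence* $S$ — a permutation constrained so each biomarker's
levels appear in ascending order.

The expected value of biomarker $i$ at stage $k \in \{0, \dots, N\}$ is the
piecewise-linear interpolant through $(0, 0)$, each of the biomarker's
events $(\text{position}, \text{level})$, and $(N, z_{\max})$; it is
nondecreasing in $k$ and defined for continuous stages by the same
interpolation. $z_{\max}$ defaults to 5 z-units per biomarker — it must
exceed the largest level (3), and the ceiling mainly shapes the trajectory
after a biomarker's last retained event.

## Likelihood

Observed z-scores are modeled as Gaussian around the stage's expected
profile with per-biomarker noise SD $\sigma_i$,

$$ p(\mathbf{x}_j \mid S, k) = \prod_{i\ \text{observed}}
   \mathcal{N}\!\left(x_{ij};\ E_i(S, k),\ \sigma_i\right), $$

missing biomarkers contributing a factor of one. Stages carry a uniform
prior, so a subject's marginal likelihood is
$\frac{1}{N+1}\sum_{k=0}^{N} p(\mathbf{x}_j \mid S, k)$, and a $C$-subtype
model mixes subtypes with fractions $f_c$ on the simplex. The default
$\sigma_i = 1$ z-unit is the natural scale for z-scored data and is
configurable per biomarker; analyses of synthetic cohorts in this package's
tests set $\sigma$ to the generator's noise scale, which is known there.

## Fitting

`fit_single_subtype()` maximizes the one-subtype likelihood by greedy
single-event repositioning: from a uniform random valid sequence, each event
in turn is removed and re-inserted at the best valid position, sweeping to a
fixed point; `n_startpoints` restarts (default 25) guard against local
optima, and the lowest candidate position wins exact ties so the result is
deterministic given the seed. For grids of up to six events the greedy
optimum is verified against exhaustive enumeration in the test suite.

`fit_sustain()` builds models hierarchically: the $C$-subtype model is
initialized by splitting one cluster of the $(C-1)$-subtype model,
bipartitioning its maximum-likelihood members, refitting each half, then
alternating (i) posterior-weighted fraction updates and (ii) greedy sequence
refits on hard-assigned members until the total log-likelihood improves by
less than $10^{-6}$ or 100 iterations. Every cluster is tried and the best
split kept.

One design choice deserves emphasis. Purely *random* bipartitions put close
to half of each latent subtype into each half; both half-fits then learn the
same compromise sequence, and the alternating optimization is left at a
symmetric fixed point — with two reversed orderings, repeated random
attempts converge to hybrid solutions far below the truth-initialized
optimum. The first split attempt is therefore
*guided*: cluster members are split by the sign of the first principal
component of their residuals from the cluster's own trajectory (evaluated at
each member's ML stage), which separates divergent orderings at every stage;
subsequent attempts (`n_splits`, default 5) use random bipartitions. On
two-subtype synthetic cohorts this initialization recovers the generating
solution essentially always.

## Positional uncertainty

`mcmc_positional_uncertainty()` quantifies sequence uncertainty by
Metropolis–Hastings: propose swapping two positions in one subtype's
sequence (a symmetric proposal), reject proposals violating the
within-biomarker order, and accept by the mixture-likelihood ratio with
fractions held fixed. The positional variance diagram (PVD) is the
empirical probability that each event occupies each position, after
discarding the first 10% of samples as burn-in. The chain is a display of
uncertainty, not an estimator; on three-event instances its PVD is within
total variation 0.05 of the exactly enumerated posterior at $10^4$ samples.

## Assignment

`assign_visits()` gives each MRI visit a subtype posterior
$\propto f_c \cdot \frac{1}{N+1}\sum_k p(\mathbf{x} \mid S_c, k)$ and a
stage posterior conditional on the ML subtype, along with `ml_stage` and
`expected_stage`. Subjects with uninformative profiles (all-normal, stage
0) have subtype posteriors equal to the mixture fractions; they are still
assigned, and downstream analyses may filter on
`subtype_probability` (`filter_by_assignment_probability()`, thresholds
0.95/0.99 in the sensitivity analyses).

# Model selection and cross-fold similarity

`cross_validate()` partitions *subjects* into folds (default 10; the tests
and the acceptance script use 3 to keep run times proportionate), fits all
candidate subtype counts on each training remainder, and scores the
held-out mixture log-likelihood, per-subject normalized because folds can
differ in size. The preferred $C$ maximizes the fold-mean held-out
log-likelihood. The event grid is built once on the full data and reused in
folds: the 5% rule is part of the problem definition, and per-fold grids
would make likelihoods non-comparable.

Cross-validation similarity (CVS) asks whether the *patterns* are stable
across folds: fold subtypes are matched to full-model subtypes by the
one-to-one matching that maximizes total event-wise Bhattacharyya
similarity, and CVS is the mean over events of the Bhattacharyya
coefficient $\sum_k \sqrt{p_k q_k}$ between the event's positional
distribution in the fold versus the full model, reported mean ± SD over
folds. Matching before averaging matters: fold subtype labels are
arbitrary, and unmatched averaging would understate similarity.

# Longitudinal validation

**Stability.** Krippendorff's $\alpha$ (nominal level, coincidence-matrix
formulation) measures whether a subject's assigned subtype is consistent
across visits; subjects are the units, per-visit labels the ratings, and
subjects with one visit contribute nothing. $\alpha = 1 - D_o/D_e$ is
undefined when expected disagreement is zero (a single label overall) and
the package raises an explicit error there. Confidence intervals come from
a percentile bootstrap over subjects (1000 resamples by default); all
within-subject visits are used.

**Stage change.** `fit_stage_change()` fits, by maximum likelihood,
$\text{stage}_{jt} = \beta_0 + \beta_1 t + b_{0j} + b_{1j} t +
\varepsilon$, with correlated random intercepts and slopes by subject
(lme4, with Satterthwaite-based tests via lmerTest). The stage is treated
as continuous although observed stages are integers — it is the linear
model the validation design calls for. A subject-level moderator (baseline
subtype, or baseline stage) adds its main effect and its interaction with
time; a negative baseline-stage × time interaction is the *plateau effect*
(flatter progression at higher baseline stage). When the moderator is the
subtype, the input should be restricted to subjects who kept their baseline
subtype at every visit (`retained_subtype_subjects()`, the literal reading
of "retained the initial subtype"). Subjects with a single visit stay in
the model; they inform intercepts. `fit_biomarker_trajectories()` reuses
the machinery with each biomarker's z-score as the outcome.

# Clinical-outcome models

`build_outcome_design()` assembles the fixed predictor blocks: coded
subtype (DGM-first = 0, cortex-first = 1), baseline stage, their product,
age, and sex (F = 0, M = 1) for baseline EDSS — five predictors — with
follow-up time and therapy code (0 none, 1 interferon, 2 glatiramer
acetate, 3 natalizumab) added for the long-term outcomes — seven. Baseline
EDSS as an additional long-term covariate is available behind a flag but
off by default, matching the predictor tables the design mirrors. Baseline
EDSS is modeled on its observed 0.5-step categories by a proportional-odds
model (MASS::polr); long-term motor and cognitive disability (0–3) likewise;
the secondary-progressive transition (SP = 1, RR = 0) by binary logistic
regression. Confidence intervals are percentile bootstrap over subjects,
5000 resamples by default per the reported analysis convention (tests use
fewer; each fit records its resample count and failures). Overall fit is
summarized by the likelihood-ratio $\chi^2$, $-2$LL, and McFadden and
Nagelkerke pseudo-$R^2$; an $R^2$-and-$F$ summary for ordinal models is
not standard and is not produced. The ML baseline stage is the default
stage covariate; `expected_stage` is available via `stage_col`.

# The synthetic cohort generator

`sim_config()` encodes the study conditions the pipeline targets: 425
patients (~2.7 visits each, ~1129 visits), 148 healthy controls, 80
external patients; 11 biomarkers (bilateral thalami, right putamen,
bilateral insulae, bilateral anterior cingulate, right middle cingulate,
bilateral cunei, TLV) with plausible raw means in mL; two subtypes with
60/40 mixing; z-events at levels 1/2/3 with $z_{\max} = 5$; biomarker noise
$\sigma_{\text{gen}} = 0.25$ z; stage accrual $\beta_t = 0.20$/year with
plateau coefficient $-0.05$ per baseline-stage unit and between-subject
slope SD 0.1; and clinical outcomes drawn from proportional-odds/logistic
latent models whose stage, subtype, age, sex, follow-up and therapy
coefficients mirror the reported effect directions and magnitudes — as
generator inputs, not as reproduction claims.

Two generator choices are worth making explicit:

* **Orderings.** Subtype 1 orders deep gray matter first (thalami,
  putamen), then lesion volume, then cortex; subtype 2 is the reverse. The
  default sequences interleave levels in a staircase — an early region
  reaches $z = 2$ while later regions are still reaching $z = 1$ — the
  pattern positional variance diagrams of this model family display.
  Strictly level-blocked orderings (all $z=1$ events before any $z=2$)
  were rejected: besides being biologically odd, they make tail-block
  permutations nearly likelihood-neutral and any fitting procedure
  fragile.
* **Stage distribution.** Baseline stages are uniform over $0..N$ by
  default, which maximizes sequence identifiability for recovery tests; a
  skewed distribution (the clinically realistic case — most RRMS patients
  sit at low stages) is configurable via `stage_dist`.
* **Plateau centering.** The longitudinal rate is
  $\beta_t + \text{plateau}\,(k_0 - \bar{k}_0) + u_j$, with the plateau
  term centered on the mean baseline stage. An uncentered plateau of
  $-0.05$ against a uniform stage distribution over 34 stages would drive
  the *average* accrual strongly negative, contradicting the emulated
  condition of a positive ~0.2 stages/year population-average increase
  coexisting with the negative baseline-stage × time moderation; centering
  makes $\beta_t$ the population-average accrual and leaves the fitted
  interaction unchanged.

What the generator does *not* emulate: scanner and site effects,
segmentation error structure, informative dropout, correlated regional
noise, age- and sex-dependence of raw volumes, and measurement error in the
clinical scales. Passing recovery tests on these synthetic cohorts
therefore demonstrates the correctness and internal consistency of the
estimation machinery under the stated generative model — not performance on
real MRI data.

# Numerical choices and degenerate inputs

* Likelihood evaluations run in log space with a guarded log-sum-exp;
  missing values are masked so they contribute a factor of one.
* Greedy moves are accepted only on strict improvement ($>10^{-12}$), so
  sweeps terminate; exact ties resolve to the lowest position.
* The alternating optimization stops at a $10^{-6}$ log-likelihood gain or
  100 iterations; mixture fractions are floored at $10^{-12}$ before
  renormalization.
* All stochastic stages draw from named child streams of one master seed
  (`derive_seed()`), so every stage is independently reproducible and
  seeds stay below $2^{31}$.
* Degenerate cases fail loudly: zero-variance reference biomarkers, zero
  residual variance in Cohen's $f$ (infinite effect size), an empty event
  grid, a constant outcome, single-label stability tables, and
  non-converged fits all raise or record explicit diagnostics rather than
  returning silently.

# Problem sizes in the test suite

The test suite exercises the pipeline at sizes chosen to make the
statistical properties sharp while staying proportionate: sequence recovery
uses 5 biomarkers × 3 levels at $n = 500$ over 10 seeds; subtype recovery
and model selection use two reversed-order subtypes at $n = 400$ with
3-fold cross-validation; multilevel recovery uses 200 replicates at
$n = 300$ subjects; outcome-model recovery uses 200 replicates with
500-resample bootstraps (5000 remains the production default). The
acceptance script runs the full pipeline once at the emulated study scale
(425 patients, 116 candidate volumes).

# Known limitations

* Only the z-score flavor of the event-based subtype model is implemented —
  no mixture-of-Gaussians event likelihoods, ordinal/discrete variants,
  covariate-adjusted trajectories, or parallel tempering.
* $\sigma_i$ is fixed by the analyst, not estimated; a misspecified noise
  scale flattens or sharpens posteriors accordingly.
* The MCMC is a single chain intended for uncertainty display; no formal
  convergence diagnostics are computed.
* Subtype labeling (`label_subtypes()`) is defined for one- and two-subtype
  models; richer taxonomies need a labeling rule of their own.
* The stage is modeled as continuous in longitudinal models and the
  bootstrap is percentile (not BCa) — both deliberate simplicity choices.
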