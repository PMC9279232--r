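# msstratify

Unsupervised, single-visit stratification of relapsing-remitting multiple
sclerosis (RRMS) patients from volumetric brain-MRI biomarkers.

Regional gray-matter volumes and total demyelinating lesion volume (TLV)
index disease burden in RRMS, but their between-patient variance defeats
absolute cut-offs. msstratify implements the full analysis pipeline for an
event-based stratification of a patient cohort:

1. **Normalization** — raw volumes (mL) become direction-corrected z-scores:
   `z = flip * (x − μ)/σ`, with μ, σ from healthy controls (gray matter,
   `flip = −1`) or an external RRMS population (lesion volume, `flip = +1`),
   so higher z always means worse disease.
2. **Feature selection** — regions with a moderate-to-large patient-control
   difference (Cohen's *f* > 0.25, strict) enter the model; lesion volume is
   always included.
3. **Subtype and stage inference** — a z-score event-based mixture model.
   Each biomarker crossing z = 1, 2, 3 is an *event* (events reached by
   fewer than 5% of subjects are excluded); a *subtype* is an ordering of
   all N events; a subject's *stage* k means the first k events have
   occurred. Biomarker observations are Gaussian around piecewise-linear
   expected trajectories anchored at (0, 0), (event position, level) and
   (N, z_max), stages carry a uniform prior, and subtypes mix with
   fractions on the simplex. Fitting is greedy maximum-likelihood sequence
   optimization with hierarchical cluster splitting;
   Metropolis–Hastings sampling over sequences yields positional variance
   diagrams (PVDs).
4. **Model selection** — cross-validation over subjects; the subtype count
   maximizing mean held-out log-likelihood wins; pattern stability across
   folds is the event-wise Bhattacharyya cross-validation similarity (CVS).
5. **Validation** — Krippendorff's α for subtype stability across a
   subject's visits; random-intercept/random-slope models of stage change
   over time (annual accrual, and its moderation by baseline stage — the
   plateau effect); proportional-odds / logistic models of baseline EDSS and
   long-term outcomes with subject-bootstrap confidence intervals.
6. **Synthetic cohorts** — a generator with known ground truth (true
   sequences, subtypes, stages, progression rates, outcome coefficients)
   emulating the study conditions (425 patients / ~1129 visits, 148
   controls, 80 external patients, 11 biomarkers, two subtypes with 60/40
   mixing), so every stage of the pipeline is testable against truth.

The intended users are imaging/biostatistics researchers who want a tested,
reproducible reimplementation of this class of analysis to run on their own
cohorts or to study its statistical behavior on synthetic data.

## Worked example

Generate a two-subtype synthetic cohort, z-score it, fit models with one
and two subtypes, and assign every subject a subtype and stage:

```r
library(msstratify)
library(dplyr)

cfg <- sim_config(n_patients = 200, n_hc = 100, n_external = 40)
refs <- generate_reference_populations(cfg, seed = 7)
cohort <- generate_patient_cohort(cfg, seed = 7)

# reference stats: gray matter vs controls, lesion volume vs external RRMS
stats <- bind_rows(
  fit_reference_stats(refs$hc, setdiff(biomarker_names(refs$hc), "tlv"),
                      flip = -1, reference_id = "HC"),
  fit_reference_stats(refs$external, "tlv", flip = 1,
                      reference_id = "external_patients")
)
z <- apply_zscore(cohort$biomarkers, stats)

grid <- build_event_grid(z)            # 5% rule at z = 1, 2, 3
models <- fit_sustain(z, grid, max_subtypes = 2, sigma = 0.25,
                      n_startpoints = 5, seed = 1)
models[[2]]
#> Subtype-and-stage model: 2 subtype(s), 33 events over 11 biomarkers
#>   fractions: 0.564, 0.436
#>   log-likelihood: -1003.921

assignments <- assign_visits(models[[2]], z)
assignments %>% select(subject_id, ml_subtype, subtype_probability,
                       ml_stage, expected_stage) %>% head(3)
#> # A tibble: 3 × 5
#>   subject_id ml_subtype subtype_probability ml_stage expected_stage
#>   <chr>           <int>               <dbl>    <int>          <dbl>
#> 1 P0001               1               1           33          33
#> 2 P0002               1               1.000        2           1.97
#> 3 P0003               1               1           23          22.9

# accuracy against the generator's ground truth (labels matched)
max(mean(assignments$ml_subtype == cohort$ground_truth$true_subtype),
    mean(3L - assignments$ml_subtype == cohort$ground_truth$true_subtype))
#> [1] 0.985
```

The fractions approximate the configured 60/40 mixing; `ml_stage` is each
subject's maximum-likelihood position along its subtype's event sequence
(0 = no events yet, 33 = all events), and `subtype_probability` is the
posterior mass of the assigned subtype — near 1 except for subjects with
little abnormality, whose profiles are uninformative at stage 0.

`tidy()`, `glance()` and `autoplot()` methods cover the fitted objects:
`tidy(models[[2]])` lists each subtype's event ordering,
`autoplot(mcmc_positional_uncertainty(z, models[[2]], 10000, seed = 1))`
draws the positional variance diagrams, and `autoplot()` on a
`cross_validate()` result plots the model-selection curve.

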