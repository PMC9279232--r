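test_that("generators are pure functions of config and seed", {
  cfg <- two_subtype_config(n_patients = 20)
  expect_identical(generate_reference_populations(cfg, seed = 5),
                   generate_reference_populations(cfg, seed = 5))
  c1 <- generate_patient_cohort(cfg, seed = 5)
  c2 <- generate_patient_cohort(cfg, seed = 5)
  expect_identical(c1$biomarkers, c2$biomarkers)
  expect_identical(generate_longitudinal_visits(c1, seed = 6)$biomarkers,
                   generate_longitudinal_visits(c2, seed = 6)$biomarkers)
  expect_identical(generate_clinical_outcomes(c1, seed = 7),
                   generate_clinical_outcomes(c2, seed = 7))
})

test_that("configured reference moments are recovered at large n", {
  cfg <- sim_config(n_hc = 1000, n_external = 1000)
  refs <- generate_reference_populations(cfg, seed = 8)
  bm <- cfg$biomarkers[1, ]
  x <- refs$hc[[bm$name]]
  se <- bm$sd / sqrt(1000)
  expect_lt(abs(mean(x) - bm$mean), 4 * se)
  expect_lt(abs(sd(x) - bm$sd), 4 * bm$sd / sqrt(2 * 999))
})

test_that("raw volumes invert to the latent z under the true reference stats", {
  cfg <- two_subtype_config(n_patients = 50, sigma_gen = 1e-12)
  coh <- generate_patient_cohort(cfg, seed = 9)
  z <- apply_zscore(coh$biomarkers, true_reference_stats(cfg))
  # with vanishing noise the z values are exactly the trajectory values
  for (j in sample(50, 5)) {
    s <- coh$sequences[[coh$ground_truth$true_subtype[j]]]
    for (b in attr(coh$grid, "biomarkers")) {
      expect_equal(z[[b]][j],
                   expected_value(s, coh$grid, b,
                                  coh$ground_truth$true_stage[j]),
                   tolerance = 1e-9)
    }
  }
})

test_that("noise-free generation lets assignment recover every true stage", {
  cfg <- two_subtype_config(n_patients = 80, sigma_gen = 0.01)
  coh <- generate_patient_cohort(cfg, seed = 10)
  z <- apply_zscore(coh$biomarkers, true_reference_stats(cfg))
  model <- msstratify:::new_sustain_model(
    coh$grid, coh$sequences, cfg$fractions,
    sigma = msstratify:::expand_sigma(0.01, attr(coh$grid, "biomarkers"))
  )
  asg <- assign_visits(model, z)
  expect_equal(asg$ml_stage, coh$ground_truth$true_stage)
})

test_that("subtype proportions match the configured fractions", {
  cfg <- two_subtype_config(n_patients = 2000)
  coh <- generate_patient_cohort(cfg, seed = 12)
  p <- mean(coh$ground_truth$true_subtype == 1)
  se <- sqrt(0.6 * 0.4 / 2000)
  expect_lt(abs(p - 0.6), 3 * se)
})

test_that("latent stages progress linearly, clip at the ends, and plateau", {
  cfg <- two_subtype_config(n_patients = 100)
  cfg$plateau <- 0
  cfg$slope_sd <- 0
  cfg$beta_time <- 0.2
  cfg$visit_count_probs <- c(0, 0, 1)  # three visits each
  coh <- generate_patient_cohort(cfg, seed = 13)
  lng <- generate_longitudinal_visits(coh, cfg, seed = 14)
  gt <- lng$ground_truth
  N <- nrow(coh$grid)
  expect_true(all(gt$true_stage >= 0 & gt$true_stage <= N))
  # un-clipped stages advance at exactly 0.2/year
  t <- lng$biomarkers$years_from_baseline
  k0 <- coh$ground_truth$true_stage[match(gt$subject_id,
                                          coh$ground_truth$subject_id)]
  unclipped <- (k0 + 0.2 * t) >= 0 & (k0 + 0.2 * t) <= N
  expect_equal(gt$true_stage[unclipped], (k0 + 0.2 * t)[unclipped],
               tolerance = 1e-12)
})

test_that("a negative plateau produces a negative fitted interaction", {
  signs <- vapply(1:10, function(r) {
    cfg <- two_subtype_config(n_patients = 150)
    cfg$plateau <- -0.05
    cfg$beta_time <- 0.4
    cfg$visit_count_probs <- c(0, 0, 0, 1)
    coh <- generate_patient_cohort(cfg, seed = 900 + r)
    lng <- generate_longitudinal_visits(coh, cfg, seed = 900 + r)
    gt <- lng$ground_truth
    gt$baseline_stage <- coh$ground_truth$true_stage[
      match(gt$subject_id, coh$ground_truth$subject_id)]
    gt$years_from_baseline <- lng$biomarkers$years_from_baseline
    # staged-with-noise outcome, as assignment would observe it
    gt$stage_obs <- gt$true_stage +
      withr::with_seed(333 + r, rnorm(nrow(gt), 0, 0.5))
    fit <- fit_stage_change(gt, outcome_col = "stage_obs",
                            moderator = "baseline_stage")
    fit$fixed$estimate[grepl(":", fit$fixed$term)] < 0
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("clinical outcomes depend on stage only through the coefficients", {
  cfg <- two_subtype_config(n_patients = 400)
  # null coefficients: outcomes independent of stage
  for (nm in c("baseline_edss", "lt_edss", "lt_bicams")) {
    cfg$outcomes[[nm]]$coef[] <- 0
  }
  cfg$outcomes$lt_sp$coef[] <- 0
  coh <- generate_patient_cohort(cfg, seed = 15)
  clin <- generate_clinical_outcomes(coh, cfg, seed = 16)
  tert <- cut(coh$ground_truth$true_stage, 3)
  p <- suppressWarnings(
    chisq.test(table(tert, clin$motor_disability_lt))$p.value)
  expect_gt(p, 0.01)

  # strong positive stage effect: monotone mean outcome across tertiles
  cfg2 <- two_subtype_config(n_patients = 400)
  cfg2$outcomes$lt_edss$coef["stage"] <- 0.6
  coh2 <- generate_patient_cohort(cfg2, seed = 17)
  clin2 <- generate_clinical_outcomes(coh2, cfg2, seed = 18)
  means <- tapply(clin2$motor_disability_lt,
                  cut(coh2$ground_truth$true_stage, 3), mean)
  expect_true(all(diff(means) > 0))
})

test_that("null gray-matter columns carry no disease effect", {
  cfg <- two_subtype_config(n_patients = 300)
  cfg2 <- sim_config(n_patients = 300, n_hc = 200, n_external = 10,
                     biomarkers = cfg$biomarkers, n_null_gm = 5,
                     fractions = c(0.6, 0.4))
  coh <- generate_patient_cohort(cfg2, seed = 19)
  refs <- generate_reference_populations(cfg2, seed = 19)
  sel <- select_biomarkers(coh$biomarkers, refs$hc)
  null_rows <- sel[startsWith(sel$biomarker, "null_region_"), ]
  expect_true(all(!null_rows$selected))
  disease_rows <- sel[!startsWith(sel$biomarker, "null_region_"), ]
  expect_true(all(disease_rows$selected))
})
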