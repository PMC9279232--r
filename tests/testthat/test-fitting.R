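test_that("greedy fitting equals exhaustive search on small grids", {
  withr::with_seed(21, {
    for (i in 1:5) {
      grid <- make_grid(c("A", "A", "B", "C"), c(1, 2, 1, 1))
      bms <- attr(grid, "biomarkers")
      true_seq <- msstratify:::random_valid_sequence(grid)
      X <- make_stage_data(grid, true_seq,
                           stages = sample(0:nrow(grid), 12, replace = TRUE),
                           sigma_gen = 0.6, seed = 100 + i)
      fit <- fit_single_subtype(X, grid, sigma = 0.6, n_startpoints = 20,
                                seed = i)
      cands <- oracle_valid_sequences(grid_events(grid))
      lls <- vapply(cands, function(s) {
        sequence_log_likelihood(X, s, grid, 0.6)
      }, numeric(1))
      expect_equal(fit$log_likelihood, max(lls), tolerance = 1e-10)
    }
  })
})

test_that("fitting is deterministic given the seed", {
  grid <- make_grid(c("A", "A", "B"), c(1, 2, 1))
  X <- make_stage_data(grid, c(1L, 3L, 2L), stages = 0:3, sigma_gen = 0.5,
                       seed = 2)
  f1 <- fit_single_subtype(X, grid, n_startpoints = 4, seed = 77)
  f2 <- fit_single_subtype(X, grid, n_startpoints = 4, seed = 77)
  expect_identical(f1, f2)
})

test_that("a noise-free cohort spanning all stages recovers its sequence", {
  grid <- make_grid(c("A", "A", "B", "C"), c(1, 2, 1, 1))
  true_seq <- c(3L, 1L, 4L, 2L)
  X <- make_stage_data(grid, true_seq, stages = rep(0:4, 3),
                       sigma_gen = 0.05, seed = 3)
  fit <- fit_single_subtype(X, grid, sigma = 0.05, n_startpoints = 10,
                            seed = 1)
  expect_identical(fit$sequence, true_seq)
})

test_that("degenerate all-identical data still returns, with a warning", {
  grid <- make_grid(c("A", "B"), c(1, 1))
  X <- matrix(0.5, 6, 2, dimnames = list(NULL, c("A", "B")))
  expect_warning(fit <- fit_single_subtype(X, grid, n_startpoints = 2,
                                           seed = 1),
                 "degenerate")
  expect_true(msstratify:::is_valid_sequence(fit$sequence, grid))
})

test_that("the one-subtype mixture model matches the single-subtype fit", {
  cfg <- two_subtype_config(n_patients = 50)
  coh <- generate_patient_cohort(cfg, seed = 4)
  z <- apply_zscore(coh$biomarkers, true_reference_stats(cfg))
  models <- fit_sustain(z, coh$grid, max_subtypes = 2, sigma = 0.25,
                        n_startpoints = 3, seed = 9)
  single <- fit_single_subtype(z, coh$grid, sigma = 0.25, n_startpoints = 3,
                               seed = msstratify:::derive_seed(9, "subtype-fit-1"))
  expect_identical(models[[1]]$sequences[[1]], single$sequence)
  for (m in models) {
    expect_equal(sum(m$fractions), 1, tolerance = 1e-12)
    expect_true(all(m$fractions >= 0))
  }
  expect_error(fit_sustain(z[1:3, ], coh$grid, max_subtypes = 4),
               "exceeds")
})

test_that("well-separated reversed subtypes are recovered accurately", {
  cfg <- two_subtype_config(n_patients = 200)
  coh <- generate_patient_cohort(cfg, seed = 31)
  z <- apply_zscore(coh$biomarkers, true_reference_stats(cfg))
  models <- fit_sustain(z, coh$grid, max_subtypes = 2, sigma = 0.25,
                        n_startpoints = 4, seed = 13)
  asg <- assign_visits(models[[2]], z)
  acc <- matched_accuracy(coh$ground_truth$true_subtype, asg$ml_subtype, 2)
  expect_gte(acc, 0.85)
})

test_that("assignment posteriors are coherent and exact in the easy limits", {
  cfg <- two_subtype_config(n_patients = 60, sigma_gen = 0.05)
  coh <- generate_patient_cohort(cfg, seed = 6)
  z <- apply_zscore(coh$biomarkers, true_reference_stats(cfg))
  grid <- coh$grid
  model <- msstratify:::new_sustain_model(
    grid, coh$sequences, cfg$fractions, sigma =
      msstratify:::expand_sigma(0.05, attr(grid, "biomarkers"))
  )
  asg <- assign_visits(model, z)
  # posteriors sum to one
  p_sub <- as.matrix(asg[, c("p_subtype_1", "p_subtype_2")])
  expect_equal(rowSums(p_sub), rep(1, nrow(asg)), tolerance = 1e-9)
  stage_sums <- vapply(asg$stage_posterior, sum, numeric(1))
  expect_equal(stage_sums, rep(1, nrow(asg)), tolerance = 1e-9)
  # near-noiseless generation recovers every true stage
  expect_equal(asg$ml_stage, coh$ground_truth$true_stage)
  # ml_* are the argmaxes of their posteriors
  expect_equal(asg$ml_subtype, max.col(p_sub, ties.method = "first"))

  # an all-zero visit sits at stage 0
  z0 <- stats::setNames(rep(0, length(attr(grid, "biomarkers"))),
                        attr(grid, "biomarkers"))
  one <- assign_visit(model, z0)
  expect_equal(one$ml_stage, 0L)
})

test_that("subtype labeling follows the DGM-event positions", {
  grid <- make_grid(c("thal", "cortex", "tlv"), c(1, 1, 1))
  # model 1: thal first; model 2 mirrored
  m <- msstratify:::new_sustain_model(
    grid, list(c(1L, 3L, 2L), c(2L, 3L, 1L)), c(0.5, 0.5),
    sigma = msstratify:::expand_sigma(1, attr(grid, "biomarkers"))
  )
  lab <- label_subtypes(m, "thal", "cortex", lesion_biomarker = "tlv")
  expect_equal(lab$label, c("DGM-first", "cortex-first"))

  m_swapped <- msstratify:::new_sustain_model(
    grid, list(c(2L, 3L, 1L), c(1L, 3L, 2L)), c(0.5, 0.5),
    sigma = msstratify:::expand_sigma(1, attr(grid, "biomarkers"))
  )
  lab2 <- label_subtypes(m_swapped, "thal", "cortex", lesion_biomarker = "tlv")
  expect_equal(lab2$label, c("cortex-first", "DGM-first"))

  m1 <- msstratify:::new_sustain_model(
    grid, list(c(1L, 3L, 2L)), 1,
    sigma = msstratify:::expand_sigma(1, attr(grid, "biomarkers"))
  )
  expect_warning(lab3 <- label_subtypes(m1, "thal", "cortex"),
                 "undifferentiated")
  expect_equal(lab3$label, "undifferentiated")

  expect_error(label_subtypes(m, "missing_bm", "cortex"), "not in grid")
})
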