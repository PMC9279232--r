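test_that("alpha is 1 under perfect within-subject agreement", {
  d <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3),
                  ml_subtype = rep(c(1, 2, 1), each = 3))
  res <- krippendorff_alpha(d, bootstrap_reps = 50, seed = 1)
  expect_equal(res$alpha, 1)
  expect_true(res$ci_low <= res$alpha && res$alpha <= res$ci_high)
  expect_equal(res$n_subjects_included, 3)
})

test_that("alpha matches the independent pairwise-formula oracle", {
  # the quoted two-subject example
  d <- data.frame(subject_id = c("s1", "s1", "s2", "s2"),
                  ml_subtype = c(1, 1, 1, 2))
  res <- krippendorff_alpha(d, bootstrap_reps = 0)
  expect_equal(res$alpha,
               oracle_kripp_alpha(list(c(1, 1), c(1, 2))),
               tolerance = 1e-12)

  withr::with_seed(14, {
    for (i in 1:20) {
      n_subj <- sample(3:8, 1)
      labels <- lapply(seq_len(n_subj), function(s) {
        sample(1:3, sample(1:4, 1), replace = TRUE)
      })
      if (length(unique(unlist(labels[lengths(labels) >= 2]))) < 2) next
      d <- data.frame(
        subject_id = rep(seq_len(n_subj), lengths(labels)),
        ml_subtype = unlist(labels)
      )
      got <- krippendorff_alpha(d, bootstrap_reps = 0)$alpha
      expect_equal(got, oracle_kripp_alpha(labels), tolerance = 1e-12)
    }
  })
})

test_that("alpha is near zero when labels are shuffled within subjects", {
  alphas <- vapply(1:7, function(s) {
    withr::with_seed(700 + s, {
      d <- data.frame(subject_id = rep(seq_len(300), each = 3),
                      ml_subtype = sample(1:2, 900, replace = TRUE))
    })
    krippendorff_alpha(d, bootstrap_reps = 0)$alpha
  }, numeric(1))
  expect_lt(abs(median(alphas)), 0.05)
})

test_that("alpha is invariant to relabeling and to single-visit subjects", {
  d <- data.frame(subject_id = rep(c("a", "b", "c", "d"), c(3, 3, 2, 1)),
                  ml_subtype = c(1, 1, 2, 2, 2, 2, 1, 2, 1))
  a0 <- krippendorff_alpha(d, bootstrap_reps = 0)$alpha
  relab <- d
  relab$ml_subtype <- ifelse(d$ml_subtype == 1, "B", "A")
  expect_equal(krippendorff_alpha(relab, bootstrap_reps = 0)$alpha, a0,
               tolerance = 1e-12)
  no_single <- d[d$subject_id != "d", ]
  expect_equal(krippendorff_alpha(no_single, bootstrap_reps = 0)$alpha, a0,
               tolerance = 1e-12)
  one_label <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                          ml_subtype = 1)
  expect_error(krippendorff_alpha(one_label, bootstrap_reps = 0),
               "undefined")
})

test_that("assignment-probability filtering is monotone in the threshold", {
  asg <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:10), visit_index = 0L,
    subtype_probability = seq(0.5, 1, length.out = 10)
  )
  all_subj <- filter_by_assignment_probability(asg, 0)
  at95 <- filter_by_assignment_probability(asg, 0.95)
  at99 <- filter_by_assignment_probability(asg, 0.99)
  expect_equal(all_subj, asg$subject_id)
  expect_true(all(at99 %in% at95))
  expect_equal(filter_by_assignment_probability(asg, 1.0), "S10")
})

test_that("retained-subtype subjects require an identical label at every visit", {
  asg <- tibble::tibble(
    subject_id = c("a", "a", "b", "b", "c"),
    visit_index = c(0L, 1L, 0L, 1L, 0L),
    ml_subtype = c(1, 1, 1, 2, 2)
  )
  expect_setequal(retained_subtype_subjects(asg), c("a", "c"))
})

test_that("noise-free common-slope data is fit exactly", {
  d <- expand.grid(subject_id = sprintf("S%02d", 1:20), visit = 0:2)
  d$years_from_baseline <- d$visit
  intercepts <- rep(withr::with_seed(8, runif(20, 0, 5)), 3)
  d$ml_stage <- intercepts + 0.2 * d$years_from_baseline
  fit <- fit_stage_change(d)
  est <- fit$fixed$estimate[fit$fixed$term == "years_from_baseline"]
  expect_equal(est, 0.2, tolerance = 1e-8)
})

test_that("with no random variation the mixed fit matches ordinary regression", {
  # zero random-effect generation (no intercept or slope spread): the mixed
  # model collapses to ordinary least squares
  withr::with_seed(31, {
    d <- make_longitudinal_stage_data(150, beta_time = 0.2, slope_sd = 0,
                                      resid_sd = 0.3, n_visits = 4,
                                      k0_max = 0)
  })
  fit <- fit_stage_change(d)
  ols <- lm(ml_stage ~ years_from_baseline, data = d)
  est <- fit$fixed$estimate[fit$fixed$term == "years_from_baseline"]
  expect_lt(abs(est - coef(ols)[["years_from_baseline"]]), 1e-4)
})

test_that("the annual stage slope and its moderation are recovered", {
  withr::with_seed(55, {
    ests <- numeric(20); cover <- logical(20)
    for (r in 1:20) {
      d <- make_longitudinal_stage_data(150, beta_time = 0.2,
                                        slope_sd = 0.1, resid_sd = 0.5)
      fit <- fit_stage_change(d)
      row <- fit$fixed[fit$fixed$term == "years_from_baseline", ]
      ests[r] <- row$estimate
      cover[r] <- row$ci_low <= 0.2 && 0.2 <= row$ci_high
    }
    expect_lt(abs(mean(ests) - 0.2), 0.05)
    expect_gte(mean(cover), 0.8)

    neg <- vapply(1:20, function(r) {
      d <- make_longitudinal_stage_data(150, beta_time = 0.3,
                                        plateau = -0.05, slope_sd = 0.05,
                                        resid_sd = 0.5)
      fit <- fit_stage_change(d, moderator = "baseline_stage")
      fit$fixed$estimate[grepl(":", fit$fixed$term)] < 0
    }, logical(1))
    expect_gte(mean(neg), 0.9)
  })
})

test_that("per-biomarker trajectory fits reuse the multilevel machinery", {
  withr::with_seed(77, {
    rows <- lapply(1:60, function(j) {
      t <- 0:2
      data.frame(subject_id = sprintf("S%03d", j), visit_index = t,
                 years_from_baseline = t, age_years = 35 + t, sex = "F",
                 drifting = rnorm(1) + 0.1 * t,   # deterministic 0.1 z/year
                 flat = rnorm(3))
    })
    z <- dplyr::bind_rows(rows)
  })
  fits <- fit_biomarker_trajectories(z)
  expect_named(fits, c("drifting", "flat"))
  est <- fits$drifting$fixed
  expect_equal(est$estimate[est$term == "years_from_baseline"], 0.1,
               tolerance = 1e-6)
  flat_row <- fits$flat$fixed[fits$flat$fixed$term == "years_from_baseline", ]
  expect_true(flat_row$ci_low <= 0 && 0 <= flat_row$ci_high)
})
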