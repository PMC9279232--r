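# Programmatic fixtures shared across test files.

# An event grid built directly from biomarker/level pairs.
make_grid <- function(biomarkers, levels, z_max = 5) {
  msstratify:::new_event_grid(biomarkers, levels, z_max = z_max)
}

# Events of a grid as a plain data frame for the oracles.
grid_events <- function(grid) {
  data.frame(event_id = grid$event_id, biomarker = grid$biomarker,
             level = grid$level, stringsAsFactors = FALSE)
}

# A well-formed per-visit biomarker tibble.
make_visit_table <- function(n_subjects = 3, visits_per_subject = 1,
                             biomarkers = c("thalamus_left", "tlv"),
                             seed = 42) {
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      for (v in seq_len(visits_per_subject) - 1L) {
        row <- data.frame(
          subject_id = sprintf("S%02d", s), visit_index = v,
          years_from_baseline = if (v == 0) 0 else v + runif(1, -0.3, 0.3),
          age_years = 30 + s, sex = ifelse(s %% 2 == 0, "M", "F"),
          stringsAsFactors = FALSE
        )
        for (b in biomarkers) row[[b]] <- rnorm(1, 10, 2)
        rows[[length(rows) + 1]] <- row
      }
    }
    tibble::as_tibble(do.call(rbind, rows))
  })
}

# Z-scored data drawn from a sequence: subjects at the given stages plus
# Gaussian noise. Returns a matrix aligned with the grid biomarkers.
make_stage_data <- function(grid, seq_ids, stages, sigma_gen, seed = 1) {
  withr::with_seed(seed, {
    bms <- attr(grid, "biomarkers")
    X <- matrix(NA_real_, length(stages), length(bms),
                dimnames = list(NULL, bms))
    for (j in seq_along(stages)) {
      for (b in bms) {
        mu <- expected_value(seq_ids, grid, b, stages[j])
        X[j, b] <- mu + rnorm(1, 0, sigma_gen)
      }
    }
    X
  })
}

# Small single-subtype generator configuration (5 gray-matter biomarkers,
# three z levels -> 15 events).
small_recovery_config <- function(n_patients = 500, sigma_gen = 0.25) {
  panel <- tibble::tibble(
    name = paste0("region_", letters[1:5]),
    mean = c(8, 6, 5, 4, 7), sd = c(0.8, 0.6, 0.5, 0.4, 0.7),
    flip = -1, reference = "HC", dgm = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    lesion = FALSE
  )
  sim_config(n_patients = n_patients, n_hc = 60, n_external = 10,
             biomarkers = panel, fractions = 1, sigma_gen = sigma_gen)
}

# Two-subtype configuration with reversed orderings (4 biomarkers, three
# levels -> 12 events).
two_subtype_config <- function(n_patients = 400, sigma_gen = 0.25) {
  panel <- tibble::tibble(
    name = c("thalamus_left", "putamen_right", "insula_left", "cuneus_left"),
    mean = c(8, 4, 7, 4), sd = c(0.8, 0.45, 0.75, 0.5),
    flip = -1, reference = "HC",
    dgm = c(TRUE, TRUE, FALSE, FALSE), lesion = FALSE
  )
  sim_config(n_patients = n_patients, n_hc = 60, n_external = 10,
             biomarkers = panel, fractions = c(0.6, 0.4),
             sigma_gen = sigma_gen)
}

# Accuracy of fitted subtype labels against truth, maximized over label
# permutations (fitted subtype identities are arbitrary).
matched_accuracy <- function(true_labels, fitted_labels, C) {
  perms <- oracle_permutations(seq_len(C))
  best <- 0
  for (p in perms) {
    acc <- mean(p[fitted_labels] == true_labels)
    best <- max(best, acc)
  }
  best
}

# Multilevel stage-change data generated straight from the random-slope
# model: y = k0 + (beta + u_j) t + e, visits at ~annual intervals.
make_longitudinal_stage_data <- function(n_subjects, beta_time = 0.2,
                                         plateau = 0, slope_sd = 0.1,
                                         resid_sd = 0.5, n_visits = 3,
                                         k0_max = 20) {
  k0 <- runif(n_subjects, 0, k0_max)
  u <- rnorm(n_subjects, 0, slope_sd)
  rows <- lapply(seq_len(n_subjects), function(j) {
    t <- c(0, cumsum(runif(n_visits - 1, 0.7, 1.3)))
    data.frame(
      subject_id = sprintf("S%04d", j),
      years_from_baseline = t,
      baseline_stage = k0[j],
      ml_stage = k0[j] + (beta_time + plateau * k0[j] + u[j]) * t +
        rnorm(n_visits, 0, resid_sd)
    )
  })
  do.call(rbind, rows)
}
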