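# Synthetic cohort generator: reference populations and patient cohorts with
# known subtype sequences, stages, longitudinal progression and clinical
# outcomes, so every pipeline stage can be tested against ground truth.

#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the study conditions the pipeline targets: 425
#' relapsing-remitting patients (about 2.7 MRI visits each), 148 healthy
#' controls and 80 external patients as references; 11 biomarkers (10
#' gray-matter regional volumes plus total lesion volume); two latent
#' subtypes with 60/40 mixing, one ordering deep-gray-matter events first
#' and the other cortical events first; z-score events at levels 1/2/3 with
#' a trajectory ceiling of 5; Gaussian biomarker noise of 0.25 z around the
#' piecewise-linear trajectories; stages accruing 0.2 stages/year with a
#' plateau (baseline-stage-by-time interaction -0.05) and a between-subject
#' slope SD of 0.1; and ordinal/binary clinical outcomes generated from
#' stage, subtype, age, sex, follow-up time and therapy through
#' proportional-odds / logistic latent models.
#'
#' @param n_patients,n_hc,n_external Population sizes.
#' @param biomarkers Tibble with columns `name`, `mean` (mL), `sd` (mL),
#'   `flip` (+1/-1), `reference` (`"HC"` or `"external"`), `dgm` (logical),
#'   `lesion` (logical). `NULL` uses the built-in 11-biomarker panel.
#' @param n_null_gm Extra gray-matter columns carrying no disease effect
#'   (patients drawn from the control distribution), used to exercise
#'   feature selection on wide tables.
#' @param levels Z-score event levels per biomarker.
#' @param z_max Trajectory ceiling (z units).
#' @param fractions Subtype mixing fractions (simplex).
#' @param sigma_gen Biomarker noise SD around the trajectory, in z units.
#' @param stage_dist `"uniform"` over stages 0..N, or a probability vector
#'   of length N + 1.
#' @param beta_time Annual stage accrual (stages/year).
#' @param plateau Baseline-stage-by-time interaction (per stage unit per
#'   year; negative flattens slopes at higher baseline stages).
#' @param slope_sd Between-subject SD of the annual stage slope.
#' @param visit_count_probs Distribution of the number of visits per subject
#'   (1, 2, ... visits); the default has mean 2.7.
#' @param visit_gap Range (years) of the uniform gap between visits.
#' @param fu_mean,fu_sd Long-term follow-up time distribution (years).
#' @param dmt_probs Probabilities of therapy codes 0..3.
#' @param outcomes Named list of coefficient blocks for
#'   `baseline_edss`, `lt_edss`, `lt_bicams` (each with `coef` and
#'   `cutpoints`) and `lt_sp` (with `coef` and `intercept`).
#' @param seed Master seed recorded in the config (generator calls may
#'   override it).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 425, n_hc = 148, n_external = 80,
                       biomarkers = NULL, n_null_gm = 0,
                       levels = c(1, 2, 3), z_max = 5,
                       fractions = c(0.6, 0.4), sigma_gen = 0.25,
                       stage_dist = "uniform", beta_time = 0.20,
                       plateau = -0.05, slope_sd = 0.1,
                       visit_count_probs = c(0.25, 0.25, 0.20, 0.15, 0.15),
                       visit_gap = c(0.6, 1.4),
                       fu_mean = 10, fu_sd = 2,
                       dmt_probs = c(0.073, 0.787, 0.028, 0.112),
                       outcomes = NULL, seed = 1L) {
  if (is.null(biomarkers)) biomarkers <- default_biomarker_panel()
  if (n_null_gm > 0) {
    null_rows <- tibble::tibble(
      name = sprintf("null_region_%03d", seq_len(n_null_gm)),
      mean = 5, sd = 0.5, flip = -1, reference = "HC",
      dgm = FALSE, lesion = FALSE
    )
    biomarkers <- dplyr::bind_rows(biomarkers, null_rows)
  }
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0)) {
    abort_msg("fractions must lie on the simplex")
  }
  if (sigma_gen <= 0) abort_msg("sigma_gen must be positive")
  if (is.null(outcomes)) outcomes <- default_outcome_blocks()
  structure(list(
    n_patients = n_patients, n_hc = n_hc, n_external = n_external,
    biomarkers = biomarkers, levels = levels, z_max = z_max,
    fractions = fractions, sigma_gen = sigma_gen, stage_dist = stage_dist,
    beta_time = beta_time, plateau = plateau, slope_sd = slope_sd,
    visit_count_probs = visit_count_probs, visit_gap = visit_gap,
    fu_mean = fu_mean, fu_sd = fu_sd, dmt_probs = dmt_probs,
    outcomes = outcomes,
    age = list(patients = c(35.9, 9.9), hc = c(35.9, 13.0),
               external = c(40.4, 11.9)),
    sex_prob_f = c(patients = 0.708, hc = 0.52, external = 0.70),
    seed = seed
  ), class = "sim_config")
}

# 10 gray-matter regions plus total lesion volume; raw means/SDs in mL are
# plausible adult values for the named structures.
default_biomarker_panel <- function() {
  tibble::tibble(
    name = c("thalamus_left", "thalamus_right", "putamen_right",
             "insula_left", "insula_right", "cingulate_ant_left",
             "cingulate_ant_right", "cingulate_mid_right",
             "cuneus_left", "cuneus_right", "tlv"),
    mean = c(8.1, 7.9, 4.1, 7.4, 7.2, 4.6, 4.8, 5.2, 3.9, 4.1, 3.4),
    sd = c(0.85, 0.82, 0.45, 0.80, 0.78, 0.55, 0.57, 0.60, 0.48, 0.50, 2.4),
    flip = c(rep(-1, 10), 1),
    reference = c(rep("HC", 10), "external"),
    dgm = c(TRUE, TRUE, TRUE, rep(FALSE, 8)),
    lesion = c(rep(FALSE, 10), TRUE)
  )
}

# Latent proportional-odds / logistic coefficient blocks for the clinical
# outcomes, on raw covariate scales (stage units, coded subtype 0/1, years
# of age, sex M=1, years of follow-up, therapy code 0-3). Cutpoints are
# placed so category frequencies resemble a moderate-disability RRMS
# cohort.
default_outcome_blocks <- function() {
  list(
    baseline_edss = list(
      coef = c(stage = 0.042, subtype = -0.28, interaction = -0.012,
               age = 0.033, sex = -0.12),
      cutpoints = 1.65 + stats::qlogis(c(0.03, 0.08, 0.16, 0.28, 0.42,
                                         0.58, 0.74, 0.87, 0.95))
    ),
    lt_edss = list(
      coef = c(stage = 0.030, subtype = -0.06, interaction = -0.016,
               age = 0.015, sex = 0.004, fu_time = -0.112, dmt = 0.28),
      cutpoints = c(1.2, 2.2, 3.2)
    ),
    lt_bicams = list(
      coef = c(stage = 0.048, subtype = -0.442, interaction = -0.08,
               age = 0.001, sex = 0.196, fu_time = 0.11, dmt = 0.093),
      cutpoints = c(1.2, 2.2, 2.95)
    ),
    lt_sp = list(
      coef = c(stage = 0.079, subtype = 0.422, interaction = 0.044,
               age = 0.095, sex = -0.926, fu_time = -0.301, dmt = 0.571),
      intercept = -4.3
    )
  )
}

#' True event grid and subtype sequences of a generator configuration
#'
#' The true grid holds every configured disease biomarker at every
#' configured level (null gray-matter columns carry no events). When the
#' config does not fix sequences explicitly, subtype 1 orders events
#' deep-gray-matter first (DGM regions, then lesion volume, then cortex,
#' level-by-level) and subtype 2 cortex first.
#'
#' @param config A `sim_config`.
#' @return A list with `grid` (an `event_grid`) and `sequences` (list of
#'   valid event orderings, one per subtype).
#' @export
sim_truth <- function(config) {
  bm <- config$biomarkers
  disease <- bm[!startsWith(bm$name, "null_region_"), ]
  nm <- disease$name
  grid <- new_event_grid(rep(nm, each = length(config$levels)),
                         rep(config$levels, length(nm)),
                         z_max = config$z_max)
  order1 <- c(nm[disease$dgm], nm[disease$lesion],
              nm[!disease$dgm & !disease$lesion])
  order2 <- rev(order1)
  # staircase interleave: a region reaches its next z level while later
  # regions are still reaching their first, as in observed atrophy cascades
  seq_for <- function(ord) {
    key <- match(grid$biomarker, ord) + (grid$level - 1) * 0.6 * length(nm)
    grid$event_id[order(key, grid$level)]
  }
  seqs <- list(seq_for(order1), seq_for(order2))[seq_along(config$fractions)]
  list(grid = grid, sequences = seqs)
}

#' True reference statistics of the generator
#'
#' The exact means, SDs and flips the generator uses to turn latent z-scores
#' into raw volumes; z-scoring generated raw data against these recovers the
#' latent z exactly.
#'
#' @param config A `sim_config`.
#' @return A reference-statistics tibble as from [fit_reference_stats()].
#' @export
true_reference_stats <- function(config) {
  bm <- config$biomarkers
  tibble::tibble(biomarker = bm$name, mean = bm$mean, sd = bm$sd,
                 flip = bm$flip,
                 reference_id = ifelse(bm$reference == "HC", "HC",
                                       "external_patients"))
}

make_key_cols <- function(ids, age_par, sex_pf) {
  n <- length(ids)
  tibble::tibble(
    subject_id = ids, visit_index = 0L, years_from_baseline = 0,
    age_years = round(stats::rnorm(n, age_par[1], age_par[2]), 1),
    sex = ifelse(stats::runif(n) < sex_pf, "F", "M")
  )
}

#' Generate the healthy-control and external-patient reference tables
#'
#' Raw volumes drawn per biomarker from the configured normal
#' distributions; controls carry near-zero lesion volumes while the
#' external patient population provides the lesion-volume reference.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (defaults to the config's master seed).
#' @return A list with raw-scale biomarker tables `hc` and `external`.
#' @export
generate_reference_populations <- function(config, seed = config$seed) {
  bm <- config$biomarkers
  if (config$n_hc < 2 || config$n_external < 2) {
    abort_msg("reference populations need at least 2 subjects")
  }
  with_seed(derive_seed(seed, "references"), {
    hc <- make_key_cols(sprintf("HC%04d", seq_len(config$n_hc)),
                        config$age$hc, config$sex_prob_f[["hc"]])
    ext <- make_key_cols(sprintf("EXT%04d", seq_len(config$n_external)),
                         config$age$external,
                         config$sex_prob_f[["external"]])
    for (i in seq_len(nrow(bm))) {
      b <- bm$name[i]
      if (bm$lesion[i]) {
        # controls have essentially no demyelinating lesions
        hc[[b]] <- pmax(stats::rnorm(config$n_hc, 0.3, 0.25), 0)
        ext[[b]] <- stats::rnorm(config$n_external, bm$mean[i], bm$sd[i])
      } else {
        hc[[b]] <- stats::rnorm(config$n_hc, bm$mean[i], bm$sd[i])
        ext[[b]] <- stats::rnorm(config$n_external, bm$mean[i], bm$sd[i])
      }
    }
    list(hc = validate_biomarker_table(hc, "raw"),
         external = validate_biomarker_table(ext, "raw"))
  })
}

# latent z -> raw volume under the true reference stats
z_to_raw <- function(z, mean, sd, flip) mean + flip * z * sd

#' Generate a baseline patient cohort with known subtypes and stages
#'
#' Each patient draws a subtype from the mixing fractions and a baseline
#' stage from the configured stage distribution; latent z-scores follow the
#' subtype's piecewise-linear trajectory at that stage plus Gaussian noise
#' (`sigma_gen`), and raw volumes invert the z-scoring under the true
#' reference statistics. Null gray-matter columns are drawn from the control
#' distribution unchanged.
#'
#' @inheritParams generate_reference_populations
#' @return A list: `biomarkers` (raw baseline table), `ground_truth`
#'   (per-subject `true_subtype`, `true_stage`), `grid`, `sequences`,
#'   `config`.
#' @export
generate_patient_cohort <- function(config, seed = config$seed) {
  truth <- sim_truth(config)
  grid <- truth$grid
  N <- nrow(grid)
  n <- config$n_patients
  bm <- config$biomarkers
  with_seed(derive_seed(seed, "cohort"), {
    tab <- make_key_cols(sprintf("P%04d", seq_len(n)),
                         config$age$patients,
                         config$sex_prob_f[["patients"]])
    subtype <- sample.int(length(config$fractions), n, replace = TRUE,
                          prob = config$fractions)
    stage_probs <- if (identical(config$stage_dist, "uniform")) {
      rep(1 / (N + 1), N + 1)
    } else {
      config$stage_dist
    }
    if (length(stage_probs) != N + 1) {
      abort_msg("stage_dist must have length N_events + 1")
    }
    stage <- sample(0:N, n, replace = TRUE, prob = stage_probs)
    E <- lapply(truth$sequences, expected_matrix, grid = grid)
    for (i in seq_len(nrow(bm))) {
      b <- bm$name[i]
      if (startsWith(b, "null_region_")) {
        tab[[b]] <- stats::rnorm(n, bm$mean[i], bm$sd[i])
      } else {
        mu_z <- vapply(seq_len(n), function(j) E[[subtype[j]]][b, stage[j] + 1],
                       numeric(1))
        z <- mu_z + stats::rnorm(n, 0, config$sigma_gen)
        tab[[b]] <- z_to_raw(z, bm$mean[i], bm$sd[i], bm$flip[i])
      }
    }
    list(biomarkers = validate_biomarker_table(tab, "raw"),
         ground_truth = tibble::tibble(subject_id = tab$subject_id,
                                       true_subtype = subtype,
                                       true_stage = stage),
         grid = grid, sequences = truth$sequences, config = config)
  })
}

#' Generate longitudinal visits from a baseline cohort
#'
#' Each subject's latent stage follows
#' `k(t) = k0 + (beta_time + plateau * (k0 - mean(k0)) + subject slope) * t`,
#' clipped to `[0, N]`; the plateau term is centered on the mean baseline
#' stage of the configured stage distribution so that `beta_time` is the
#' population-average annual accrual and `plateau` the baseline-stage
#' moderation — the two quantities the emulated longitudinal analysis
#' reports. Visit times follow the configured visit-count distribution and
#' inter-visit gaps, and biomarker values are regenerated from the latent
#' (continuous) stage with fresh noise. Baseline rows are carried over from
#' the cohort unchanged.
#'
#' @param cohort Output of [generate_patient_cohort()].
#' @param config A `sim_config` (defaults to the cohort's).
#' @param seed Integer seed.
#' @return A list: `biomarkers` (multi-visit raw table) and `ground_truth`
#'   (per-visit `true_stage` on the continuous scale, plus the subject's
#'   slope).
#' @export
generate_longitudinal_visits <- function(cohort, config = cohort$config,
                                         seed = config$seed) {
  grid <- cohort$grid
  N <- nrow(grid)
  bm <- config$biomarkers
  base <- cohort$biomarkers
  gt <- cohort$ground_truth
  if (any(config$visit_gap < 0)) abort_msg("visit gaps must be nonnegative")
  with_seed(derive_seed(seed, "longitudinal"), {
    n <- nrow(base)
    n_visits <- sample(seq_along(config$visit_count_probs), n, replace = TRUE,
                       prob = config$visit_count_probs)
    slope_dev <- stats::rnorm(n, 0, config$slope_sd)
    stage_probs <- if (identical(config$stage_dist, "uniform")) {
      rep(1 / (N + 1), N + 1)
    } else {
      config$stage_dist
    }
    k_center <- sum(stage_probs * 0:N)
    E <- lapply(cohort$sequences, expected_matrix, grid = grid)
    rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (j in seq_len(n)) {
      k0 <- gt$true_stage[j]
      rate <- config$beta_time + config$plateau * (k0 - k_center) +
        slope_dev[j]
      nv <- n_visits[j]
      times <- c(0, cumsum(stats::runif(max(nv - 1, 0), config$visit_gap[1],
                                        config$visit_gap[2])))
      stages <- pmin(pmax(k0 + rate * times, 0), N)
      base_row <- base[j, ]
      vis <- base_row[rep(1, nv), ]
      vis$visit_index <- seq_len(nv) - 1L
      vis$years_from_baseline <- times
      vis$age_years <- base_row$age_years + times
      if (nv > 1) {
        seq_j <- cohort$sequences[[gt$true_subtype[j]]]
        for (i in seq_len(nrow(bm))) {
          b <- bm$name[i]
          if (startsWith(b, "null_region_")) {
            vis[[b]][-1] <- stats::rnorm(nv - 1, bm$mean[i], bm$sd[i])
          } else {
            mu_z <- expected_value(seq_j, grid, b, stages[-1])
            z <- mu_z + stats::rnorm(nv - 1, 0, config$sigma_gen)
            vis[[b]][-1] <- z_to_raw(z, bm$mean[i], bm$sd[i], bm$flip[i])
          }
        }
      }
      rows[[j]] <- vis
      truth_rows[[j]] <- tibble::tibble(
        subject_id = base_row$subject_id,
        visit_index = seq_len(nv) - 1L,
        true_subtype = gt$true_subtype[j],
        true_stage = stages,
        slope = rate
      )
    }
    list(biomarkers = validate_biomarker_table(dplyr::bind_rows(rows), "raw"),
         ground_truth = dplyr::bind_rows(truth_rows))
  })
}

#' Generate clinical outcomes from the cohort's ground truth
#'
#' Baseline EDSS, long-term motor and cognitive disability (ordinal 0-3)
#' and secondary-progressive transition are drawn from latent
#' proportional-odds / logistic models on the true baseline stage, coded
#' subtype (subtype 1 = DGM-first = 0), age, sex, follow-up time and
#' therapy code, using the configured coefficient blocks.
#'
#' @inheritParams generate_longitudinal_visits
#' @return A per-subject clinical tibble (see [read_clinical_table()]).
#' @export
generate_clinical_outcomes <- function(cohort, config = cohort$config,
                                       seed = config$seed) {
  gt <- cohort$ground_truth
  base <- cohort$biomarkers
  n <- nrow(gt)
  blocks <- config$outcomes
  for (nm in c("baseline_edss", "lt_edss", "lt_bicams", "lt_sp")) {
    if (is.null(blocks[[nm]]) || is.null(blocks[[nm]]$coef)) {
      abort_msg("outcome block '", nm, "' missing from config")
    }
  }
  with_seed(derive_seed(seed, "clinical"), {
    subtype01 <- as.numeric(gt$true_subtype == 2)  # subtype 1 = DGM-first = 0
    stage <- gt$true_stage
    age <- base$age_years[match(gt$subject_id, base$subject_id)]
    sexM <- as.numeric(base$sex[match(gt$subject_id, base$subject_id)] == "M")
    fu <- pmin(pmax(stats::rnorm(n, config$fu_mean, config$fu_sd), 5), 15)
    dmt <- sample(0:3, n, replace = TRUE, prob = config$dmt_probs)
    eta <- function(cf) {
      e <- cf[["stage"]] * stage + cf[["subtype"]] * subtype01 +
        cf[["interaction"]] * subtype01 * stage + cf[["age"]] * age +
        cf[["sex"]] * sexM
      if ("fu_time" %in% names(cf)) {
        e <- e + cf[["fu_time"]] * fu + cf[["dmt"]] * dmt
      }
      e
    }
    ordinal_draw <- function(block) {
      latent <- eta(block$coef) + stats::rlogis(n)
      findInterval(latent, block$cutpoints)
    }
    edss_cat <- ordinal_draw(blocks$baseline_edss)
    sp_eta <- blocks$lt_sp$intercept + eta(blocks$lt_sp$coef)
    tibble::tibble(
      subject_id = gt$subject_id,
      baseline_edss = edss_cat * 0.5,
      motor_disability_lt = ordinal_draw(blocks$lt_edss),
      cognitive_disability_lt = ordinal_draw(blocks$lt_bicams),
      sp_transition = as.integer(stats::runif(n) < stats::plogis(sp_eta)),
      dmt_code = dmt,
      fu_time_years = fu
    )
  })
}
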