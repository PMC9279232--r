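# Longitudinal validation: subtype stability across visits and the rate and
# moderation of stage change over time.

#' Krippendorff's alpha for subtype stability across visits
#'
#' Nominal-level alpha `1 - D_o / D_e` via the coincidence-matrix
#' formulation, treating subjects as units and their per-visit subtype
#' labels as ratings: alpha 1 means every subject keeps one label, 0 means
#' agreement at chance level. A percentile bootstrap over subjects gives the
#' confidence interval. Subjects with a single visit contribute no pairable
#' values and leave alpha unchanged.
#'
#' @param data Data frame with one row per visit.
#' @param subject_col,label_col Column names of the subject id and the
#'   categorical label.
#' @param bootstrap_reps Bootstrap resamples of subjects (default 1000).
#' @param conf_level Confidence level of the percentile interval.
#' @param seed Integer seed for the bootstrap.
#' @param probability_threshold Record-keeping only: the baseline assignment
#'   probability threshold that produced `data` (see
#'   [filter_by_assignment_probability()]).
#' @return A `stability_result` list: `alpha`, `ci_low`, `ci_high`,
#'   `n_subjects_included`, `bootstrap_reps`, `probability_threshold`.
#' @export
krippendorff_alpha <- function(data, subject_col = "subject_id",
                               label_col = "ml_subtype",
                               bootstrap_reps = 1000, conf_level = 0.95,
                               seed = NULL, probability_threshold = NA) {
  data <- as.data.frame(data)
  units <- split(as.character(data[[label_col]]),
                 as.character(data[[subject_col]]))
  units <- lapply(units, function(v) v[!is.na(v)])
  alpha <- kripp_alpha_units(units, strict = TRUE)
  boot <- rep(NA_real_, bootstrap_reps)
  if (bootstrap_reps > 0) {
    with_seed(derive_seed(seed, "kripp-boot"), {
      for (r in seq_len(bootstrap_reps)) {
        resampled <- units[sample.int(length(units), replace = TRUE)]
        boot[r] <- kripp_alpha_units(resampled, strict = FALSE)
      }
    })
  }
  boot <- boot[!is.na(boot)]
  qs <- if (length(boot) > 0) {
    stats::quantile(boot, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                    names = FALSE)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(alpha = alpha, ci_low = qs[1], ci_high = qs[2],
                 n_subjects_included = length(units),
                 bootstrap_reps = bootstrap_reps,
                 probability_threshold = probability_threshold),
            class = "stability_result")
}

# Coincidence-matrix nominal alpha over a list of per-unit label vectors.
kripp_alpha_units <- function(units, strict = TRUE) {
  pairable <- units[vapply(units, length, integer(1)) >= 2]
  if (length(pairable) == 0) {
    if (strict) abort_msg("no subject has >= 2 visits: alpha undefined")
    return(NA_real_)
  }
  vals <- sort(unique(unlist(pairable)))
  V <- length(vals)
  if (V < 2) {
    if (strict) {
      abort_msg("only one label present among pairable values: expected ",
                "disagreement is zero and alpha is undefined")
    }
    return(NA_real_)
  }
  o <- matrix(0, V, V, dimnames = list(vals, vals))
  for (u in pairable) {
    m <- length(u)
    cnt <- table(factor(u, levels = vals))
    contrib <- (outer(cnt, cnt) - diag(as.numeric(cnt), V)) / (m - 1)
    o <- o + contrib
  }
  n_c <- rowSums(o)
  n_tot <- sum(n_c)
  d_o <- sum(o) - sum(diag(o))
  d_e <- (n_tot^2 - sum(n_c^2)) / (n_tot - 1)
  if (d_e == 0) {
    if (strict) abort_msg("expected disagreement is zero: alpha undefined")
    return(NA_real_)
  }
  1 - d_o / d_e
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Krippendorff's alpha = %.3f (%.0f%% CI %.3f, %.3f), %d subjects",
              x$alpha, 95, x$ci_low, x$ci_high, x$n_subjects_included))
  if (!is.na(x$probability_threshold)) {
    cat(" [baseline probability >=", x$probability_threshold, "]")
  }
  cat("\n")
  invisible(x)
}

#' Subjects exceeding a baseline assignment-probability threshold
#'
#' Retains subjects whose baseline (visit 0) subtype assignment probability
#' is at least `threshold`; the sensitivity analyses raise the threshold to
#' 0.95 and 0.99. The subset at 0.99 is always contained in the subset at
#' 0.95.
#'
#' @param assignments Per-visit assignment tibble from [assign_visits()].
#' @param threshold Probability threshold in `[0, 1]`.
#' @return Character vector of retained subject ids.
#' @export
filter_by_assignment_probability <- function(assignments, threshold) {
  assignments <- as.data.frame(assignments)
  base <- assignments[assignments$visit_index == 0L, ]
  if (nrow(base) == 0) abort_msg("no baseline (visit_index 0) assignments")
  as.character(base$subject_id[base$subtype_probability >= threshold])
}

#' Subjects whose ML subtype is identical at every visit
#'
#' Operationalizes "retained the initial subtype": the maximum-likelihood
#' subtype equals the baseline one at every follow-up visit.
#'
#' @param assignments Per-visit assignment tibble.
#' @return Character vector of subject ids.
#' @export
retained_subtype_subjects <- function(assignments) {
  assignments <- as.data.frame(assignments)
  keep <- tapply(assignments$ml_subtype, assignments$subject_id,
                 function(v) length(unique(v)) == 1)
  names(keep)[keep]
}

#' Multilevel model of stage change over time
#'
#' Fits a random-intercept, random-slope linear mixed model of the
#' subtype-and-stage model's stage on follow-up time (years), by maximum
#' likelihood: `stage ~ time + (time | subject)`. An optional moderator
#' (baseline subtype or baseline stage) enters with its main effect and its
#' interaction with time; a negative baseline-stage-by-time interaction is
#' the plateau effect (flatter slopes at higher baseline stages). When the
#' moderator is the subtype, restrict the input to subjects who retained
#' their baseline subtype (see [retained_subtype_subjects()]).
#'
#' @param data One row per visit with the outcome, a time column and a
#'   subject id.
#' @param outcome_col,time_col,subject_col Column names.
#' @param moderator Optional column name of a subject-level moderator.
#' @return A `longitudinal_fit`: tibbles of fixed effects (estimate, SE,
#'   Wald 95% CI, df, t, p) and variance components, plus convergence
#'   diagnostics. Stage is modeled as continuous even though observed
#'   stages are integers.
#' @export
fit_stage_change <- function(data, outcome_col = "ml_stage",
                             time_col = "years_from_baseline",
                             subject_col = "subject_id",
                             moderator = NULL) {
  data <- as.data.frame(data)
  for (col in c(outcome_col, time_col, subject_col, moderator)) {
    if (!col %in% names(data)) abort_msg("missing column '", col, "'")
  }
  d <- data.frame(.y = data[[outcome_col]], .t = data[[time_col]],
                  .id = factor(data[[subject_col]]))
  if (!is.null(moderator)) d$.m <- data[[moderator]]
  d <- d[stats::complete.cases(d), ]
  if (length(unique(d$.id[duplicated(d$.id)])) < 2) {
    abort_msg("need at least 2 subjects with >= 2 visits")
  }
  form <- if (is.null(moderator)) {
    .y ~ .t + (.t | .id)
  } else {
    .y ~ .t * .m + (.t | .id)
  }
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(form, data = d, REML = FALSE,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       calc.derivs = FALSE)),
      error = function(e) {
        abort_msg("mixed model failed to fit: ", conditionMessage(e))
      }
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  cf <- as.data.frame(stats::coef(summary(fit)))
  term_map <- c(".t" = time_col, ".m" = moderator %||% "",
                ".t:.m" = if (is.null(moderator)) "" else
                  paste0(time_col, ":", moderator))
  terms <- rownames(cf)
  for (k in names(term_map)) terms[terms == k] <- term_map[[k]]
  z <- stats::qnorm(0.975)
  fixed <- tibble::tibble(
    term = terms,
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    ci_low = cf[, "Estimate"] - z * cf[, "Std. Error"],
    ci_high = cf[, "Estimate"] + z * cf[, "Std. Error"],
    df = if ("df" %in% colnames(cf)) cf[, "df"] else NA_real_,
    statistic = cf[, "t value"],
    p_value = if ("Pr(>|t|)" %in% colnames(cf)) cf[, "Pr(>|t|)"] else
      2 * stats::pnorm(-abs(cf[, "t value"]))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  random <- tibble::tibble(
    component = ifelse(is.na(vc$var2), vc$var1, paste(vc$var1, vc$var2,
                                                      sep = ":")),
    grouping = vc$grp,
    variance = vc$vcov
  )
  random$component[is.na(random$component)] <- "residual"
  structure(list(fixed = fixed, random = random,
                 n_subjects = length(unique(d$.id)), n_obs = nrow(d),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 converged = length(msgs) == 0, messages = msgs,
                 moderator = moderator, outcome = outcome_col),
            class = "longitudinal_fit")
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat("Multilevel fit of", x$outcome, "on time")
  if (!is.null(x$moderator)) cat(" moderated by", x$moderator)
  cat(":", x$n_obs, "visits,", x$n_subjects, "subjects\n")
  print(x$fixed)
  if (!x$converged) cat("notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Per-biomarker longitudinal trajectory models
#'
#' Fits the [fit_stage_change()] machinery with each biomarker's z-score as
#' the outcome, one model per biomarker.
#'
#' @param z_visits Z-scored multi-visit biomarker table.
#' @param biomarkers Biomarkers to model; defaults to all in the table.
#' @param assignments Optional per-visit assignment tibble, joined in when a
#'   moderator refers to its columns (e.g. `"ml_subtype"`).
#' @param moderator Optional moderator column name.
#' @return Named list of `longitudinal_fit` objects, one per biomarker.
#' @export
fit_biomarker_trajectories <- function(z_visits, biomarkers = NULL,
                                       assignments = NULL,
                                       moderator = NULL) {
  z_visits <- tibble::as_tibble(z_visits)
  if (is.null(biomarkers)) biomarkers <- biomarker_names(z_visits)
  d <- z_visits
  if (!is.null(assignments)) {
    d <- merge_assignments(z_visits, assignments)
  }
  fits <- lapply(biomarkers, function(b) {
    fit_stage_change(d, outcome_col = b, moderator = moderator)
  })
  stats::setNames(fits, biomarkers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
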