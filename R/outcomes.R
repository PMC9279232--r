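# Clinical-outcome regressions: baseline disability and long-term prognosis
# from baseline subtype and stage, with subject-resampling bootstrap CIs.

#' Code subtype labels for outcome models
#'
#' The DGM-first subtype is coded 0 and the cortex-first subtype 1.
#'
#' @param labels Character vector of subtype labels (`"DGM-first"` /
#'   `"cortex-first"`).
#' @return Numeric 0/1 vector.
#' @export
code_subtype <- function(labels) {
  out <- ifelse(labels == "DGM-first", 0,
                ifelse(labels == "cortex-first", 1, NA_real_))
  if (any(is.na(out) & !is.na(labels))) {
    abort_msg("labels must be 'DGM-first' or 'cortex-first'")
  }
  out
}

#' Assemble the predictor design for a clinical-outcome model
#'
#' Builds the outcome column plus the fixed predictor block: coded subtype
#' (0 = DGM-first, 1 = cortex-first), baseline stage, their product
#' (`subtype_x_stage`), age and sex (F = 0, M = 1) for the baseline EDSS
#' model; long-term models add follow-up time and the therapy code
#' (0 = none, 1 = interferon, 2 = glatiramer acetate, 3 = natalizumab), and
#' can optionally add baseline EDSS as a covariate.
#'
#' @param data Merged analysis table (see [merge_assignments()]) with
#'   columns `subtype` (coded 0/1; see [code_subtype()]), a stage column,
#'   `age_years`, `sex`, and for long-term outcomes `fu_time_years` and
#'   `dmt_code`.
#' @param outcome_name One of `"baseline_edss"`, `"lt_edss"` (long-term
#'   motor disability), `"lt_bicams"` (long-term cognitive disability),
#'   `"lt_sp"` (secondary-progressive transition).
#' @param stage_col Which stage point estimate to use (default the
#'   maximum-likelihood baseline stage; `"expected_stage"` is available).
#' @param include_baseline_edss Add baseline EDSS as a long-term covariate.
#' @return A tibble whose first column is the outcome, the rest predictors.
#' @export
build_outcome_design <- function(data,
                                 outcome_name = c("baseline_edss", "lt_edss",
                                                  "lt_bicams", "lt_sp"),
                                 stage_col = "ml_stage",
                                 include_baseline_edss = FALSE) {
  outcome_name <- match.arg(outcome_name)
  data <- as.data.frame(data)
  outcome_col <- switch(outcome_name,
                        baseline_edss = "baseline_edss",
                        lt_edss = "motor_disability_lt",
                        lt_bicams = "cognitive_disability_lt",
                        lt_sp = "sp_transition")
  long_term <- outcome_name != "baseline_edss"
  required <- c(outcome_col, "subtype", stage_col, "age_years", "sex",
                if (long_term) c("fu_time_years", "dmt_code"),
                if (long_term && include_baseline_edss) "baseline_edss")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_msg("missing required column(s): ", paste(missing, collapse = ", "))
  }
  sex_num <- if (is.numeric(data$sex)) data$sex else
    ifelse(data$sex == "M", 1, 0)
  out <- tibble::tibble(
    !!outcome_name := data[[outcome_col]],
    subtype = as.numeric(data$subtype),
    stage = as.numeric(data[[stage_col]]),
    subtype_x_stage = as.numeric(data$subtype) * as.numeric(data[[stage_col]]),
    age = data$age_years,
    sex = sex_num
  )
  if (long_term) {
    out$fu_time <- data$fu_time_years
    out$dmt <- data$dmt_code
    if (include_baseline_edss) out$baseline_edss_cov <- data$baseline_edss
  }
  out[stats::complete.cases(out), ]
}

#' Proportional-odds model of an ordinal clinical outcome
#'
#' Fits an ordinal logistic (proportional-odds) regression of the outcome's
#' observed categories on the predictors, with Wald tests and percentile
#' bootstrap confidence intervals from resampling subjects (rows). The sign
#' convention is that positive coefficients push towards higher (worse)
#' outcome categories. Overall fit is summarized with the likelihood-ratio
#' chi-square against the intercept-only model, -2 log-likelihood, and
#' McFadden and Nagelkerke pseudo-R-squared.
#'
#' @param data Design tibble from [build_outcome_design()] (outcome first)
#'   or any data frame containing `outcome` and `predictors`.
#' @param outcome Outcome column name; defaults to the first column.
#' @param predictors Predictor column names; default all other columns.
#' @param bootstrap_reps Bootstrap resamples (production default 5000).
#' @param conf_level Confidence level of the percentile intervals.
#' @param seed Integer seed.
#' @return An `outcome_fit` with `terms` (estimate, bootstrap CI, SE, t, p),
#'   overall-fit statistics, `n`, `bootstrap_reps` and the count of failed
#'   resamples.
#' @export
ordinal_outcome_model <- function(data, outcome = NULL, predictors = NULL,
                                  bootstrap_reps = 5000, conf_level = 0.95,
                                  seed = NULL) {
  prep <- outcome_prep(data, outcome, predictors)
  y <- factor(prep$y, ordered = TRUE)
  if (nlevels(y) < 2) abort_msg("outcome has fewer than 2 observed levels")
  X <- as.matrix(prep$X)
  storage.mode(X) <- "double"
  d <- data.frame(.y = y)
  d$.x <- X  # matrix column: avoids per-resample formula machinery
  fit <- tryCatch(
    suppressWarnings(MASS::polr(.y ~ .x, data = d, method = "logistic",
                                Hess = TRUE)),
    error = function(e) abort_msg("proportional-odds fit failed ",
                                  "(possible separation): ",
                                  conditionMessage(e))
  )
  cf <- summary(fit)$coefficients
  k <- length(prep$predictors)
  est <- stats::setNames(cf[seq_len(k), "Value"], prep$predictors)
  se <- stats::setNames(cf[seq_len(k), "Std. Error"], prep$predictors)
  tval <- est / se
  p <- 2 * stats::pnorm(-abs(tval))

  start <- c(fit$coefficients, fit$zeta)
  boot_fun <- function(idx) {
    di <- data.frame(.y = y[idx])
    di$.x <- X[idx, , drop = FALSE]
    f <- suppressWarnings(MASS::polr(.y ~ .x, data = di,
                                     method = "logistic", Hess = FALSE,
                                     start = start))
    f$coefficients
  }
  boot <- bootstrap_coefs(nrow(d), boot_fun, bootstrap_reps, seed,
                          n_terms = k)
  ci <- boot_ci(boot$draws, conf_level)

  ll <- as.numeric(stats::logLik(fit))
  fit0 <- suppressWarnings(MASS::polr(.y ~ 1, data = d, method = "logistic"))
  ll0 <- as.numeric(stats::logLik(fit0))
  n <- nrow(d)
  lr <- 2 * (ll - ll0)
  new_outcome_fit(
    family = "ordinal",
    terms = tibble::tibble(term = prep$predictors, estimate = est,
                           ci_low = ci[1, ], ci_high = ci[2, ],
                           std_error = se, statistic = tval, p_value = p),
    glance = list(
      n = n, logLik = ll, minus2LL = -2 * ll, lr_statistic = lr,
      lr_df = length(prep$predictors),
      lr_p = stats::pchisq(lr, length(prep$predictors), lower.tail = FALSE),
      mcfadden_r2 = 1 - ll / ll0,
      nagelkerke_r2 = nagelkerke(ll, ll0, n)
    ),
    bootstrap_reps = bootstrap_reps, failed_reps = boot$failed, seed = seed
  )
}

#' Logistic model of a binary clinical outcome
#'
#' As [ordinal_outcome_model()] but with a binary logit (used for the
#' transition to a secondary-progressive course, coded SP = 1, RR = 0),
#' reporting z statistics, Nagelkerke pseudo-R-squared and -2LL.
#'
#' @inheritParams ordinal_outcome_model
#' @export
logistic_outcome_model <- function(data, outcome = NULL, predictors = NULL,
                                   bootstrap_reps = 5000, conf_level = 0.95,
                                   seed = NULL) {
  prep <- outcome_prep(data, outcome, predictors)
  y <- prep$y
  if (length(unique(y[!is.na(y)])) < 2) {
    abort_msg("outcome has no variation (constant)")
  }
  X <- as.matrix(prep$X)
  storage.mode(X) <- "double"
  Xi <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial()))
  if (!fit$converged) {
    abort_msg("logistic fit did not converge (possible quasi-complete ",
              "separation)")
  }
  terms_all <- c("(Intercept)", prep$predictors)
  est <- stats::setNames(fit$coefficients, terms_all)
  # Wald SEs from the final IWLS weights
  XtWX <- crossprod(Xi * sqrt(fit$weights))
  se <- stats::setNames(sqrt(diag(solve(XtWX))), terms_all)
  zval <- est / se
  p <- 2 * stats::pnorm(-abs(zval))

  boot_fun <- function(idx) {
    f <- suppressWarnings(stats::glm.fit(Xi[idx, , drop = FALSE], y[idx],
                                         family = stats::binomial(),
                                         start = fit$coefficients))
    if (!f$converged) stop("non-convergence")
    f$coefficients
  }
  boot <- bootstrap_coefs(length(y), boot_fun, bootstrap_reps, seed,
                          n_terms = length(terms_all))
  ci <- boot_ci(boot$draws, conf_level)

  # for 0/1 outcomes the saturated log-likelihood is 0, so ll = -deviance/2
  ll <- -fit$deviance / 2
  fit0 <- suppressWarnings(stats::glm.fit(matrix(1, length(y)), y,
                                          family = stats::binomial()))
  ll0 <- -fit0$deviance / 2
  n <- length(y)
  lr <- 2 * (ll - ll0)
  new_outcome_fit(
    family = "logistic",
    terms = tibble::tibble(term = terms_all, estimate = est,
                           ci_low = ci[1, ], ci_high = ci[2, ],
                           std_error = se, statistic = zval, p_value = p),
    glance = list(
      n = n, logLik = ll, minus2LL = -2 * ll, lr_statistic = lr,
      lr_df = length(prep$predictors),
      lr_p = stats::pchisq(lr, length(prep$predictors), lower.tail = FALSE),
      mcfadden_r2 = 1 - ll / ll0,
      nagelkerke_r2 = nagelkerke(ll, ll0, n)
    ),
    bootstrap_reps = bootstrap_reps, failed_reps = boot$failed, seed = seed
  )
}

outcome_prep <- function(data, outcome, predictors) {
  data <- as.data.frame(data)
  if (is.null(outcome)) outcome <- names(data)[1]
  if (is.null(predictors)) predictors <- setdiff(names(data), outcome)
  missing <- setdiff(c(outcome, predictors), names(data))
  if (length(missing) > 0) {
    abort_msg("missing column(s): ", paste(missing, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, c(outcome, predictors)])
  list(y = data[[outcome]][keep],
       X = data[keep, predictors, drop = FALSE],
       predictors = predictors)
}

bootstrap_coefs <- function(n, boot_fun, reps, seed, n_terms) {
  draws <- matrix(NA_real_, reps, n_terms)
  failed <- 0L
  if (reps > 0) {
    with_seed(derive_seed(seed, "outcome-boot"), {
      for (r in seq_len(reps)) {
        idx <- sample.int(n, replace = TRUE)
        res <- tryCatch(boot_fun(idx), error = function(e) NULL)
        if (is.null(res) || anyNA(res)) failed <- failed + 1L
        else draws[r, ] <- res
      }
    })
  }
  list(draws = draws[!is.na(draws[, 1]), , drop = FALSE], failed = failed)
}

boot_ci <- function(draws, conf_level) {
  if (nrow(draws) == 0) {
    return(matrix(NA_real_, 2, ncol(draws)))
  }
  apply(draws, 2, stats::quantile,
        probs = c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
        names = FALSE)
}

nagelkerke <- function(ll, ll0, n) {
  cox_snell <- 1 - exp(2 * (ll0 - ll) / n)
  max_r2 <- 1 - exp(2 * ll0 / n)
  cox_snell / max_r2
}

new_outcome_fit <- function(family, terms, glance, bootstrap_reps,
                            failed_reps, seed) {
  structure(list(family = family, terms = terms, glance = glance,
                 n = glance$n, bootstrap_reps = bootstrap_reps,
                 failed_reps = failed_reps, seed = seed),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(switch(x$family, ordinal = "Proportional-odds", "Logistic"),
      "outcome model:", x$n, "subjects;",
      x$bootstrap_reps, "bootstrap resamples")
  if (x$failed_reps > 0) cat(" (", x$failed_reps, "failed)")
  cat("\n")
  print(x$terms)
  g <- x$glance
  cat(sprintf("LR chi2(%d) = %.2f, p = %.3g; Nagelkerke R2 = %.3f; -2LL = %.1f\n",
              g$lr_df, g$lr_statistic, g$lr_p, g$nagelkerke_r2, g$minus2LL))
  invisible(x)
}
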