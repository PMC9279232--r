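# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted subtype-and-stage model
#'
#' One row per (subtype, position): the event's biomarker, level and
#' sequence position, plus the subtype's mixture fraction.
#'
#' @param x A `sustain_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sustain_model <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_subtypes), function(c) {
    s <- x$sequences[[c]]
    tibble::tibble(
      subtype = c,
      position = seq_along(s),
      biomarker = x$grid$biomarker[s],
      level = x$grid$level[s],
      fraction = x$fractions[c]
    )
  })
}

#' @rdname tidy.sustain_model
#' @export
glance.sustain_model <- function(x, ...) {
  tibble::tibble(n_subtypes = x$n_subtypes, n_events = n_events(x$grid),
                 n_biomarkers = length(attr(x$grid, "biomarkers")),
                 log_likelihood = x$log_likelihood)
}

#' Tidy a multilevel longitudinal fit
#'
#' @param x A `longitudinal_fit`.
#' @param effects `"fixed"` (default) or `"random"` (variance components).
#' @param ... Unused.
#' @return A tibble of coefficients or variance components.
#' @export
tidy.longitudinal_fit <- function(x, effects = c("fixed", "random"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed else x$random
}

#' @rdname tidy.longitudinal_fit
#' @export
glance.longitudinal_fit <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, n_obs = x$n_obs,
                 log_likelihood = x$log_likelihood, aic = x$aic,
                 converged = x$converged)
}

#' Tidy a clinical-outcome regression
#'
#' @param x An `outcome_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term (estimate, bootstrap CI,
#'   SE, test statistic, p).
#' @export
tidy.outcome_fit <- function(x, ...) x$terms

#' @rdname tidy.outcome_fit
#' @export
glance.outcome_fit <- function(x, ...) {
  g <- x$glance
  tibble::tibble(family = x$family, n = g$n, minus2LL = g$minus2LL,
                 lr_statistic = g$lr_statistic, lr_p = g$lr_p,
                 mcfadden_r2 = g$mcfadden_r2,
                 nagelkerke_r2 = g$nagelkerke_r2,
                 bootstrap_reps = x$bootstrap_reps,
                 failed_reps = x$failed_reps)
}

#' Tidy a subtype-stability result
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.stability_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_subjects_included = x$n_subjects_included,
                 bootstrap_reps = x$bootstrap_reps,
                 probability_threshold = x$probability_threshold)
}

#' Tidy a cross-validation result
#'
#' @param x A `sustain_cv`.
#' @param ... Unused.
#' @return The per-C summary tibble (mean and SD of held-out per-subject
#'   log-likelihood).
#' @export
tidy.sustain_cv <- function(x, ...) x$summary

#' @rdname tidy.sustain_cv
#' @export
glance.sustain_cv <- function(x, ...) {
  tibble::tibble(chosen_C = x$chosen_C, folds = nrow(x$heldout),
                 n_subjects = length(x$fold_of_subject))
}

#' Tidy a positional variance diagram
#'
#' @param x A `sustain_pvd`.
#' @param ... Unused.
#' @return A long tibble with columns `subtype`, `biomarker`, `level`,
#'   `event`, `position`, `probability`.
#' @export
tidy.sustain_pvd <- function(x, ...) {
  purrr::map_dfr(seq_along(x$pvd), function(c) {
    m <- x$pvd[[c]]
    tibble::tibble(
      subtype = c,
      biomarker = rep(x$grid$biomarker, ncol(m)),
      level = rep(x$grid$level, ncol(m)),
      event = rep(rownames(m), ncol(m)),
      position = rep(seq_len(ncol(m)), each = nrow(m)),
      probability = as.vector(m)
    )
  })
}
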