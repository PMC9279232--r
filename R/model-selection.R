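# Cross-validated choice of the number of subtypes and cross-fold
# similarity of progression patterns.

#' Bhattacharyya coefficient between two discrete distributions
#'
#' `sum_k sqrt(p_k * q_k)`, in `[0, 1]`; 1 for identical distributions, 0
#' for disjoint supports.
#'
#' @param p,q Nonnegative vectors of equal length, each summing to 1.
#' @return A single number in `[0, 1]`.
#' @export
bhattacharyya_coefficient <- function(p, q) {
  if (length(p) != length(q)) abort_msg("p and q must have equal length")
  if (any(p < 0) || any(q < 0)) abort_msg("negative probability entries")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort_msg("p and q must each sum to 1")
  }
  sum(sqrt(p * q))
}

#' Cross-validate the number of subtypes
#'
#' Partitions subjects (never visits) into folds; for each fold, fits models
#' with 1..`max_subtypes` subtypes on the remaining subjects and evaluates
#' the per-subject mixture log-likelihood on the held-out subjects. The
#' preferred number of subtypes maximizes the mean held-out log-likelihood
#' across folds. Held-out log-likelihoods are per-subject normalized before
#' averaging because fold sizes may differ by one. The event grid is built
#' once on the full data and reused in every fold so likelihoods stay
#' comparable.
#'
#' @param data Baseline z-scored biomarker table (one row per subject).
#' @param grid An `event_grid` built on the full training data.
#' @param max_subtypes Largest subtype count to evaluate.
#' @param folds Number of cross-validation folds.
#' @param sigma,n_startpoints,seed As in [fit_sustain()].
#' @param keep_models If `TRUE` (default), fold models are retained for the
#'   cross-validation-similarity analysis.
#' @return A `sustain_cv` object: `summary` tibble (per C: mean and SD of
#'   held-out per-subject log-likelihood), `chosen_C`, `fold_of_subject`,
#'   and `fold_models` (list of per-fold model lists).
#' @export
cross_validate <- function(data, grid, max_subtypes = 4, folds = 10,
                           sigma = 1, n_startpoints = 25, seed = NULL,
                           keep_models = TRUE) {
  data <- tibble::as_tibble(as.data.frame(data))
  if ("visit_index" %in% names(data)) {
    data <- dplyr::filter(data, .data$visit_index == 0L)
  }
  n <- nrow(data)
  if (folds > n) abort_msg("more folds than subjects")
  subject_ids <- if ("subject_id" %in% names(data)) {
    as.character(data$subject_id)
  } else {
    as.character(seq_len(n))
  }
  fold_of <- with_seed(derive_seed(seed, "cv-folds"),
                       sample(rep_len(seq_len(folds), n)))
  held_out <- matrix(NA_real_, nrow = folds, ncol = max_subtypes)
  fold_models <- vector("list", folds)
  seen <- integer(0)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    stopifnot(length(intersect(test_idx, train_idx)) == 0)
    seen <- c(seen, test_idx)
    models <- fit_sustain(data[train_idx, , drop = FALSE], grid,
                          max_subtypes = max_subtypes, sigma = sigma,
                          n_startpoints = n_startpoints,
                          seed = derive_seed(seed, paste0("cv-fit-", f)))
    for (C in seq_len(max_subtypes)) {
      ll <- model_log_likelihood(models[[C]],
                                 data[test_idx, , drop = FALSE],
                                 per_subject = TRUE)
      held_out[f, C] <- mean(ll)
    }
    fold_models[[f]] <- if (keep_models) models else NULL
  }
  stopifnot(sort(seen) == seq_len(n))  # every subject held out exactly once
  summary <- tibble::tibble(
    n_subtypes = seq_len(max_subtypes),
    mean_heldout_loglik = colMeans(held_out),
    sd_heldout_loglik = apply(held_out, 2, stats::sd)
  )
  structure(list(summary = summary,
                 chosen_C = which.max(summary$mean_heldout_loglik),
                 fold_of_subject = stats::setNames(fold_of, subject_ids),
                 heldout = held_out,
                 fold_models = fold_models,
                 seed = seed),
            class = "sustain_cv")
}

#' @export
print.sustain_cv <- function(x, ...) {
  cat("Cross-validation over", length(unique(x$fold_of_subject)),
      "subjects,", nrow(x$heldout), "folds\n")
  print(x$summary)
  cat("chosen number of subtypes:", x$chosen_C, "\n")
  invisible(x)
}

#' Cross-validation similarity of subtype progression patterns
#'
#' Measures how similar each subtype's positional variance diagram is across
#' folds: fold subtypes are matched to full-model subtypes by maximizing the
#' total event-wise Bhattacharyya similarity over one-to-one matchings, and
#' the per-fold CVS of a subtype is the mean over events of the
#' Bhattacharyya coefficient between the event's positional distribution in
#' the fold model versus the full model. Reported as mean and SD over folds.
#'
#' @param full_pvd `sustain_pvd` of the model fitted on all subjects.
#' @param fold_pvds List of `sustain_pvd` objects, one per fold, with the
#'   same grid and subtype count.
#' @return A tibble with columns `subtype`, `cvs_mean`, `cvs_sd`; per-fold
#'   values are attached as attribute `per_fold` (folds x subtypes matrix).
#' @export
cross_validation_similarity <- function(full_pvd, fold_pvds) {
  stopifnot(inherits(full_pvd, "sustain_pvd"))
  C <- length(full_pvd$pvd)
  N <- nrow(full_pvd$pvd[[1]])
  per_fold <- matrix(NA_real_, length(fold_pvds), C)
  for (f in seq_along(fold_pvds)) {
    fp <- fold_pvds[[f]]
    if (!inherits(fp, "sustain_pvd") || length(fp$pvd) != C ||
        nrow(fp$pvd[[1]]) != N ||
        !identical(rownames(fp$pvd[[1]]), rownames(full_pvd$pvd[[1]]))) {
      abort_msg("fold PVD ", f, " does not match the full model's grid")
    }
    sim <- matrix(NA_real_, C, C)  # sim[full c, fold c']
    for (a in seq_len(C)) {
      for (b in seq_len(C)) {
        sim[a, b] <- mean(vapply(seq_len(N), function(e) {
          bhattacharyya_coefficient(full_pvd$pvd[[a]][e, ], fp$pvd[[b]][e, ])
        }, numeric(1)))
      }
    }
    perms <- all_permutations(C)
    totals <- vapply(perms, function(p) sum(sim[cbind(seq_len(C), p)]),
                     numeric(1))
    best <- perms[[which.max(totals)]]
    per_fold[f, ] <- sim[cbind(seq_len(C), best)]
  }
  out <- tibble::tibble(
    subtype = seq_len(C),
    cvs_mean = colMeans(per_fold),
    cvs_sd = apply(per_fold, 2, stats::sd)
  )
  attr(out, "per_fold") <- per_fold
  out
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (i in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = i)
    }
  }
  out
}
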