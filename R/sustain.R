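# Z-score event-based subtype-and-stage model: piecewise-linear expected
# trajectories, marginal-stage likelihood, greedy ML fitting, hierarchical
# subtype splitting, MCMC positional uncertainty, per-visit assignment.

new_sustain_model <- function(grid, sequences, fractions, sigma,
                              log_likelihood = NA_real_, seed = NULL,
                              hyperparameters = list(), mcmc = NULL) {
  stopifnot(length(sequences) == length(fractions))
  fractions <- as.numeric(fractions)
  if (any(fractions < -1e-12) || abs(sum(fractions) - 1) > 1e-8) {
    abort_msg("mixture fractions must lie on the simplex")
  }
  for (s in sequences) {
    if (!is_valid_sequence(s, grid)) abort_msg("invalid subtype sequence")
  }
  # renormalize only when needed, so serialization round-trips bit-exactly
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-15) {
    fractions <- pmax(fractions, 0) / sum(pmax(fractions, 0))
  }
  structure(
    list(grid = grid, n_subtypes = length(sequences),
         sequences = lapply(sequences, as.integer),
         fractions = fractions,
         sigma = sigma, log_likelihood = log_likelihood,
         seed = seed, hyperparameters = hyperparameters, mcmc = mcmc),
    class = "sustain_model"
  )
}

#' @export
print.sustain_model <- function(x, ...) {
  cat("Subtype-and-stage model:", x$n_subtypes, "subtype(s),",
      n_events(x$grid), "events over", length(attr(x$grid, "biomarkers")),
      "biomarkers\n")
  cat("  fractions:", paste(sprintf("%.3f", x$fractions), collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$log_likelihood), "\n")
  invisible(x)
}

# Expected z value of every biomarker at stages 0..N (or the given stages)
# for a sequence: piecewise-linear through (0, 0), (position of each event,
# its level) and (N, z_max).
expected_matrix <- function(seq, grid, stages = NULL) {
  N <- nrow(grid)
  if (is.null(stages)) stages <- 0:N
  bms <- attr(grid, "biomarkers")
  z_max <- attr(grid, "z_max")
  ev_by_bm <- grid_events_by_biomarker(grid)
  pos_of_event <- integer(N)
  pos_of_event[seq] <- seq_len(N)
  E <- matrix(0, nrow = length(bms), ncol = length(stages),
              dimnames = list(bms, NULL))
  for (i in seq_along(bms)) {
    ev <- ev_by_bm[[i]]
    xs <- c(0, pos_of_event[ev$ids])
    ys <- c(0, ev$levels)
    if (xs[length(xs)] < N) {
      xs <- c(xs, N); ys <- c(ys, z_max[[i]])
    }
    j <- findInterval(stages, xs)
    j <- pmin(pmax(j, 1L), length(xs) - 1L)
    E[i, ] <- ys[j] + (ys[j + 1L] - ys[j]) * (stages - xs[j]) /
      (xs[j + 1L] - xs[j])
  }
  E
}

# Cached per-biomarker event ids and levels, in grid order.
grid_events_by_biomarker <- function(grid) {
  cache <- attr(grid, "ev_by_bm")
  if (!is.null(cache)) return(cache)
  bms <- attr(grid, "biomarkers")
  lapply(bms, function(b) {
    sel <- grid$biomarker == b
    list(ids = grid$event_id[sel], levels = grid$level[sel])
  })
}

# Precomputed quantities for repeated Gaussian stage-likelihood evaluation
# of a fixed data matrix under many candidate sequences. Missing values are
# masked so they contribute a factor of one.
ll_context <- function(X, sigma) {
  obs <- !is.na(X)
  Xz <- X
  Xz[!obs] <- 0
  inv_var <- 1 / sigma^2
  Xs <- sweep(Xz, 2, inv_var, "*")
  X2 <- drop((Xz^2) %*% inv_var)
  has_na <- !all(obs)
  if (has_na) {
    mask <- matrix(as.numeric(obs), nrow(X))
    const <- -drop(mask %*% log(sigma)) -
      0.918938533204672742 * rowSums(mask)
  } else {
    mask <- NULL
    const <- rep(-sum(log(sigma)) - 0.918938533204672742 * length(sigma),
                 nrow(X))
  }
  list(Xs = Xs, X2 = X2, mask = mask, const = const, inv_var = inv_var,
       has_na = has_na, n = nrow(X))
}

# n x K matrix of per-subject log-likelihoods at each stage, from a context.
ctx_stage_loglik <- function(ctx, E) {
  cross <- ctx$Xs %*% E
  if (ctx$has_na) {
    t3 <- ctx$mask %*% (E^2 * ctx$inv_var)
    ll <- cross - 0.5 * t3 - 0.5 * ctx$X2
  } else {
    r_k <- drop(crossprod(E^2, ctx$inv_var))
    ll <- cross - 0.5 * outer(ctx$X2, r_k, "+")
  }
  ll + ctx$const
}

ctx_marginal_loglik <- function(ctx, seq, grid) {
  E <- expected_matrix(seq, grid)
  ll <- ctx_stage_loglik(ctx, E)
  row_logsumexp(ll) - log(ncol(ll))
}

#' Expected biomarker value along a subtype trajectory
#'
#' The model's expected z-score of `biomarker` at a given stage of the
#' sequence `seq`: linear interpolation through the anchors (stage 0, z 0),
#' (position of each of the biomarker's events, its z level) and
#' (N events, `z_max`). Nondecreasing in stage; continuous stages are
#' interpolated the same way.
#'
#' @param seq Integer vector of event ids in position order (a valid
#'   subtype sequence).
#' @param grid An `event_grid`.
#' @param biomarker Biomarker name.
#' @param stage Stage(s) in `[0, N]` (integer or continuous).
#' @return Numeric vector of expected z values.
#' @export
expected_value <- function(seq, grid, biomarker, stage) {
  N <- nrow(grid)
  if (any(stage < 0 | stage > N)) {
    abort_msg("stage must lie in [0, ", N, "]")
  }
  if (!biomarker %in% attr(grid, "biomarkers")) {
    abort_msg("unknown biomarker '", biomarker, "'")
  }
  E <- expected_matrix(seq, grid, stages = stage)
  unname(E[biomarker, ])
}

# n x (N+1) matrix of per-subject log-likelihoods at each stage. Missing
# biomarker values contribute a factor of 1 (log 0 contribution).
stage_loglik_matrix <- function(X, E, sigma) {
  n <- nrow(X)
  K <- ncol(E)
  out <- matrix(0, n, K)
  for (i in seq_len(ncol(X))) {
    d <- outer(X[, i], E[i, ], "-")
    li <- -0.5 * (d / sigma[i])^2 - log(sigma[i]) - 0.918938533204672742
    li[is.na(li)] <- 0
    out <- out + li
  }
  out
}

#' Stage likelihoods of a single visit
#'
#' For a vector of z-scored biomarker values, the likelihood of observing it
#' at each stage k = 0..N of the sequence: the product over observed
#' biomarkers of the normal density around the stage-k expected value with
#' per-biomarker noise SD `sigma`. Missing biomarkers contribute a factor of
#' one, so an all-missing vector yields a flat profile.
#'
#' @param z Named (or grid-ordered) numeric vector of z values; may contain
#'   `NA`.
#' @inheritParams expected_value
#' @param sigma Per-biomarker noise SD in z units (> 0); a single value is
#'   recycled.
#' @return Numeric vector of length N + 1 (stages 0..N).
#' @export
stage_likelihoods <- function(z, seq, grid, sigma = 1) {
  bms <- attr(grid, "biomarkers")
  sigma <- expand_sigma(sigma, bms)
  if (!is.null(names(z))) {
    missing <- setdiff(bms, names(z))
    if (length(missing) > 0) abort_msg("z lacks biomarker(s): ",
                                       paste(missing, collapse = ", "))
    z <- z[bms]
  } else if (length(z) != length(bms)) {
    abort_msg("z must have one value per grid biomarker")
  }
  E <- expected_matrix(seq, grid)
  ll <- stage_loglik_matrix(matrix(z, nrow = 1), E, sigma)
  exp(drop(ll))
}

expand_sigma <- function(sigma, bms) {
  if (length(sigma) == 1) sigma <- stats::setNames(rep(sigma, length(bms)), bms)
  if (!is.null(names(sigma))) {
    if (!all(bms %in% names(sigma))) abort_msg("sigma must cover all biomarkers")
    sigma <- sigma[bms]
  } else if (length(sigma) != length(bms)) {
    abort_msg("sigma must have one entry per biomarker")
  }
  if (any(sigma <= 0)) abort_msg("sigma must be positive")
  sigma
}

#' Data log-likelihood of one subtype sequence
#'
#' Sum over subjects of the log of the stage-marginalized likelihood under a
#' uniform prior over stages 0..N:
#' `sum_j log( (1/(N+1)) * sum_k L_j(k) )`.
#'
#' @param data Z-scored biomarker table or matrix (rows = subjects).
#' @inheritParams stage_likelihoods
#' @return A single number.
#' @export
sequence_log_likelihood <- function(data, seq, grid, sigma = 1) {
  X <- as_z_matrix(data, biomarkers = attr(grid, "biomarkers"))
  if (nrow(X) < 1) abort_msg("need at least one subject")
  if (any(is.infinite(X))) abort_msg("non-finite biomarker values")
  sigma <- expand_sigma(sigma, attr(grid, "biomarkers"))
  E <- expected_matrix(seq, grid)
  M <- stage_loglik_matrix(X, E, sigma)
  sum(row_logsumexp(M) - log(ncol(M)))
}

# Internal fast path: per-subject marginal log-likelihood vector for a
# sequence, data already a matrix aligned with the grid.
subject_marginal_loglik <- function(X, seq, grid, sigma) {
  ctx_marginal_loglik(ll_context(X, sigma), seq, grid)
}

# Greedy single-event repositioning to a fixed point. For each event in id
# order: remove it, evaluate every valid reinsertion position, move if the
# likelihood strictly improves; among exact ties the lowest position wins.
greedy_optimize <- function(X, grid, sigma, seq0, ctx = NULL) {
  N <- nrow(grid)
  if (is.null(ctx)) ctx <- ll_context(X, sigma)
  cur <- seq0
  cur_ll <- sum(ctx_marginal_loglik(ctx, cur, grid))
  repeat {
    improved <- FALSE
    for (e in grid$event_id) {
      b <- grid$biomarker[e]
      l <- grid$level[e]
      s <- cur[cur != e]
      sel <- grid$biomarker == b
      lv <- grid$level[sel]; ids <- grid$event_id[sel]
      lower <- ids[lv < l]; upper <- ids[lv > l]
      lo <- if (length(lower) > 0) max(match(lower, s)) else 0L
      hi <- if (length(upper) > 0) min(match(upper, s)) else N
      positions <- (lo + 1L):hi
      lls <- vapply(positions, function(p) {
        cand <- append(s, e, after = p - 1L)
        sum(ctx_marginal_loglik(ctx, cand, grid))
      }, numeric(1))
      best <- which.max(lls)
      if (lls[best] > cur_ll + 1e-12) {
        cur <- append(s, e, after = positions[best] - 1L)
        cur_ll <- lls[best]
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(sequence = cur, log_likelihood = cur_ll)
}

#' Fit the maximum-likelihood event sequence for a single subtype
#'
#' Runs `n_startpoints` greedy optimizations (uniform random valid start,
#' then single-event repositioning to convergence) and returns the best
#' sequence found. Deterministic given `seed`.
#'
#' @param data Z-scored baseline biomarker table or matrix.
#' @param grid An `event_grid`.
#' @param sigma Per-biomarker noise SD (default 1 z-unit).
#' @param n_startpoints Number of random restarts.
#' @param seed Integer seed.
#' @return A list with `sequence` (integer event ids in position order) and
#'   `log_likelihood`.
#' @export
fit_single_subtype <- function(data, grid, sigma = 1, n_startpoints = 25,
                               seed = NULL) {
  X <- as_z_matrix(data, biomarkers = attr(grid, "biomarkers"))
  sigma <- expand_sigma(sigma, attr(grid, "biomarkers"))
  if (nrow(X) > 1 && all(apply(X, 2, function(v) {
    v <- v[!is.na(v)]; length(unique(v)) <= 1
  }))) {
    warning("degenerate data: all subjects identical", call. = FALSE)
  }
  ctx <- ll_context(X, sigma)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_startpoints)) {
      res <- greedy_optimize(X, grid, sigma, random_valid_sequence(grid),
                             ctx = ctx)
      if (is.null(best) || res$log_likelihood > best$log_likelihood) best <- res
    }
    best
  })
}

# Mixture machinery -----------------------------------------------------

# n x C matrix of per-subject marginal log-likelihoods under each subtype.
mixture_loglik_matrix <- function(X, sequences, grid, sigma, ctx = NULL) {
  if (is.null(ctx)) ctx <- ll_context(X, sigma)
  m <- vapply(sequences, function(s) ctx_marginal_loglik(ctx, s, grid),
              numeric(ctx$n))
  matrix(m, nrow = ctx$n)
}

# Total mixture log-likelihood and posterior responsibilities.
mixture_eval <- function(M, fractions) {
  lw <- sweep(M, 2, log(fractions), "+")
  tot <- row_logsumexp(lw)
  r <- exp(lw - tot)
  list(log_likelihood = sum(tot), responsibilities = r)
}

# Alternate hard-assignment sequence refits with soft fraction updates until
# the total log-likelihood stalls.
alternate_optimize <- function(X, grid, sigma, sequences, fractions,
                               tol = 1e-6, max_iter = 100) {
  C <- length(sequences)
  ctx <- ll_context(X, sigma)
  M <- mixture_loglik_matrix(X, sequences, grid, sigma, ctx = ctx)
  ev <- mixture_eval(M, fractions)
  ll_old <- ev$log_likelihood
  for (it in seq_len(max_iter)) {
    fractions <- pmax(colMeans(ev$responsibilities), 1e-12)
    fractions <- fractions / sum(fractions)
    hard <- max.col(ev$responsibilities, ties.method = "first")
    for (c in seq_len(C)) {
      members <- which(hard == c)
      if (length(members) >= 1) {
        res <- greedy_optimize(X[members, , drop = FALSE], grid, sigma,
                               sequences[[c]])
        sequences[[c]] <- res$sequence
      }
    }
    M <- mixture_loglik_matrix(X, sequences, grid, sigma, ctx = ctx)
    ev <- mixture_eval(M, fractions)
    if (ev$log_likelihood - ll_old < tol) break
    ll_old <- ev$log_likelihood
  }
  list(sequences = sequences, fractions = fractions,
       log_likelihood = ev$log_likelihood)
}

#' Fit subtype-and-stage models with 1 to `max_subtypes` subtypes
#'
#' The C-subtype solution is initialized from the (C-1)-subtype solution by
#' splitting one of its clusters: the subjects maximum-likelihood-assigned
#' to that cluster are bipartitioned, each half is refit as its own
#' sequence, and sequences and mixture fractions are then optimized
#' alternately to convergence. Every cluster of the (C-1) solution is tried
#' and the best-likelihood split kept. The first bipartition of each
#' cluster is guided: members are split by the sign of the first principal
#' component of their residuals from the cluster's own trajectory (at each
#' member's maximum-likelihood stage), which separates divergent event
#' orderings at every stage; `n_splits - 1` further random bipartitions
#' follow, because purely random 50/50 splits make both half-fits learn the
#' same compromise sequence and strand the alternating optimization in
#' hybrid local optima.
#'
#' @inheritParams fit_single_subtype
#' @param max_subtypes Largest number of subtypes to fit (1..4 typical).
#' @param n_startpoints Random restarts for the single-subtype fits.
#' @param n_splits Random bipartitions tried per split cluster.
#' @param tol,max_iter Convergence controls of the alternating optimization.
#' @return A list of `sustain_model` objects, element C holding the
#'   C-subtype model.
#' @export
fit_sustain <- function(data, grid, max_subtypes = 4, sigma = 1,
                        n_startpoints = 25, n_splits = 5, seed = NULL,
                        tol = 1e-6, max_iter = 100) {
  X <- as_z_matrix(data, biomarkers = attr(grid, "biomarkers"))
  sigma <- expand_sigma(sigma, attr(grid, "biomarkers"))
  if (max_subtypes > nrow(X)) {
    abort_msg("max_subtypes exceeds the number of subjects")
  }
  hyper <- list(n_startpoints = n_startpoints, n_splits = n_splits,
                tol = tol, max_iter = max_iter)
  models <- vector("list", max_subtypes)

  one <- fit_single_subtype(X, grid, sigma, n_startpoints,
                            seed = derive_seed(seed, "subtype-fit-1"))
  models[[1]] <- new_sustain_model(grid, list(one$sequence), 1, sigma,
                                   log_likelihood = one$log_likelihood,
                                   seed = seed, hyperparameters = hyper)

  for (C in seq_len(max_subtypes)[-1]) {
    base <- models[[C - 1]]
    Mb <- mixture_loglik_matrix(X, base$sequences, grid, sigma)
    evb <- mixture_eval(Mb, base$fractions)
    hard <- max.col(evb$responsibilities, ties.method = "first")
    best <- NULL
    for (c_split in seq_len(C - 1)) {
      members <- which(hard == c_split)
      if (length(members) < 2) next
      for (a in seq_len(n_splits)) {
        key <- paste0("split-", C, "-", c_split, "-", a)
        halves <- NULL
        if (a == 1) {
          halves <- residual_pca_split(X[members, , drop = FALSE],
                                       base$sequences[[c_split]], grid,
                                       sigma, members)
        }
        if (is.null(halves)) {
          halves <- with_seed(derive_seed(seed, key), {
            g <- sample(rep_len(1:2, length(members)))
            split(members, g)
          })
        }
        if (length(halves) < 2) next
        sub_seqs <- lapply(seq_along(halves), function(h) {
          fit_single_subtype(
            X[halves[[h]], , drop = FALSE], grid, sigma,
            n_startpoints = max(1L, ceiling(n_startpoints / 2)),
            seed = derive_seed(seed, paste0(key, "-half-", h))
          )$sequence
        })
        seqs <- c(base$sequences[-c_split], sub_seqs)
        f_old <- base$fractions[-c_split]
        f_new <- base$fractions[c_split] *
          vapply(halves, length, integer(1)) / length(members)
        fracs <- c(f_old, f_new)
        fracs <- fracs / sum(fracs)
        res <- alternate_optimize(X, grid, sigma, seqs, fracs,
                                  tol = tol, max_iter = max_iter)
        if (is.null(best) || res$log_likelihood > best$log_likelihood) {
          best <- res
        }
      }
    }
    if (is.null(best)) {
      abort_msg("could not split any cluster into ", C, " subtypes")
    }
    ord <- order(best$fractions, decreasing = TRUE)
    models[[C]] <- new_sustain_model(grid, best$sequences[ord],
                                     best$fractions[ord], sigma,
                                     log_likelihood = best$log_likelihood,
                                     seed = seed, hyperparameters = hyper)
  }
  models
}

# Deterministic guided bipartition of a cluster: split members by the sign
# of the first principal component of their residuals from the cluster
# trajectory at each member's ML stage. Returns NULL when degenerate (one
# side empty, missing values, or no residual variance).
residual_pca_split <- function(Xm, seq, grid, sigma, members) {
  if (nrow(Xm) < 4 || anyNA(Xm)) return(NULL)
  E <- expected_matrix(seq, grid)
  ctx <- ll_context(Xm, sigma)
  M <- ctx_stage_loglik(ctx, E)
  ml_stage <- max.col(M, ties.method = "first")
  R <- Xm - t(E)[ml_stage, , drop = FALSE]
  if (all(abs(R - rep(colMeans(R), each = nrow(R))) < 1e-12)) return(NULL)
  pc <- tryCatch(stats::prcomp(R, center = TRUE, scale. = FALSE),
                 error = function(e) NULL)
  if (is.null(pc)) return(NULL)
  side <- pc$x[, 1] > 0
  if (all(side) || !any(side)) return(NULL)
  list(members[side], members[!side])
}

#' Mixture log-likelihood of data under a fitted model
#'
#' `sum_j log( sum_c f_c * (1/(N+1)) * sum_k L_j(k | S_c) )`, the quantity
#' cross-validation holds out.
#'
#' @param model A `sustain_model`.
#' @param data Z-scored biomarker table or matrix.
#' @param per_subject If `TRUE`, return the per-subject vector instead of
#'   the sum.
#' @return Total (or per-subject) log-likelihood.
#' @export
model_log_likelihood <- function(model, data, per_subject = FALSE) {
  X <- as_z_matrix(data, biomarkers = attr(model$grid, "biomarkers"))
  M <- mixture_loglik_matrix(X, model$sequences, model$grid, model$sigma)
  lw <- sweep(M, 2, log(model$fractions), "+")
  tot <- row_logsumexp(lw)
  if (per_subject) tot else sum(tot)
}

# MCMC ------------------------------------------------------------------

#' Positional uncertainty of event sequences by Metropolis-Hastings
#'
#' Samples subtype sequences by proposing swaps of two event positions
#' (rejecting proposals that violate the within-biomarker level order) and
#' accepting by the mixture-likelihood ratio with fractions held fixed. The
#' positional variance diagram (PVD) records, per subtype, the empirical
#' probability that each event occupies each sequence position; the first
#' 10% of samples are discarded as burn-in.
#'
#' @param data Z-scored baseline biomarker table or matrix.
#' @param model A fitted `sustain_model` (the chain starts from its ML
#'   sequences).
#' @param n_samples Number of MCMC iterations (>= 1).
#' @param seed Integer seed.
#' @return A `sustain_pvd`: list with `pvd` (per subtype, an N x N row-
#'   stochastic matrix, rows = events, columns = positions), the grid, the
#'   acceptance rate and the retained sample count.
#' @export
mcmc_positional_uncertainty <- function(data, model, n_samples = 10000,
                                        seed = NULL) {
  if (n_samples < 1) abort_msg("n_samples must be >= 1")
  grid <- model$grid
  X <- as_z_matrix(data, biomarkers = attr(grid, "biomarkers"))
  sigma <- model$sigma
  C <- model$n_subtypes
  N <- nrow(grid)
  seqs <- model$sequences
  ctx <- ll_context(X, sigma)
  cur_M <- mixture_loglik_matrix(X, seqs, grid, sigma, ctx = ctx)
  cur_ll <- mixture_eval(cur_M, model$fractions)$log_likelihood

  counts <- lapply(seq_len(C), function(i) matrix(0, N, N))
  burn <- floor(0.1 * n_samples)
  accepted <- 0L

  with_seed(seed, {
    for (it in seq_len(n_samples)) {
      c_i <- if (C > 1) sample.int(C, 1) else 1L
      pos <- sample.int(N, 2)
      prop <- seqs[[c_i]]
      prop[pos] <- prop[rev(pos)]
      if (is_valid_sequence(prop, grid)) {
        new_M <- cur_M
        new_M[, c_i] <- ctx_marginal_loglik(ctx, prop, grid)
        new_ll <- mixture_eval(new_M, model$fractions)$log_likelihood
        if (log(stats::runif(1)) < new_ll - cur_ll) {
          seqs[[c_i]] <- prop
          cur_M <- new_M
          cur_ll <- new_ll
          accepted <- accepted + 1L
        }
      }
      if (it > burn) {
        for (ci in seq_len(C)) {
          p <- match(seq_len(N), seqs[[ci]])
          counts[[ci]][cbind(seq_len(N), p)] <-
            counts[[ci]][cbind(seq_len(N), p)] + 1
        }
      }
    }
  })
  kept <- n_samples - burn
  ev_names <- paste0(grid$biomarker, ".z", grid$level)
  pvd <- lapply(counts, function(m) {
    m <- m / kept
    dimnames(m) <- list(ev_names, paste0("pos", seq_len(N)))
    m
  })
  structure(list(pvd = pvd, grid = grid, n_samples = kept,
                 acceptance_rate = accepted / n_samples),
            class = "sustain_pvd")
}

#' @export
print.sustain_pvd <- function(x, ...) {
  cat("Positional variance diagram:", length(x$pvd), "subtype(s),",
      nrow(x$pvd[[1]]), "events;", x$n_samples, "retained samples",
      sprintf("(acceptance %.2f)\n", x$acceptance_rate))
  invisible(x)
}

# Assignment ------------------------------------------------------------

#' Probabilistic subtype and stage assignment of visits
#'
#' For each visit, the subtype posterior is proportional to
#' `f_c * (1/(N+1)) * sum_k L(k | S_c)`; the stage posterior is conditional
#' on the maximum-likelihood subtype. Ties in the argmax resolve to the
#' first (lowest) index.
#'
#' @param model A fitted `sustain_model`.
#' @param z_table Z-scored biomarker table (any number of visits), or a
#'   matrix / plain data frame of z values.
#' @return A tibble with one row per visit: `subject_id`, `visit_index`
#'   (when present in the input), `ml_subtype`, `subtype_probability` (the
#'   max posterior), per-subtype posterior columns `p_subtype_<c>`,
#'   `ml_stage`, `expected_stage`, and a list column `stage_posterior`.
#' @export
assign_visits <- function(model, z_table) {
  grid <- model$grid
  X <- as_z_matrix(z_table, biomarkers = attr(grid, "biomarkers"))
  if (nrow(X) == 0 || ncol(X) == 0) abort_msg("empty z input")
  C <- model$n_subtypes
  N <- nrow(grid)
  stage_ll <- lapply(model$sequences, function(s) {
    stage_loglik_matrix(X, expected_matrix(s, grid), model$sigma)
  })
  marg <- vapply(stage_ll, function(m) row_logsumexp(m) - log(N + 1),
                 numeric(nrow(X)))
  marg <- matrix(marg, nrow = nrow(X))
  lw <- sweep(marg, 2, log(model$fractions), "+")
  post <- exp(lw - row_logsumexp(lw))
  ml_subtype <- max.col(post, ties.method = "first")

  stage_post <- matrix(NA_real_, nrow(X), N + 1)
  for (c in seq_len(C)) {
    rows <- which(ml_subtype == c)
    if (length(rows) > 0) {
      m <- stage_ll[[c]][rows, , drop = FALSE]
      stage_post[rows, ] <- exp(m - row_logsumexp(m))
    }
  }
  ml_stage <- max.col(stage_post, ties.method = "first") - 1L
  expected_stage <- drop(stage_post %*% (0:N))

  out <- tibble::tibble(
    ml_subtype = ml_subtype,
    subtype_probability = post[cbind(seq_len(nrow(X)), ml_subtype)],
    ml_stage = ml_stage,
    expected_stage = expected_stage,
    stage_posterior = lapply(seq_len(nrow(X)), function(i) stage_post[i, ])
  )
  for (c in seq_len(C)) out[[paste0("p_subtype_", c)]] <- post[, c]
  if (is.data.frame(z_table) && all(c("subject_id", "visit_index") %in%
                                    names(z_table))) {
    out <- dplyr::bind_cols(
      tibble::tibble(subject_id = as.character(z_table$subject_id),
                     visit_index = as.integer(z_table$visit_index)),
      out
    )
  }
  out
}

#' Assign a single visit
#'
#' @inheritParams assign_visits
#' @param z Named numeric vector of z values for one visit.
#' @return A one-row tibble as in [assign_visits()].
#' @export
assign_visit <- function(model, z) {
  assign_visits(model, matrix(z, nrow = 1,
                              dimnames = list(NULL, names(z))))
}

#' Name subtypes by where deep-gray-matter atrophy falls in the sequence
#'
#' With two subtypes, the one whose deep-gray-matter (DGM) events occupy
#' earlier mean sequence positions is labeled `"DGM-first"`, the other
#' `"cortex-first"`. Exact ties are broken by the mean position of the
#' lesion-volume events (earlier lesion accrual goes with the DGM-first
#' pattern), with a warning. A one-subtype model gets the single label
#' `"undifferentiated"` with a warning.
#'
#' @param model A fitted `sustain_model` with 1 or 2 subtypes.
#' @param dgm_biomarkers,cortical_biomarkers Names partitioning the grid's
#'   gray-matter biomarkers.
#' @param lesion_biomarker Optional lesion-volume biomarker name (used only
#'   to break ties).
#' @return A tibble with columns `subtype` and `label`.
#' @export
label_subtypes <- function(model, dgm_biomarkers, cortical_biomarkers,
                           lesion_biomarker = NULL) {
  grid <- model$grid
  bms <- attr(grid, "biomarkers")
  unknown <- setdiff(c(dgm_biomarkers, cortical_biomarkers), bms)
  if (length(unknown) > 0) {
    abort_msg("biomarker(s) not in grid: ", paste(unknown, collapse = ", "))
  }
  if (model$n_subtypes == 1) {
    warning("single-subtype model: labeling as 'undifferentiated'",
            call. = FALSE)
    return(tibble::tibble(subtype = 1L, label = "undifferentiated"))
  }
  if (model$n_subtypes != 2) {
    abort_msg("subtype labeling is defined for 1- or 2-subtype models")
  }
  mean_pos <- function(s, set) {
    ids <- grid$event_id[grid$biomarker %in% set]
    mean(match(ids, s))
  }
  dgm_pos <- vapply(model$sequences, mean_pos, numeric(1), set = dgm_biomarkers)
  if (dgm_pos[1] == dgm_pos[2]) {
    warning("tied mean DGM event positions; breaking tie by lesion events",
            call. = FALSE)
    if (!is.null(lesion_biomarker) && lesion_biomarker %in% bms) {
      les <- vapply(model$sequences, mean_pos, numeric(1),
                    set = lesion_biomarker)
      first <- which.min(les)
    } else {
      first <- 1L
    }
  } else {
    first <- which.min(dgm_pos)
  }
  labels <- rep("cortex-first", 2)
  labels[first] <- "DGM-first"
  tibble::tibble(subtype = 1:2, label = labels)
}
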