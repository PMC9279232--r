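# Independent oracle implementations, written with explicit loops and no
# shared code with the package, used to validate the package's likelihood,
# optimizer, MCMC posterior and agreement statistics.

# Expected z of one biomarker at stage k, by direct segment search through
# the anchors (0,0), (position, level)..., (N, z_max).
oracle_expected_value <- function(positions, levels, z_max, N, k) {
  xs <- c(0, positions)
  ys <- c(0, levels)
  if (max(xs) < N) {
    xs <- c(xs, N)
    ys <- c(ys, z_max)
  }
  if (k >= xs[length(xs)]) return(ys[length(ys)])
  for (t in seq_len(length(xs) - 1)) {
    if (k >= xs[t] && k <= xs[t + 1]) {
      return(ys[t] + (ys[t + 1] - ys[t]) * (k - xs[t]) / (xs[t + 1] - xs[t]))
    }
  }
  stop("stage outside anchor range")
}

# Brute-force marginal log-likelihood: explicit loops over subjects, stages
# and biomarkers; uniform stage prior.
oracle_sequence_loglik <- function(X, events, seq_ids, z_max, sigma) {
  N <- length(seq_ids)
  bms <- colnames(X)
  total <- 0
  for (j in seq_len(nrow(X))) {
    stage_liks <- numeric(N + 1)
    for (k in 0:N) {
      p <- 1
      for (b in bms) {
        x <- X[j, b]
        if (is.na(x)) next
        ids <- events$event_id[events$biomarker == b]
        positions <- numeric(0)
        for (id in ids) positions <- c(positions, which(seq_ids == id))
        mu <- oracle_expected_value(positions,
                                    events$level[events$biomarker == b],
                                    z_max[[b]], N, k)
        s <- if (length(sigma) == 1) sigma else sigma[[b]]
        p <- p * stats::dnorm(x, mu, s)
      }
      stage_liks[k + 1] <- p
    }
    total <- total + log(mean(stage_liks))
  }
  total
}

# All permutations of a vector, recursively.
oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# All orderings of the events that keep each biomarker's levels ascending.
oracle_valid_sequences <- function(events) {
  perms <- oracle_permutations(events$event_id)
  keep <- list()
  for (p in perms) {
    ok <- TRUE
    for (b in unique(events$biomarker)) {
      ids <- events$event_id[events$biomarker == b]
      pos <- numeric(0)
      for (id in ids) pos <- c(pos, which(p == id))
      if (length(pos) > 1 && any(diff(pos) <= 0)) { ok <- FALSE; break }
    }
    if (ok) keep[[length(keep) + 1]] <- p
  }
  keep
}

# Nominal Krippendorff's alpha by the pairwise-disagreement formulation.
oracle_kripp_alpha <- function(units) {
  m_u <- vapply(units, length, integer(1))
  units <- units[m_u >= 2]
  vals <- unlist(units)
  n <- length(vals)
  num <- 0
  for (u in units) {
    m <- length(u)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j && u[i] != u[j]) num <- num + 1 / (m - 1)
      }
    }
  }
  d_obs <- num / n
  tab <- table(vals)
  den <- 0
  for (a in names(tab)) {
    for (b in names(tab)) {
      if (a != b) den <- den + tab[[a]] * tab[[b]]
    }
  }
  d_exp <- den / (n * (n - 1))
  1 - d_obs / d_exp
}

# Kendall's tau between the position vectors of two sequences over the same
# events.
sequence_kendall_tau <- function(seq_true, seq_fit) {
  n <- length(seq_true)
  pos_true <- match(seq_len(n), seq_true)
  pos_fit <- match(seq_len(n), seq_fit)
  stats::cor(pos_true, pos_fit, method = "kendall")
}
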