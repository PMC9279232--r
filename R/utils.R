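# Internal helpers shared across modules.

# Key (non-biomarker) columns of a per-visit biomarker table.
.bm_key_cols <- c("subject_id", "visit_index", "years_from_baseline",
                  "age_years", "sex")

#' Biomarker column names of a per-visit table
#'
#' Every column of a biomarker table that is not one of the key columns
#' (`subject_id`, `visit_index`, `years_from_baseline`, `age_years`, `sex`)
#' is treated as a biomarker.
#'
#' @param table A biomarker table (see [read_biomarker_table()]).
#' @return Character vector of biomarker column names.
#' @export
biomarker_names <- function(table) {
  setdiff(names(table), .bm_key_cols)
}

# Derive a reproducible child seed from a master seed and a stream name,
# so each stochastic stage of the pipeline draws from its own stream.
derive_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  codes <- utf8ToInt(key)
  h <- sum(as.numeric(codes) * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Row-wise log-sum-exp of a matrix, guarding against -Inf rows.
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0
  mx + log(rowSums(exp(m - mx)))
}

abort_msg <- function(...) {
  stop(paste0(...), call. = FALSE)
}
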