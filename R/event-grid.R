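# Event grid: the discrete z-score events (biomarker, level) a model orders.

new_event_grid <- function(biomarker, level, z_max) {
  grid <- tibble::tibble(
    biomarker = as.character(biomarker),
    level = as.numeric(level),
    event_id = seq_along(biomarker)
  )
  bms <- unique(grid$biomarker)
  if (length(z_max) == 1) z_max <- stats::setNames(rep(z_max, length(bms)), bms)
  z_max <- z_max[bms]
  for (b in bms) {
    lv <- grid$level[grid$biomarker == b]
    if (is.unsorted(lv, strictly = TRUE)) {
      abort_msg("levels for biomarker '", b, "' must be strictly ascending")
    }
    if (z_max[b] <= max(lv)) {
      abort_msg("z_max for '", b, "' must exceed its largest retained level")
    }
  }
  attr(grid, "z_max") <- z_max
  attr(grid, "biomarkers") <- bms
  attr(grid, "ev_by_bm") <- lapply(bms, function(b) {
    sel <- grid$biomarker == b
    list(ids = grid$event_id[sel], levels = grid$level[sel])
  })
  class(grid) <- c("event_grid", class(grid))
  grid
}

#' Build the z-score event grid from a baseline z-scored table
#'
#' Each biomarker contributes candidate events at abnormality levels
#' z = 1, 2, 3 (mild / moderate / severe). A level is retained only if at
#' least `min_fraction` of subjects reach it at baseline (the default 5%
#' rule: events reached by fewer than 5% of subjects are excluded).
#' Biomarkers with no retained level are dropped with a warning.
#'
#' @param z_table Baseline z-scored biomarker table (or a plain data frame /
#'   matrix of z values).
#' @param levels Candidate z levels, a subset of `c(1, 2, 3)`.
#' @param min_fraction Minimum fraction of subjects reaching a level for the
#'   event to be retained.
#' @param z_max Trajectory ceiling per biomarker (must exceed the largest
#'   retained level); a single number is recycled.
#' @return An `event_grid`: a tibble of `(biomarker, level, event_id)` rows
#'   ordered by biomarker then level, with attributes `z_max` and
#'   `biomarkers`. `n_events(grid)` gives the total event count.
#' @export
build_event_grid <- function(z_table, levels = c(1, 2, 3),
                             min_fraction = 0.05, z_max = 5) {
  z <- as_z_matrix(z_table)
  bms <- colnames(z)
  kept_b <- character(); kept_l <- numeric()
  dropped <- character()
  for (b in bms) {
    x <- z[, b]
    x <- x[!is.na(x)]
    keep <- levels[vapply(levels, function(l) mean(x >= l) >= min_fraction,
                          logical(1))]
    if (length(keep) == 0) {
      dropped <- c(dropped, b)
    } else {
      kept_b <- c(kept_b, rep(b, length(keep)))
      kept_l <- c(kept_l, sort(keep))
    }
  }
  if (length(dropped) > 0) {
    warning("dropping biomarker(s) with no retained z-score event: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(kept_b) == 0) abort_msg("empty event grid: no event retained")
  if (length(z_max) > 1) z_max <- z_max[unique(kept_b)]
  new_event_grid(kept_b, kept_l, z_max = z_max)
}

#' @rdname build_event_grid
#' @param grid An `event_grid`.
#' @export
n_events <- function(grid) nrow(grid)

# Coerce a biomarker table / data frame / matrix to a numeric z matrix with
# biomarker columns. Key columns are stripped when present.
as_z_matrix <- function(x, biomarkers = NULL) {
  if (is.matrix(x)) {
    m <- x
  } else {
    x <- as.data.frame(x)
    drop <- intersect(.bm_key_cols, names(x))
    m <- as.matrix(x[, setdiff(names(x), drop), drop = FALSE])
  }
  if (!is.null(biomarkers)) {
    missing <- setdiff(biomarkers, colnames(m))
    if (length(missing) > 0) {
      abort_msg("table lacks grid biomarker(s): ",
                paste(missing, collapse = ", "))
    }
    m <- m[, biomarkers, drop = FALSE]
  }
  storage.mode(m) <- "double"
  m
}

# TRUE iff, within every biomarker, event levels appear in ascending
# position order.
is_valid_sequence <- function(seq, grid) {
  pos <- match(grid$event_id, seq)
  if (anyNA(pos) || length(seq) != nrow(grid)) return(FALSE)
  for (b in attr(grid, "biomarkers")) {
    p <- pos[grid$biomarker == b]
    if (is.unsorted(p, strictly = TRUE)) return(FALSE)
  }
  TRUE
}

# Uniform draw over valid sequences: permute event slots, then fill each
# biomarker's slots with its levels in ascending order.
random_valid_sequence <- function(grid) {
  N <- nrow(grid)
  slot_of_event <- integer(N)
  perm <- sample.int(N)
  for (b in attr(grid, "biomarkers")) {
    ids <- grid$event_id[grid$biomarker == b]
    slots <- sort(perm[ids])
    slot_of_event[ids] <- slots
  }
  seq_out <- integer(N)
  seq_out[slot_of_event] <- grid$event_id
  seq_out
}
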