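#' Read and validate a per-visit biomarker table
#'
#' Reads a comma-separated file (UTF-8, `.` decimal separator) holding one row
#' per MRI visit: the keys `subject_id`, `visit_index`, `years_from_baseline`,
#' `age_years`, `sex` plus one numeric column per biomarker (volumes in mL on
#' the raw scale, dimensionless on the z-score scale). Empty cells are read as
#' missing values and stay missing downstream; the event-based likelihood
#' skips them rather than treating them as zero.
#'
#' @param path Path to a delimited text file with a header row.
#' @param scale Either `"raw"` or `"zscore"`; recorded on the returned table.
#' @return A validated tibble with attribute `scale`.
#' @seealso [validate_biomarker_table()]
#' @export
read_biomarker_table <- function(path, scale = c("raw", "zscore")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort_msg("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  validate_biomarker_table(tibble::as_tibble(raw), scale = scale)
}

#' Validate the invariants of a biomarker table
#'
#' Checks that `(subject_id, visit_index)` is unique, every subject has a
#' visit 0, `years_from_baseline` is 0 exactly at visit 0 and strictly
#' increasing across visits within a subject, `sex` is F/M, and all biomarker
#' columns are numeric. Fails with a message naming the offending key.
#'
#' @param table A data frame of per-visit rows.
#' @param scale `"raw"` or `"zscore"`, stored as an attribute.
#' @return The table as a tibble, with attribute `scale` set.
#' @export
validate_biomarker_table <- function(table, scale = c("raw", "zscore")) {
  scale <- match.arg(scale)
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(.bm_key_cols, names(table))
  if (length(missing_cols) > 0) {
    abort_msg("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  table$subject_id <- as.character(table$subject_id)
  table$visit_index <- as.integer(table$visit_index)

  key <- paste(table$subject_id, table$visit_index, sep = "/")
  if (anyDuplicated(key)) {
    abort_msg("duplicated (subject_id, visit_index) key(s): ",
              paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(table$visit_index < 0, na.rm = TRUE)) {
    abort_msg("visit_index must be >= 0")
  }

  by_subj <- split(seq_len(nrow(table)), table$subject_id)
  for (sid in names(by_subj)) {
    idx <- by_subj[[sid]]
    vi <- table$visit_index[idx]
    yrs <- table$years_from_baseline[idx]
    if (!0L %in% vi) abort_msg("subject ", sid, " has no baseline visit (visit_index 0)")
    ord <- order(vi)
    vi <- vi[ord]; yrs <- yrs[ord]
    bad0 <- xor(vi == 0L, yrs == 0)
    if (any(bad0)) {
      abort_msg("subject ", sid, ": years_from_baseline must be 0 exactly at ",
                "visit_index 0 (violated at visit ", vi[which(bad0)[1]], ")")
    }
    if (length(yrs) > 1 && any(diff(yrs) <= 0)) {
      v_bad <- vi[which(diff(yrs) <= 0)[1] + 1]
      abort_msg("subject ", sid, ": years_from_baseline not strictly ",
                "increasing at visit_index ", v_bad)
    }
  }

  if (!all(table$sex %in% c("F", "M"))) {
    abort_msg("sex must be coded F or M")
  }
  bms <- biomarker_names(table)
  for (b in bms) {
    if (!is.numeric(table[[b]])) {
      abort_msg("biomarker column '", b, "' is not numeric ",
                "(non-numeric cell or wrong type)")
    }
  }
  attr(table, "scale") <- scale
  table
}

#' Read a per-subject clinical table
#'
#' One row per subject: `subject_id`, `baseline_edss` (0-10 in 0.5 steps),
#' long-term motor and cognitive disability levels (`motor_disability_lt`,
#' `cognitive_disability_lt`, both 0-3), transition to a secondary-progressive
#' course (`sp_transition`, 0/1), disease-modifying-therapy code (`dmt_code`,
#' 0 = no therapy, 1 = interferon, 2 = glatiramer acetate, 3 = natalizumab)
#' and follow-up time in years (`fu_time_years`).
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort_msg("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  validate_clinical_table(tibble::as_tibble(raw))
}

#' @rdname read_clinical_table
#' @param table A data frame of per-subject clinical rows.
#' @export
validate_clinical_table <- function(table) {
  table <- tibble::as_tibble(table)
  if (!"subject_id" %in% names(table)) abort_msg("missing column subject_id")
  table$subject_id <- as.character(table$subject_id)
  if (anyDuplicated(table$subject_id)) {
    abort_msg("duplicated subject_id in clinical table: ",
              paste(unique(table$subject_id[duplicated(table$subject_id)]),
                    collapse = ", "))
  }
  chk_levels <- function(col, levels) {
    if (col %in% names(table)) {
      v <- table[[col]]
      bad <- !is.na(v) & !v %in% levels
      if (any(bad)) {
        abort_msg(col, " outside {", paste(levels, collapse = ","),
                  "} for subject(s) ",
                  paste(table$subject_id[bad], collapse = ", "))
      }
    }
  }
  chk_levels("motor_disability_lt", 0:3)
  chk_levels("cognitive_disability_lt", 0:3)
  chk_levels("sp_transition", 0:1)
  chk_levels("dmt_code", 0:3)
  if ("baseline_edss" %in% names(table)) {
    v <- table$baseline_edss
    bad <- !is.na(v) & (v < 0 | v > 10 | (v * 2) %% 1 != 0)
    if (any(bad)) {
      abort_msg("baseline_edss must lie in 0-10 in steps of 0.5")
    }
  }
  table
}

#' Serialize / restore a fitted subtype-and-stage model
#'
#' The artifact is a JSON file recording the event grid, the maximum-
#' likelihood subtype sequences, mixture fractions, per-biomarker noise
#' scales, hyperparameters, the random seed and the package version. Numeric
#' fields round-trip exactly; re-serializing a read artifact is
#' byte-identical.
#'
#' @param model A fitted model from [fit_sustain()].
#' @param path Destination file path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sustain_model"))
  grid <- model$grid
  art <- list(
    format = "msstratify-model",
    msstratify_version = as.character(utils::packageVersion("msstratify")),
    grid = list(
      biomarker = grid$biomarker,
      level = grid$level,
      z_max = as.list(attr(grid, "z_max"))
    ),
    n_subtypes = model$n_subtypes,
    sequences = model$sequences,
    fractions = model$fractions,
    sigma = as.list(model$sigma),
    log_likelihood = model$log_likelihood,
    seed = model$seed,
    hyperparameters = model$hyperparameters
  )
  json <- jsonlite::toJSON(art, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort_msg("file not found: ", path)
  art <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort_msg("cannot parse model artifact: ", conditionMessage(e))
  )
  if (is.null(art$format) || art$format != "msstratify-model") {
    abort_msg("not a msstratify model artifact: ", path)
  }
  cur <- as.character(utils::packageVersion("msstratify"))
  if (!identical(art$msstratify_version, cur)) {
    warning("model artifact written by msstratify ", art$msstratify_version,
            ", reading with ", cur, call. = FALSE)
  }
  grid <- new_event_grid(art$grid$biomarker, art$grid$level,
                         z_max = unlist(art$grid$z_max))
  seqs <- art$sequences
  if (is.matrix(seqs)) seqs <- lapply(seq_len(nrow(seqs)), function(i) seqs[i, ])
  seqs <- lapply(seqs, as.integer)
  new_sustain_model(
    grid = grid,
    sequences = seqs,
    fractions = as.numeric(art$fractions),
    sigma = stats::setNames(unlist(art$sigma), names(art$sigma)),
    log_likelihood = art$log_likelihood,
    seed = art$seed,
    hyperparameters = art$hyperparameters
  )
}

#' Merge visit-level assignments and subject-level clinical data
#'
#' Left-joins per-visit subtype/stage assignments and the per-subject
#' clinical table onto the visit table, producing one analysis row per MRI
#' visit. Visits without clinical data keep their biomarker fields; an
#' assignment that refers to an unknown (subject, visit) key is an error.
#'
#' @param biomarkers Per-visit biomarker table.
#' @param assignments Per-visit assignment tibble from [assign_visits()].
#' @param clinical Optional per-subject clinical table.
#' @return A tibble with one row per visit.
#' @export
merge_assignments <- function(biomarkers, assignments, clinical = NULL) {
  biomarkers <- tibble::as_tibble(biomarkers)
  assignments <- tibble::as_tibble(assignments)
  key_b <- paste(biomarkers$subject_id, biomarkers$visit_index, sep = "/")
  key_a <- paste(assignments$subject_id, assignments$visit_index, sep = "/")
  unknown <- setdiff(key_a, key_b)
  if (length(unknown) > 0) {
    abort_msg("assignment(s) for unknown visit key(s): ",
              paste(unknown, collapse = ", "))
  }
  out <- dplyr::left_join(biomarkers, assignments,
                          by = c("subject_id", "visit_index"))
  if (!is.null(clinical)) {
    clinical <- tibble::as_tibble(clinical)
    if (length(intersect(biomarkers$subject_id, clinical$subject_id)) == 0) {
      warning("no subjects in common between visit and clinical tables; ",
              "clinical columns are all missing", call. = FALSE)
    }
    out <- dplyr::left_join(out, clinical, by = "subject_id")
  }
  stopifnot(nrow(out) == nrow(biomarkers))
  out
}
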