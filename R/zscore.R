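#' Reference statistics for z-score normalization
#'
#' Computes the per-biomarker sample mean and standard deviation (n - 1
#' denominator) of a single-visit reference population, together with the
#' direction flip applied when z-scoring: `flip = -1` for volumes whose
#' decrease is pathological (gray-matter regions), `flip = +1` for lesion
#' volume, so that higher z always means worse disease.
#'
#' Gray-matter volumes are normalized against healthy controls while lesion
#' volume is normalized against an external patient population (controls
#' carry next to no lesions); fit each reference separately and bind the
#' resulting rows.
#'
#' @param reference Single-visit biomarker table of the reference population.
#' @param biomarkers Biomarker columns to summarize; defaults to all.
#' @param flip +1 or -1, recycled across biomarkers or named per biomarker.
#' @param reference_id Label for the reference population (e.g. `"HC"`,
#'   `"external_patients"`).
#' @return A tibble with columns `biomarker`, `mean`, `sd`, `flip`,
#'   `reference_id`.
#' @export
fit_reference_stats <- function(reference, biomarkers = NULL, flip = -1,
                                reference_id = "HC") {
  reference <- tibble::as_tibble(reference)
  if (is.null(biomarkers)) biomarkers <- biomarker_names(reference)
  if ("visit_index" %in% names(reference) &&
      any(reference$visit_index != 0L)) {
    abort_msg("reference population must be single-visit (baseline only)")
  }
  if (nrow(reference) < 2) abort_msg("reference needs at least 2 subjects")
  if (length(flip) == 1) flip <- stats::setNames(rep(flip, length(biomarkers)),
                                                 biomarkers)
  if (!all(biomarkers %in% names(flip))) {
    abort_msg("flip must cover every biomarker")
  }
  if (!all(flip %in% c(-1, 1))) abort_msg("flip entries must be +1 or -1")

  purrr::map_dfr(biomarkers, function(b) {
    x <- reference[[b]]
    if (is.null(x)) abort_msg("biomarker '", b, "' not in reference table")
    x <- x[!is.na(x)]
    if (length(x) < 2) abort_msg("biomarker '", b, "' has < 2 reference values")
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      abort_msg("biomarker '", b, "' has zero variance in the reference")
    }
    tibble::tibble(biomarker = b, mean = mean(x), sd = s,
                   flip = unname(flip[b]), reference_id = reference_id)
  })
}

#' Z-score a raw biomarker table against reference statistics
#'
#' Applies `z = flip * (x - mean) / sd` per biomarker; missing raw values
#' stay missing. The result carries `scale = "zscore"`.
#'
#' @param table Raw-scale biomarker table.
#' @param stats Reference statistics from [fit_reference_stats()] (rows for
#'   several references may be bound together; each biomarker must appear
#'   exactly once).
#' @return The z-scored table.
#' @export
apply_zscore <- function(table, stats) {
  table <- tibble::as_tibble(table)
  bms <- biomarker_names(table)
  missing <- setdiff(bms, stats$biomarker)
  if (length(missing) > 0) {
    abort_msg("no reference statistics for biomarker(s): ",
              paste(missing, collapse = ", "))
  }
  if (anyDuplicated(stats$biomarker)) {
    abort_msg("duplicate reference rows for biomarker(s): ",
              paste(unique(stats$biomarker[duplicated(stats$biomarker)]),
                    collapse = ", "))
  }
  out <- table
  for (b in bms) {
    row <- stats[stats$biomarker == b, ]
    out[[b]] <- row$flip * (table[[b]] - row$mean) / row$sd
  }
  attr(out, "scale") <- "zscore"
  out
}

#' Cohen's f effect size for a two-group comparison
#'
#' Computes `f = sqrt(eta2_partial / (1 - eta2_partial))` for the group
#' effect in a linear model, optionally adjusting for covariates (age, sex,
#' total intracranial volume, ...). Without covariates this is the classical
#' one-way ANOVA effect size; for two equal-sized groups it equals |d| / 2
#' where d is the pooled standardized mean difference.
#'
#' @param ms_values Numeric vector for the patient group.
#' @param hc_values Numeric vector for the control group.
#' @param covariates Optional data frame of covariates, stacked in the same
#'   order (`ms_values` rows first, then `hc_values` rows).
#' @return A single non-negative number.
#' @export
cohens_f <- function(ms_values, hc_values, covariates = NULL) {
  ms_values <- ms_values[!is.na(ms_values)]
  hc_values <- hc_values[!is.na(hc_values)]
  if (is.null(covariates)) {
    if (length(ms_values) < 2 || length(hc_values) < 2) {
      abort_msg("need at least 2 observations per group")
    }
    y <- c(ms_values, hc_values)
    g <- factor(rep(c("MS", "HC"), c(length(ms_values), length(hc_values))))
    full <- stats::lm(y ~ g)
    reduced <- stats::lm(y ~ 1)
  } else {
    covariates <- as.data.frame(covariates)
    y <- c(ms_values, hc_values)
    if (nrow(covariates) != length(y)) {
      abort_msg("covariates must have one row per observation")
    }
    g <- factor(rep(c("MS", "HC"), c(length(ms_values), length(hc_values))))
    dat <- cbind(data.frame(.y = y, .g = g), covariates)
    full <- stats::lm(.y ~ ., data = dat)
    reduced <- stats::lm(.y ~ . - .g, data = dat)
  }
  ss_res <- sum(stats::residuals(full)^2)
  ss_grp <- sum(stats::residuals(reduced)^2) - ss_res
  ss_grp <- max(ss_grp, 0)
  if (ss_res <= .Machine$double.eps * sum(y^2)) {
    abort_msg("zero residual variance: Cohen's f is infinite")
  }
  sqrt(ss_grp / ss_res)
}

#' Select biomarkers by effect size against healthy controls
#'
#' Retains every gray-matter region whose volume shows a moderate-to-large
#' difference between patients and controls (Cohen's f strictly greater than
#' `threshold`, default 0.25) plus any always-included biomarkers (lesion
#' volume, which has no meaningful control reference).
#'
#' @param ms_baseline Patient biomarker table; only baseline visits
#'   (`visit_index == 0`) enter the comparison.
#' @param hc Healthy-control biomarker table.
#' @param threshold Effect-size threshold; selection requires `f > threshold`.
#' @param always_include Biomarkers selected regardless of effect size.
#' @param covariates Optional named list with entries `ms` and `hc`, each a
#'   data frame of per-subject covariates for adjusted effect sizes.
#' @return A tibble with columns `biomarker`, `cohens_f`, `always_included`,
#'   `selected`.
#' @export
select_biomarkers <- function(ms_baseline, hc, threshold = 0.25,
                              always_include = character(),
                              covariates = NULL) {
  ms_baseline <- tibble::as_tibble(ms_baseline)
  hc <- tibble::as_tibble(hc)
  if ("visit_index" %in% names(ms_baseline)) {
    ms_baseline <- dplyr::filter(ms_baseline, .data$visit_index == 0L)
  }
  shared <- intersect(biomarker_names(ms_baseline), biomarker_names(hc))
  candidates <- setdiff(shared, always_include)
  cov_df <- NULL
  if (!is.null(covariates)) {
    cov_df <- rbind(as.data.frame(covariates$ms), as.data.frame(covariates$hc))
  }
  report <- purrr::map_dfr(candidates, function(b) {
    f <- cohens_f(ms_baseline[[b]], hc[[b]], covariates = cov_df)
    tibble::tibble(biomarker = b, cohens_f = f, always_included = FALSE,
                   selected = f > threshold)
  })
  if (length(always_include) > 0) {
    extra <- purrr::map_dfr(always_include, function(b) {
      f <- if (b %in% shared) {
        cohens_f(ms_baseline[[b]], hc[[b]], covariates = cov_df)
      } else {
        NA_real_
      }
      tibble::tibble(biomarker = b, cohens_f = f, always_included = TRUE,
                     selected = TRUE)
    })
    report <- dplyr::bind_rows(report, extra)
  }
  if (!any(report$selected)) {
    abort_msg("no biomarker passes the effect-size threshold and ",
              "always_include is empty")
  }
  report
}
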