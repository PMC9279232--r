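# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a positional variance diagram
#'
#' Heatmap of the posterior probability that each z-score event occupies
#' each sequence position, faceted by subtype; the classical display of
#' sequence uncertainty for event-based progression models.
#'
#' @param object A `sustain_pvd` from [mcmc_positional_uncertainty()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sustain_pvd <- function(object, ...) {
  d <- tidy(object)
  d$event <- factor(d$event, levels = rev(rownames(object$pvd[[1]])))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$event,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::facet_wrap(~subtype, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sequence position", y = NULL,
                  fill = "P(event at position)") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation model-selection curve
#'
#' Mean held-out per-subject log-likelihood against the number of subtypes,
#' with one-SD error bars across folds.
#'
#' @param object A `sustain_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sustain_cv <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_subtypes,
                                  y = .data$mean_heldout_loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_heldout_loglik - .data$sd_heldout_loglik,
      ymax = .data$mean_heldout_loglik + .data$sd_heldout_loglik)) +
    ggplot2::scale_x_continuous(breaks = d$n_subtypes) +
    ggplot2::labs(x = "number of subtypes",
                  y = "held-out log-likelihood per subject") +
    ggplot2::theme_minimal()
}

#' Plot the expected biomarker trajectories of a fitted model
#'
#' Piecewise-linear expected z-score of each biomarker against stage, one
#' panel per subtype.
#'
#' @param object A `sustain_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sustain_model <- function(object, ...) {
  grid <- object$grid
  N <- n_events(grid)
  d <- purrr::map_dfr(seq_len(object$n_subtypes), function(c) {
    E <- expected_matrix(object$sequences[[c]], grid)
    tibble::tibble(
      subtype = c,
      biomarker = rep(rownames(E), ncol(E)),
      stage = rep(0:N, each = nrow(E)),
      expected_z = as.vector(E)
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$expected_z,
                                  colour = .data$biomarker)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~subtype, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "stage", y = "expected z-score") +
    ggplot2::theme_minimal()
}
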