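# ggplot2 displays for the result types

#' @importFrom ggplot2 ggplot aes geom_point geom_abline geom_line geom_col
#'   geom_histogram geom_vline labs facet_wrap coord_equal theme_minimal
NULL

#' Plot observed versus predicted activity for a PLS fit
#'
#' @param object A `qsar_pls` fit.
#' @param loo Use leave-one-out predictions when available (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qsar_pls <- function(object, loo = TRUE, ...) {
  df <- augment(object)
  use_loo <- loo && "loo_predicted" %in% names(df)
  df$predicted <- if (use_loo) df$loo_predicted else df$fitted
  ggplot(df, aes(x = .data$observed, y = .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(aes(colour = .data$outlier)) +
    coord_equal() +
    labs(x = "observed pIC50",
         y = if (use_loo) "LOO-predicted pIC50" else "fitted pIC50",
         title = sprintf("PLS %s (N = %d, q2 = %.2f, r2 = %.2f)",
                         paste(object$fields, collapse = ""),
                         object$n_components,
                         object$q2, object$r2_ncv)) +
    theme_minimal()
}

#' Plot a model-search table as ranked q2 bars
#'
#' @param object A `qsar_model_search` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qsar_model_search <- function(object, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$q2))
  df$combination <- stats::reorder(df$combination, df$q2)
  ggplot(df, aes(x = .data$combination, y = .data$q2)) +
    geom_col(fill = "steelblue") +
    geom_hline_q2() +
    labs(x = "field combination", y = "LOO q2") +
    theme_minimal()
}

geom_hline_q2 <- function() ggplot2::geom_hline(yintercept = 0.5, linetype = 2)

#' Plot the scrambled-response null distribution
#'
#' Histogram of q2 under Y-randomization with the real model's q2 marked.
#'
#' @param object A `qsar_randomization` object.
#' @param observed_q2 Optional q2 of the unscrambled model.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.qsar_randomization <- function(object, observed_q2 = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$q2)) +
    geom_histogram(bins = 20, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = 0.5, linetype = 2) +
    labs(x = "q2 of scrambled models", y = "count") +
    theme_minimal()
  if (!is.null(observed_q2)) {
    p <- p + geom_vline(xintercept = observed_q2, colour = "red")
  }
  p
}

#' Plot a q2-versus-components selection profile
#'
#' @param profile The `profile` tibble from [select_components()].
#' @return A ggplot.
#' @export
plot_q2_profile <- function(profile) {
  ggplot(profile, aes(x = .data$ncomp, y = .data$q2)) +
    geom_line() + geom_point() +
    labs(x = "latent components N", y = "LOO q2") +
    theme_minimal()
}

#' Plot a contour slice
#'
#' Scatter of favoured/disfavoured lattice points projected on two axes,
#' faceted by field block.
#'
#' @param contours A `qsar_contours` tibble.
#' @param axes Two of "x", "y", "z" (default x, y).
#' @return A ggplot.
#' @export
plot_contours <- function(contours, axes = c("x", "y")) {
  ggplot(contours, aes(x = .data[[axes[1]]], y = .data[[axes[2]]],
                       colour = .data$class, size = abs(.data$product))) +
    geom_point(alpha = 0.7) +
    facet_wrap(~block) +
    ggplot2::scale_colour_manual(values = c(favored = "forestgreen",
                                            disfavored = "firebrick")) +
    coord_equal() +
    labs(x = paste0(axes[1], " (A)"), y = paste0(axes[2], " (A)")) +
    theme_minimal()
}
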