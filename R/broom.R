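# broom-style accessors for the fitted objects

#' @describeIn fit_pls `tidy()` returns one row per retained descriptor:
#'   column id, field block, lattice position, raw-unit coefficient and the
#'   coefficient-times-sd contour product.
#' @param x A `qsar_pls` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_pls <- function(x, ...) {
  out <- x$columns
  out$estimate <- unname(x$coefficients)
  out$estimate_scaled <- unname(x$coefficients_scaled)
  out$product <- unname(x$coefficients_scaled * x$col_sd_scaled)
  out
}

#' @describeIn fit_pls `glance()` returns the one-row model summary
#'   (q2, r2_ncv, SEE, PRESS, N, n).
#' @exportS3Method generics::glance
glance.qsar_pls <- function(x, ...) {
  tibble(n = length(x$y), n_components = x$n_components,
         q2 = x$q2, r2_ncv = x$r2_ncv, see = x$see, press = x$press)
}

#' @describeIn fit_pls `augment()` returns per-compound observed, fitted,
#'   LOO-predicted values, residuals and the one-log-unit outlier flag.
#' @exportS3Method generics::augment
augment.qsar_pls <- function(x, ...) {
  out <- tibble(compound_id = x$training_ids,
                observed = unname(x$y),
                fitted = unname(x$fitted),
                residual = unname(x$y - x$fitted))
  if (!is.null(x$loo_pred)) {
    out$loo_predicted <- unname(x$loo_pred)
    out$loo_residual <- out$observed - out$loo_predicted
  }
  out$outlier <- abs(out$residual) > 1
  out
}

#' @describeIn external_metrics `tidy()` returns the Golbraikh-Tropsha
#'   condition table; pass `q2` for the internal-validation condition
#'   (otherwise that row is dropped).
#' @param x A `qsar_external` object.
#' @param q2 Internal q^2 to evaluate the first condition.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_external <- function(x, q2 = NA_real_, ...) {
  flags <- gt_conditions(x, q2)
  if (is.na(q2)) flags <- flags[-1, ]
  flags
}

#' @describeIn external_metrics `glance()` returns the metrics as one row.
#' @exportS3Method generics::glance
glance.qsar_external <- function(x, ...) {
  tibble(n = x$n, r2_test = x$r2_test, r2_0 = x$r2_0,
         r2_0_prime = x$r2_0_prime, k = x$k, k_prime = x$k_prime, rm2 = x$rm2)
}

#' @describeIn y_randomization `tidy()` returns the per-iteration q2 and
#'   r2_ncv values.
#' @param x A `qsar_randomization` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qsar_randomization <- function(x, ...) x$iterations

#' @describeIn y_randomization `glance()` summarises the scrambled-model
#'   distribution and the pass flag.
#' @exportS3Method generics::glance
glance.qsar_randomization <- function(x, ...) {
  tibble(n_iterations = x$n_iterations,
         max_q2 = max(x$iterations$q2),
         median_q2 = stats::median(x$iterations$q2),
         max_r2_ncv = max(x$iterations$r2_ncv),
         frac_q2_below_0.5 = mean(x$iterations$q2 < 0.5),
         pass = x$pass)
}
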