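#' External-set validation metrics
#'
#' Computes the quantities behind the Golbraikh-Tropsha predictivity battery
#' for a held-out test set: the ordinary squared correlation `r2_test`, the
#' through-origin slopes `k = sum(y * yhat) / sum(yhat^2)` and
#' `k' = sum(y * yhat) / sum(y^2)`, the through-origin determination
#' coefficients `r2_0` (observed regressed on predicted) and `r2_0_prime`
#' (predicted regressed on observed), and Roy's `rm2` metric.
#'
#' @param y_obs,y_pred Observed and predicted activities for at least three
#'   test compounds; neither may be constant.
#' @return A `qsar_external` object (list with `r2_test`, `r2_0`,
#'   `r2_0_prime`, `k`, `k_prime`, `rm2`, `n`).
#' @export
external_metrics <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) abort("Observed and predicted vectors differ in length.")
  if (length(y_obs) < 3) abort("External validation needs at least 3 test compounds.")
  if (stats::sd(y_obs) < 1e-12 || stats::sd(y_pred) < 1e-12) {
    abort("Observed and predicted values must both be non-constant.")
  }
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  r2_0 <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r2_0_prime <- 1 - sum((y_pred - k_prime * y_obs)^2) / sum((y_pred - mean(y_pred))^2)
  r2_test <- stats::cor(y_obs, y_pred)^2
  structure(list(r2_test = r2_test, r2_0 = r2_0, r2_0_prime = r2_0_prime,
                 k = k, k_prime = k_prime,
                 rm2 = rm2(r2_test, r2_0), n = length(y_obs)),
            class = "qsar_external")
}

#' @export
print.qsar_external <- function(x, ...) {
  cat(sprintf("<qsar_external> n = %d | r2_test = %.3f, r2_0 = %.3f, r2_0' = %.3f, k = %.3f, k' = %.3f, rm2 = %.3f\n",
              x$n, x$r2_test, x$r2_0, x$r2_0_prime, x$k, x$k_prime, x$rm2))
  invisible(x)
}

#' Roy's rm2 metric
#'
#' `rm2 = r2_test * (1 - sqrt(r2_test - r2_0))`, penalising divergence
#' between the ordinary and the through-origin determination coefficients.
#' When `r2_0 > r2_test` the absolute difference is used under the root.  A
#' predictive model should have `rm2 > 0.5`.
#'
#' @param r2_test,r2_0 Values in \[0, 1\].
#' @return The rm2 value.
#' @export
rm2 <- function(r2_test, r2_0) {
  if (any(r2_test < 0 | r2_test > 1) || any(r2_0 > 1)) {
    abort("`r2_test` must be in [0, 1] and `r2_0` cannot exceed 1.")
  }
  r2_test * (1 - sqrt(abs(r2_test - r2_0)))
}

#' Golbraikh-Tropsha condition flags
#'
#' Evaluates the predictivity conditions:
#' internal `q2 > 0.5`; external `r2_test > 0.6`;
#' `(r2_test - r2_0)/r2_test < 0.1` or the primed analogue;
#' `0.85 <= k <= 1.15` or `0.85 <= k' <= 1.15`;
#' `|r2_0 - r2_0'| < 0.3`; and, reported alongside, `rm2 > 0.5`.
#' The overall verdict requires all of the slope/correlation conditions; the
#' rm2 check is reported as its own flag.
#'
#' @param ev A `qsar_external` object.
#' @param q2 Internal LOO q^2 of the model.
#' @return Tibble of condition flags plus attributes `verdict` (all
#'   correlation/slope conditions true) and `rm2_pass`.
#' @export
gt_conditions <- function(ev, q2) {
  stopifnot(inherits(ev, "qsar_external"))
  flags <- tibble(
    condition = c("q2 > 0.5", "r2_test > 0.6",
                  "(r2_test - r2_0)/r2_test < 0.1 or primed",
                  "0.85 <= k <= 1.15 or 0.85 <= k' <= 1.15",
                  "|r2_0 - r2_0'| < 0.3",
                  "rm2 > 0.5"),
    value = c(q2, ev$r2_test,
              min((ev$r2_test - ev$r2_0) / ev$r2_test,
                  (ev$r2_test - ev$r2_0_prime) / ev$r2_test),
              ev$k, abs(ev$r2_0 - ev$r2_0_prime), ev$rm2),
    pass = c(q2 > 0.5,
             ev$r2_test > 0.6,
             (ev$r2_test - ev$r2_0) / ev$r2_test < 0.1 ||
               (ev$r2_test - ev$r2_0_prime) / ev$r2_test < 0.1,
             (ev$k >= 0.85 && ev$k <= 1.15) ||
               (ev$k_prime >= 0.85 && ev$k_prime <= 1.15),
             abs(ev$r2_0 - ev$r2_0_prime) < 0.3,
             ev$rm2 > 0.5)
  )
  attr(flags, "verdict") <- all(flags$pass[1:5])
  attr(flags, "rm2_pass") <- flags$pass[6]
  flags
}

#' Y-randomization (response scrambling) test
#'
#' The activity vector is permuted without replacement and the PLS model
#' refit with the original component count; chance correlation is excluded
#' when the scrambled models are consistently poor (`q2 < 0.5` and
#' `r2_ncv < 0.6` in every iteration).
#'
#' @inheritParams fit_pls
#' @param n_iterations Number of permutations (default 50).
#' @param seed Integer seed; the permutation stream is reproducible.
#' @return A `qsar_randomization` object: per-iteration tibble
#'   (`iteration`, `q2`, `r2_ncv`) and a `pass` flag.
#' @export
y_randomization <- function(fm, y, ncomp, n_iterations = 50, seed = 1) {
  if (n_iterations < 1) abort("`n_iterations` must be at least 1.")
  y <- align_y(fm, y)
  ids <- names(y)
  res <- withr::with_seed(seed, {
    purrr::map(seq_len(n_iterations), function(it) {
      yp <- setNames(sample(y), ids)
      fit <- fit_pls(fm, yp, ncomp, cv = FALSE)
      cv <- loo_q2(fm, yp, ncomp)
      tibble(iteration = it, q2 = cv$q2, r2_ncv = fit$r2_ncv)
    })
  })
  iterations <- bind_rows(res)
  structure(list(iterations = iterations,
                 n_iterations = n_iterations,
                 pass = all(iterations$q2 < 0.5 & iterations$r2_ncv < 0.6),
                 seed = seed),
            class = "qsar_randomization")
}

#' @export
print.qsar_randomization <- function(x, ...) {
  cat(sprintf("<qsar_randomization> %d permutations | max q2 = %.3f, max r2_ncv = %.3f | %s\n",
              x$n_iterations, max(x$iterations$q2), max(x$iterations$r2_ncv),
              if (x$pass) "PASS (no chance correlation)" else "FAIL"))
  invisible(x)
}

#' Flag prediction outliers
#'
#' Compounds whose absolute residual exceeds one logarithmic activity unit
#' (strict inequality; a residual of exactly 1.0 is not flagged).
#'
#' @param y_obs,y_pred Matched activity vectors; names (or
#'   `ids`) identify compounds.
#' @param ids Optional compound ids (defaults to names of `y_obs`).
#' @param threshold Residual threshold in log units (default 1).
#' @return Character vector of flagged compound ids.
#' @export
flag_outliers <- function(y_obs, y_pred, ids = names(y_obs), threshold = 1) {
  if (length(y_obs) != length(y_pred)) abort("Vectors differ in length.")
  if (is.null(ids)) ids <- as.character(seq_along(y_obs))
  ids[abs(y_obs - y_pred) > threshold]
}
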