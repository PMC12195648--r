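# --- NIPALS PLS1 core -------------------------------------------------------
# X, y must be centred (X additionally block-scaled upstream).  Returns
# weights W, loadings P, scores T, y-loadings q, truncated at numerical rank.
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp)
  Xk <- X; yk <- y
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xk, yk)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-10) break
    w <- w / wn
    t <- drop(Xk %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pk <- drop(crossprod(Xk, t)) / tt
    qk <- sum(yk * t) / tt
    Xk <- Xk - tcrossprod(t, pk)
    yk <- yk - qk * t
    a <- k
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- t; qv[k] <- qk
  }
  if (a == 0L) abort("PLS found no usable component (descriptors uncorrelated with y?).")
  list(W = W[, seq_len(a), drop = FALSE], P = P[, seq_len(a), drop = FALSE],
       T = Tm[, seq_len(a), drop = FALSE], q = qv[seq_len(a)], ncomp = a)
}

# regression coefficients (centred/scaled space) using the first `a` components
nipals_coef <- function(np, a) {
  Wa <- np$W[, seq_len(a), drop = FALSE]
  Pa <- np$P[, seq_len(a), drop = FALSE]
  Ra <- Wa %*% solve(crossprod(Pa, Wa))
  drop(Ra %*% np$q[seq_len(a)])
}

align_y <- function(fm, y) {
  ids <- rownames(fm$values)
  if (is.data.frame(y)) {
    act <- activity_table(y)
    idx <- match(ids, act$compound_id)
    if (anyNA(idx)) abort("Activity table is missing some compounds in the field matrix.")
    return(setNames(act$pic50[idx], ids))
  }
  if (!is.numeric(y)) abort("`y` must be numeric or an activity table.")
  if (!is.null(names(y))) {
    idx <- match(ids, names(y))
    if (anyNA(idx)) abort("Names of `y` do not cover the field-matrix compounds.")
    return(y[idx])
  }
  if (length(y) != nrow(fm$values)) abort("`y` length does not match the number of compounds.")
  setNames(y, ids)
}

#' Fit a PLS regression on a field matrix
#'
#' Latent components are extracted by the NIPALS recursion on the centred,
#' block-scaled, filter-retained descriptor matrix.  Reported alongside the
#' fit are the non-cross-validated r^2, the standard error of estimate
#' `SEE = sqrt(RSS / (n - N - 1))`, and (optionally) the leave-one-out q^2.
#'
#' @param fm A `qsar_fields` object (typically after [column_filter()]).
#' @param y Activity: numeric vector (optionally named by compound id) or an
#'   activity tibble with `compound_id` and `pic50`.
#' @param ncomp Number of latent components `N`; must satisfy
#'   `1 <= N <= min(n - 1, retained columns)`.
#' @param cv Compute leave-one-out q^2 and PRESS (default TRUE).
#' @return A `qsar_pls` object with coefficients (back-scaled to raw
#'   descriptor units), intercept, fitted values, `r2_ncv`, `see`, `q2`,
#'   `press`, per-field contribution percentages, scores and loadings.
#' @export
fit_pls <- function(fm, y, ncomp, cv = TRUE) {
  stopifnot(inherits(fm, "qsar_fields"))
  y <- align_y(fm, y)
  mm <- model_matrix_scaled(fm)
  n <- nrow(mm$X); p <- ncol(mm$X)
  if (p == 0) abort("No descriptor columns retained; relax the column filter.")
  if (stats::sd(y) < 1e-12) abort("`y` has zero variance.")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    abort(sprintf("`ncomp` must be in [1, %d].", min(n - 1, p)))
  }
  Xs <- sweep(mm$X, 2, mm$scale, "/")
  x_center <- colMeans(Xs)
  Xc <- sweep(Xs, 2, x_center)
  y_center <- mean(y)
  np <- nipals_pls1(Xc, y - y_center, ncomp)
  if (np$ncomp < ncomp) {
    warn(sprintf("PLS rank exhausted at %d component(s); requested %d.",
                 np$ncomp, ncomp))
    ncomp <- np$ncomp
  }
  beta_s <- nipals_coef(np, ncomp)
  beta_raw <- beta_s / mm$scale
  intercept <- y_center - sum(beta_raw * colMeans(mm$X))
  fitted <- drop(mm$X %*% beta_raw) + intercept
  rss <- sum((y - fitted)^2)
  tss <- sum((y - y_center)^2)
  col_sd_scaled <- apply(Xc, 2, stats::sd)
  contrib <- abs(beta_s) * col_sd_scaled
  blocks <- mm$columns$block
  frac <- tapply(contrib, blocks, sum)
  frac <- setNames(as.numeric(100 * frac / sum(frac)), names(frac))
  fit <- structure(list(
    n_components = ncomp,
    coefficients = setNames(beta_raw, colnames(mm$X)),
    coefficients_scaled = setNames(beta_s, colnames(mm$X)),
    intercept = intercept,
    fitted = fitted, y = y,
    r2_ncv = 1 - rss / tss,
    see = sqrt(rss / max(n - ncomp - 1, 1)),
    q2 = NA_real_, press = NA_real_, loo_pred = NULL,
    field_fractions = frac[unique(blocks)],
    columns = mm$columns,
    col_sd_scaled = col_sd_scaled,
    x_scale = mm$scale, x_center_scaled = x_center,
    scores = np$T, weights = np$W, loadings = np$P, y_loadings = np$q,
    training_ids = rownames(mm$X),
    fields = fm$fields, method = fm$method,
    lattice = fm$lattice, probe = fm$probe, cfg = fm$cfg, mask = fm$mask
  ), class = "qsar_pls")
  if (cv) {
    cvres <- loo_q2(fm, y, ncomp)
    fit$q2 <- cvres$q2
    fit$press <- cvres$press
    fit$loo_pred <- cvres$predictions
  }
  fit
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("<qsar_pls> %s fields %s | N = %d, r2_ncv = %.3f, SEE = %.3f",
              x$method, paste(x$fields, collapse = ""), x$n_components,
              x$r2_ncv, x$see))
  if (is.finite(x$q2)) cat(sprintf(", q2 (LOO) = %.3f", x$q2))
  cat("\n")
  ff <- paste(sprintf("%s %.1f%%", names(x$field_fractions), x$field_fractions),
              collapse = ", ")
  cat("  field contributions:", ff, "\n")
  invisible(x)
}

#' Predict activities for new compounds
#'
#' @param object A `qsar_pls` fit.
#' @param newdata A `qsar_fields` object built on the same lattice and
#'   fields, or a raw descriptor matrix with matching columns.
#' @param ... Unused.
#' @return Named numeric vector of predicted activities.
#' @export
predict.qsar_pls <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "qsar_fields")) newdata$values else as.matrix(newdata)
  cols <- names(object$coefficients)
  if (!all(cols %in% colnames(X))) {
    abort("`newdata` lacks the descriptor columns of the fitted model (same lattice and fields required).")
  }
  drop(X[, cols, drop = FALSE] %*% object$coefficients) + object$intercept
}

# latent scores for (possibly new) compounds, in the centred/scaled space
pls_scores <- function(object, newdata = NULL) {
  if (is.null(newdata)) return(object$scores)
  X <- if (inherits(newdata, "qsar_fields")) newdata$values else as.matrix(newdata)
  cols <- names(object$coefficients)
  Xs <- sweep(X[, cols, drop = FALSE], 2, object$x_scale, "/")
  Xc <- sweep(Xs, 2, object$x_center_scaled)
  R <- object$weights %*% solve(crossprod(object$loadings, object$weights))
  Xc %*% R
}

#' Leave-one-out cross-validated q^2
#'
#' Each compound is held out in turn, the PLS model refit on the remainder
#' (centring refit per fold; the column filter and block scaling are fixed
#' properties of the assembled matrix), and the held-out activity predicted.
#' `q2 = 1 - PRESS / sum((y - mean(y))^2)` with the mean taken over the full
#' training set.
#'
#' @inheritParams fit_pls
#' @return List with `q2`, `press` and the vector of LOO `predictions`.
#' @export
loo_q2 <- function(fm, y, ncomp) {
  y <- align_y(fm, y)
  n <- length(y)
  if (n < 3) abort("Leave-one-out cross-validation needs at least 3 compounds.")
  if (stats::sd(y) < 1e-12) abort("`y` has zero variance.")
  preds <- loo_predictions(fm, y, ncomp)
  pred <- preds[, ncol(preds)]
  press <- sum((y - pred)^2)
  list(q2 = 1 - press / sum((y - mean(y))^2), press = press,
       predictions = setNames(pred, names(y)))
}

# LOO predictions for every component count 1..max_n in one pass per fold
loo_predictions <- function(fm, y, max_n) {
  y <- align_y(fm, y)
  mm <- model_matrix_scaled(fm)
  n <- nrow(mm$X)
  max_n <- min(max_n, n - 2, ncol(mm$X))
  if (max_n < 1) abort("Too few compounds or descriptors for cross-validation.")
  Xs <- sweep(mm$X, 2, mm$scale, "/")
  out <- matrix(NA_real_, n, max_n, dimnames = list(rownames(mm$X), NULL))
  for (i in seq_len(n)) {
    Xi <- Xs[-i, , drop = FALSE]
    yi <- y[-i]
    xc <- colMeans(Xi)
    yc <- mean(yi)
    np <- nipals_pls1(sweep(Xi, 2, xc), yi - yc, max_n)
    xnew <- Xs[i, ] - xc
    for (a in seq_len(max_n)) {
      aa <- min(a, np$ncomp)
      out[i, a] <- sum(xnew * nipals_coef(np, aa)) + yc
    }
  }
  out
}

#' Select the number of latent components by LOO q^2
#'
#' Scans `N = 1..max_n`, computing the leave-one-out q^2 profile, and returns
#' the `N` maximising q^2 (ties broken towards the smaller model).
#'
#' @inheritParams fit_pls
#' @param max_n Largest component count scanned (default
#'   `min(10, n - 2, p)`).
#' @return List with `n_components` and the `profile` tibble
#'   (`ncomp`, `q2`, `press`).
#' @export
select_components <- function(fm, y, max_n = 10) {
  y <- align_y(fm, y)
  preds <- loo_predictions(fm, y, max_n)
  press <- colSums((y - preds)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  best <- which(q2 >= max(q2) - 1e-12)[1]
  list(n_components = best,
       profile = tibble(ncomp = seq_along(q2), q2 = q2, press = press))
}

#' Search field combinations for the best PLS model
#'
#' Enumerates every non-empty subset of the field blocks in the matrix, for
#' each subset selects the component count by LOO q^2 and fits the model, and
#' ranks the combinations by q^2.  This reproduces the conventional
#' model-search table: fields, q^2, N, SEE, r^2, per-field contributions.
#'
#' @inheritParams fit_pls
#' @param fields Field labels to search over (default: all blocks in `fm`).
#' @param max_n Largest component count scanned per combination.
#' @return A `qsar_model_search` tibble, one row per combination, ranked by
#'   decreasing q^2, with the fitted models in a list column `fit`.
#' @export
model_search <- function(fm, y, fields = NULL, max_n = 10) {
  stopifnot(inherits(fm, "qsar_fields"))
  y <- align_y(fm, y)
  fields <- fields %||% fm$fields
  if (!length(fields)) abort("At least one field must be searched.")
  combos <- unlist(lapply(seq_along(fields), function(k) {
    utils::combn(fields, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map(combos, function(fs) {
    sub <- subset_fields(fm, fs)
    if (!any(sub$mask)) {
      return(tibble(combination = paste(fs, collapse = ""),
                    n_components = NA_integer_, q2 = NA_real_,
                    r2_ncv = NA_real_, see = NA_real_,
                    fractions = list(NULL), fit = list(NULL)))
    }
    sel <- select_components(sub, y, max_n)
    fit <- fit_pls(sub, y, sel$n_components, cv = FALSE)
    fit$q2 <- sel$profile$q2[sel$n_components]
    fit$press <- sel$profile$press[sel$n_components]
    tibble(combination = paste(fs, collapse = ""),
           n_components = fit$n_components, q2 = fit$q2,
           r2_ncv = fit$r2_ncv, see = fit$see,
           fractions = list(fit$field_fractions), fit = list(fit))
  })
  out <- bind_rows(rows) %>% arrange(dplyr::desc(.data$q2))
  out$rank <- seq_len(nrow(out))
  class(out) <- c("qsar_model_search", class(out))
  out
}

# restrict a field matrix to a subset of field labels
subset_fields <- function(fm, fields) {
  keep_blocks <- paste0(fm$method, "_", fields)
  keep <- fm$columns$block %in% keep_blocks
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$columns <- fm$columns[keep, ]
  fm$mask <- fm$mask[keep]
  fm$block_scale <- fm$block_scale[keep_blocks]
  fm$fields <- fields
  fm
}

#' Per-field contribution percentages of a fitted model
#'
#' The share of `sum(|coefficient| * column sd)` (in the scaled modelling
#' space) attributable to each field block, normalised to 100.
#'
#' @param fit A `qsar_pls` object.
#' @return Named numeric vector of percentages summing to 100.
#' @export
field_fraction <- function(fit) {
  stopifnot(inherits(fit, "qsar_pls"))
  fit$field_fractions
}

#' Extract favoured / disfavoured contour regions
#'
#' For every retained lattice column the product of the (scaled-space) PLS
#' coefficient and the column standard deviation is formed — the standard
#' quantity behind grid-field contour maps.  Within each field block, points
#' above the `upper_pct` percentile are "favoured" (activity increases as the
#' field value there increases) and points below the `lower_pct` percentile
#' are "disfavoured".
#'
#' @param fit A `qsar_pls` fit.
#' @param upper_pct,lower_pct Percentiles (defaults 80 and 20).
#' @return A `qsar_contours` tibble: `block`, `point`, `x`, `y`, `z`,
#'   `product`, `class` ("favored"/"disfavored").
#' @export
contour_grid <- function(fit, upper_pct = 80, lower_pct = 20) {
  stopifnot(inherits(fit, "qsar_pls"))
  product <- fit$coefficients_scaled * fit$col_sd_scaled
  df <- fit$columns %>% mutate(product = product)
  out <- df %>%
    group_by(.data$block) %>%
    dplyr::group_modify(function(d, key) {
      if (max(d$product) - min(d$product) < 1e-12) {
        warn(paste0("Constant coefficient-sd product in block ", key$block,
                    "; no contours extracted."))
        return(d[0, ] %>% mutate(class = character()))
      }
      hi <- stats::quantile(d$product, upper_pct / 100, names = FALSE)
      lo <- stats::quantile(d$product, lower_pct / 100, names = FALSE)
      bind_rows(
        d %>% filter(.data$product > hi) %>% mutate(class = "favored"),
        d %>% filter(.data$product < lo) %>% mutate(class = "disfavored")
      )
    }) %>%
    ungroup()
  class(out) <- c("qsar_contours", class(out))
  out
}
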