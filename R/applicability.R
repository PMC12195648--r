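#' Fit a descriptor standardizer for applicability-domain scoring
#'
#' Records per-descriptor training means and (sample) standard deviations.
#' Zero-variance descriptors cannot be standardized and are excluded from
#' domain scoring with a warning.
#'
#' @param X_train Numeric matrix or data frame, training compounds by
#'   descriptors (at least two rows).
#' @return A `qsar_standardizer` with `mean`, `sd` and `dropped` columns.
#' @export
fit_standardizer <- function(X_train) {
  X <- as.matrix(X_train)
  if (nrow(X) < 2) abort("Standardization needs at least 2 training compounds.")
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  dropped <- !is.finite(s) | s < 1e-12
  if (any(dropped)) {
    warn(sprintf("%d constant descriptor(s) excluded from domain scoring.",
                 sum(dropped)))
  }
  structure(list(mean = mu[!dropped], sd = s[!dropped],
                 dropped = names(mu)[dropped] %||% which(dropped)),
            class = "qsar_standardizer")
}

# standardized absolute deviations S_ik for query rows
standardize_deviates <- function(std, X) {
  X <- as.matrix(X)
  keep <- names(std$mean)
  if (!is.null(keep) && !is.null(colnames(X))) X <- X[, keep, drop = FALSE]
  sweep(abs(sweep(X, 2, std$mean)), 2, std$sd, "/")
}

#' Domain verdict from a standardized-deviation vector
#'
#' A query compound is inside the training domain when its largest
#' standardized deviation is at most 3.  If the largest exceeds 3 but the
#' smallest does not, the border statistic
#' `S_new = mean(S) + 1.28 * sd(S)` decides: inside iff `S_new <= 3`.  If
#' every deviation exceeds 3 the compound is outside.
#'
#' @param s_k Non-empty numeric vector of standardized absolute deviations.
#' @return List with `s_max`, `s_min`, `s_new` (NA when not needed) and
#'   `verdict` ("inside"/"outside").
#' @export
ad_assess <- function(s_k) {
  if (!length(s_k)) abort("Empty standardized-deviation vector.")
  if (any(s_k < 0)) abort("Standardized deviations must be non-negative.")
  s_max <- max(s_k); s_min <- min(s_k)
  if (s_max <= 3) {
    return(list(s_max = s_max, s_min = s_min, s_new = NA_real_, verdict = "inside"))
  }
  if (s_min > 3) {
    return(list(s_max = s_max, s_min = s_min, s_new = NA_real_, verdict = "outside"))
  }
  s_new <- mean(s_k) + 1.28 * stats::sd(s_k)
  list(s_max = s_max, s_min = s_min, s_new = s_new,
       verdict = if (s_new <= 3) "inside" else "outside")
}

#' Applicability-domain report for query compounds
#'
#' Standardizes query descriptors against the training distribution and
#' applies the max/min/S_new decision rule per compound.  By default the
#' assessment runs in the PLS latent-score space of the fitted model —
#' thousands of collinear grid columns make raw-descriptor standardization
#' degenerate — with `space = "raw"` available for explicit descriptor
#' matrices.
#'
#' @param fit A `qsar_pls` model (for `space = "scores"`), or a training
#'   descriptor matrix (for `space = "raw"`).
#' @param newdata Query compounds: a `qsar_fields` object or descriptor
#'   matrix.  Defaults to the training data itself.
#' @param space `"scores"` (default) or `"raw"`.
#' @return An `ADReport` tibble: `compound_id`, `s_max`, `s_min`, `s_new`,
#'   `verdict`.
#' @export
applicability_domain <- function(fit, newdata = NULL, space = c("scores", "raw")) {
  space <- match.arg(space)
  if (space == "scores") {
    stopifnot(inherits(fit, "qsar_pls"))
    train <- pls_scores(fit)
    colnames(train) <- paste0("LV", seq_len(ncol(train)))
    query <- if (is.null(newdata)) train else {
      q <- pls_scores(fit, newdata)
      colnames(q) <- colnames(train)
      q
    }
    ids <- if (is.null(newdata)) fit$training_ids else {
      if (inherits(newdata, "qsar_fields")) rownames(newdata$values) else rownames(newdata)
    }
  } else {
    train <- as.matrix(fit)
    query <- if (is.null(newdata)) train else as.matrix(newdata)
    ids <- rownames(query)
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(query)))
  std <- fit_standardizer(train)
  S <- standardize_deviates(std, query)
  out <- purrr::map(seq_len(nrow(S)), function(i) {
    a <- ad_assess(S[i, ])
    tibble(compound_id = ids[i], s_max = a$s_max, s_min = a$s_min,
           s_new = a$s_new, verdict = a$verdict)
  })
  bind_rows(out)
}
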