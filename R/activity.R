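#' Convert an IC50 in micromolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50,
#' `-log10(ic50 * 1e-6)`.  Inhibitory potencies in this package are handled in
#' micromolar throughout (the unit in which assay tables are printed); the
#' conversion to molar happens only here.
#'
#' @param ic50 Numeric vector of IC50 values in micromolar. Must be positive.
#' @param digits Number of decimals for the reported value (default 3, the
#'   conventional reporting precision). Use `NULL` for full precision.
#' @return Numeric vector of pIC50 values.
#' @examples
#' pic50_from_ic50(86.46) # 4.063
#' pic50_from_ic50(1)     # 6
#' @export
pic50_from_ic50 <- function(ic50, digits = 3) {
  if (!is.numeric(ic50)) abort("`ic50` must be numeric.")
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("IC50 values must be finite and strictly positive (micromolar).")
  }
  p <- -log10(ic50 * 1e-6)
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Convert a pIC50 back to IC50 in micromolar
#'
#' Inverse of [pic50_from_ic50()].
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @return IC50 in micromolar.
#' @export
ic50_from_pic50 <- function(pic50) {
  if (!is.numeric(pic50)) abort("`pic50` must be numeric.")
  10^(-pic50) * 1e6
}

#' Selectivity index between a non-tumour and a tumour cell line
#'
#' The selectivity index (SI) is the growth-inhibition GI50 measured in a
#' non-tumour line divided by the GI50 in a tumour line; large values indicate
#' preferential toxicity towards tumour cells.  When the non-tumour GI50 is
#' censored (a lower bound such as ">25"), the SI computed from the bound is
#' itself a lower bound and is flagged as such.
#'
#' @param gi50_nontumor GI50 in the non-tumour (control) line, micromolar.
#' @param gi50_tumor GI50 in the tumour line, micromolar.
#' @param censored Logical; `TRUE` where the non-tumour value is a lower
#'   bound.  Recycled.
#' @return A tibble with columns `si` (full precision ratio), `si_display`
#'   (character: integers at SI >= 10, two decimals below, with a leading
#'   `">="` when the ratio is a lower bound) and `lower_bound`.
#' @examples
#' selectivity_index(25, 0.30, censored = TRUE)  # SI 83, a lower bound
#' selectivity_index(25, 1.54, censored = TRUE)  # SI 16
#' @export
selectivity_index <- function(gi50_nontumor, gi50_tumor, censored = FALSE) {
  if (any(!is.finite(gi50_nontumor)) || any(gi50_nontumor <= 0) ||
      any(!is.finite(gi50_tumor)) || any(gi50_tumor <= 0)) {
    abort("GI50 values must be finite and strictly positive (micromolar).")
  }
  n <- max(length(gi50_nontumor), length(gi50_tumor))
  censored <- rep_len(as.logical(censored), n)
  si <- gi50_nontumor / gi50_tumor
  disp <- ifelse(si >= 10,
                 formatC(round(si), format = "d"),
                 formatC(round(si, 2), format = "fg"))
  disp <- ifelse(censored, paste0(">=", disp), disp)
  tibble(si = si, si_display = disp, lower_bound = censored)
}

#' Fold-potency ratio between two compounds
#'
#' Ratio of two GI50 (or IC50) values, used for statements such as
#' "compound A is 13-fold more potent than compound B".
#'
#' @param gi50_less_potent,gi50_more_potent Concentrations in the same unit.
#' @return Numeric ratio (full precision; round for display).
#' @export
potency_ratio <- function(gi50_less_potent, gi50_more_potent) {
  if (any(gi50_less_potent <= 0) || any(gi50_more_potent <= 0)) {
    abort("Potency values must be strictly positive.")
  }
  gi50_less_potent / gi50_more_potent
}

#' Build or read a compound activity table
#'
#' Validates an activity table with columns `compound_id`, `ic50_uM` and/or
#' `pic50`, and `subset` ("train"/"test").  Missing pIC50 values are filled
#' from IC50 (full precision used for modelling).  When both are present they
#' are cross-checked at the three-decimal reporting precision; disagreement is
#' warned about and flagged, never silently resolved, since printed tables
#' occasionally carry inconsistent pairs.
#'
#' @param x A data frame, or a path to a CSV file.
#' @return A tibble with columns `compound_id`, `ic50_uM`, `pic50`, `subset`
#'   and `consistent` (FALSE where a supplied IC50/pIC50 pair disagrees).
#' @export
activity_table <- function(x) {
  df <- if (is.character(x) && length(x) == 1) {
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    as_tibble(x)
  }
  if (!"compound_id" %in% names(df)) abort("Activity table needs a `compound_id` column.")
  if (!"ic50_uM" %in% names(df)) df$ic50_uM <- NA_real_
  if (!"pic50" %in% names(df)) df$pic50 <- NA_real_
  if (!"subset" %in% names(df)) df$subset <- "train"
  df <- df %>%
    mutate(compound_id = as.character(.data$compound_id),
           ic50_uM = as.numeric(.data$ic50_uM),
           pic50 = as.numeric(.data$pic50),
           subset = as.character(.data$subset))
  if (anyDuplicated(df$compound_id)) abort("Compound ids must be unique.")
  if (!all(df$subset %in% c("train", "test"))) {
    abort("`subset` must be 'train' or 'test'.")
  }
  if (any(is.na(df$ic50_uM) & is.na(df$pic50))) {
    abort("Each record needs at least one of `ic50_uM` or `pic50`.")
  }
  if (any(df$ic50_uM <= 0, na.rm = TRUE)) abort("IC50 values must be positive.")
  both <- !is.na(df$ic50_uM) & !is.na(df$pic50)
  df$consistent <- TRUE
  if (any(both)) {
    conv <- round(pic50_from_ic50(df$ic50_uM[both], digits = NULL), 3)
    bad <- abs(conv - round(df$pic50[both], 3)) > 5e-4
    if (any(bad)) {
      ids <- df$compound_id[both][bad]
      warn(paste0("IC50/pIC50 pairs disagree at 3 decimals for: ",
                  paste(ids, collapse = ", "),
                  ". Both values kept; see `consistent` column."))
      df$consistent[both][bad] <- FALSE
    }
  }
  fill <- is.na(df$pic50)
  df$pic50[fill] <- pic50_from_ic50(df$ic50_uM[fill], digits = NULL)
  df %>% select("compound_id", "ic50_uM", "pic50", "subset", "consistent")
}

#' Read a cytotoxicity (GI50) table
#'
#' Expects columns `compound_id`, `cell_line`, `gi50_uM` and optionally
#' `censored`.  GI50 entries written as bounds (e.g. `">25"`) are parsed and
#' marked censored.
#'
#' @param x A data frame or CSV path.
#' @return Tibble with `compound_id`, `cell_line`, `gi50_uM`, `censored`.
#' @export
cytotox_table <- function(x) {
  df <- if (is.character(x) && length(x) == 1) {
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    as_tibble(x)
  }
  need <- c("compound_id", "cell_line", "gi50_uM")
  if (!all(need %in% names(df))) {
    abort(paste0("Cytotoxicity table needs columns: ", paste(need, collapse = ", ")))
  }
  gi <- df$gi50_uM
  if (is.character(gi)) {
    bound <- stringr::str_detect(gi, "^\\s*>")
    val <- as.numeric(stringr::str_remove(gi, "^\\s*>\\s*"))
    df$gi50_uM <- val
    df$censored <- if ("censored" %in% names(df)) df$censored | bound else bound
  } else if (!"censored" %in% names(df)) {
    df$censored <- FALSE
  }
  if (any(!is.finite(df$gi50_uM)) || any(df$gi50_uM <= 0)) {
    abort("GI50 values must be finite and positive.")
  }
  as_tibble(df[, c("compound_id", "cell_line", "gi50_uM", "censored")])
}

#' Stratified train/test split on activity
#'
#' Assigns compounds to training and test subsets by sampling within activity
#' tertiles, so the held-out set spans the activity range.  Used as a fallback
#' when no curated split is supplied.
#'
#' @param activities Activity tibble (see [activity_table()]).
#' @param test_fraction Fraction held out (default 0.2).
#' @param seed Integer seed; the split is fully reproducible.
#' @return The tibble with its `subset` column reassigned.
#' @export
split_train_test <- function(activities, test_fraction = 0.2, seed = 1) {
  act <- activity_table(activities)
  n <- nrow(act)
  if (n < 5) abort("Need at least 5 compounds to split.")
  withr::with_seed(seed, {
    strata <- cut(rank(act$pic50, ties.method = "first"),
                  breaks = 3, labels = FALSE)
    n_test <- max(1L, round(test_fraction * n))
    test_idx <- unlist(lapply(split(seq_len(n), strata), function(idx) {
      k <- round(length(idx) / n * n_test)
      if (k >= 1) sample(idx, min(k, length(idx))) else integer()
    }))
    # top up / trim to the requested size
    short <- n_test - length(test_idx)
    if (short > 0) {
      pool <- setdiff(seq_len(n), test_idx)
      test_idx <- c(test_idx, sample(pool, short))
    } else if (short < 0) {
      test_idx <- sample(test_idx, n_test)
    }
    act$subset <- ifelse(seq_len(n) %in% test_idx, "test", "train")
  })
  act
}
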