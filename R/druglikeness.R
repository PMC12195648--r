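#' Lipinski rule-of-five screening
#'
#' Violations among MW > 500 g/mol, HBD > 5, HBA > 10 and cLogP > 5
#' (boundary values are compliant).  The classic rule passes a compound with
#' at most one violation; `strict_pass` requires none.
#'
#' @param descriptors Data frame with columns `compound_id`, `mw`, `hbd`,
#'   `hba`, `clogp` (descriptors are inputs, computed upstream by whatever
#'   property engine the user trusts).
#' @return Tibble: `compound_id`, `lipinski_violations` (list column of rule
#'   names), `n_violations`, `pass`, `strict_pass`.
#' @export
lipinski <- function(descriptors) {
  df <- as_tibble(descriptors)
  need <- c("compound_id", "mw", "hbd", "hba", "clogp")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Missing descriptor column(s): ", paste(miss, collapse = ", ")))
  if (anyNA(df[need])) abort("Lipinski descriptors contain missing values.")
  if (any(df$mw <= 0) || any(df$hbd < 0) || any(df$hba < 0)) {
    abort("MW must be positive and H-bond counts non-negative.")
  }
  viol <- purrr::pmap(df[need], function(compound_id, mw, hbd, hba, clogp) {
    v <- character()
    if (mw > 500) v <- c(v, "MW > 500")
    if (hbd > 5) v <- c(v, "HBD > 5")
    if (hba > 10) v <- c(v, "HBA > 10")
    if (clogp > 5) v <- c(v, "cLogP > 5")
    v
  })
  tibble(compound_id = as.character(df$compound_id),
         lipinski_violations = viol,
         n_violations = lengths(viol),
         pass = lengths(viol) <= 1,
         strict_pass = lengths(viol) == 0)
}

#' Veber oral-bioavailability screening
#'
#' Violations among TPSA > 140 Angstrom^2 and more than 10 rotatable bonds
#' (10 itself is compliant).
#'
#' @param descriptors Data frame with `compound_id`, `tpsa`, `nrb`.
#' @return Tibble: `compound_id`, `veber_violations` (list column),
#'   `pass`.
#' @export
veber <- function(descriptors) {
  df <- as_tibble(descriptors)
  need <- c("compound_id", "tpsa", "nrb")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Missing descriptor column(s): ", paste(miss, collapse = ", ")))
  if (anyNA(df[need])) abort("Veber descriptors contain missing values.")
  viol <- purrr::pmap(df[need], function(compound_id, tpsa, nrb) {
    v <- character()
    if (tpsa > 140) v <- c(v, "TPSA > 140")
    if (nrb > 10) v <- c(v, "NRB > 10")
    v
  })
  tibble(compound_id = as.character(df$compound_id),
         veber_violations = viol,
         pass = lengths(viol) == 0)
}

#' Default bioavailability-radar axis ranges
#'
#' Six-axis desirability ranges commonly used for oral drugs: lipophilicity
#' (cLogP), size (MW), polarity (TPSA), insolubility (logS), unsaturation
#' (fraction sp3 carbons) and flexibility (rotatable bonds).
#'
#' @return Tibble with `axis`, `column`, `min`, `max`.
#' @export
radar_ranges <- function() {
  tibble(
    axis   = c("LIPO", "SIZE", "POLAR", "INSOLU", "INSATU", "FLEX"),
    column = c("clogp", "mw", "tpsa", "logs", "fsp3", "nrb"),
    min    = c(-0.7, 150, 20, -6, 0.25, 0),
    max    = c(5.0, 500, 130, 0, 1.0, 9)
  )
}

#' Bioavailability radar check
#'
#' Checks each available descriptor against the six-axis radar ranges;
#' axes whose descriptor column is absent are skipped.
#'
#' @param descriptors Data frame with `compound_id` and any of `clogp`,
#'   `mw`, `tpsa`, `logs`, `fsp3`, `nrb`.
#' @param ranges Axis ranges, see [radar_ranges()].
#' @return Long tibble: `compound_id`, `axis`, `value`, `in_range`; plus an
#'   `all_in_range` summary column joined per compound.
#' @export
bioavailability_radar <- function(descriptors, ranges = radar_ranges()) {
  df <- as_tibble(descriptors)
  if (!"compound_id" %in% names(df)) abort("Need a `compound_id` column.")
  ranges <- ranges %>% filter(.data$column %in% names(df))
  if (nrow(ranges) == 0) abort("No radar descriptor columns present.")
  long <- purrr::pmap(ranges, function(axis, column, min, max) {
    tibble(compound_id = as.character(df$compound_id), axis = axis,
           value = df[[column]], in_range = df[[column]] >= min & df[[column]] <= max)
  }) %>% bind_rows()
  summary <- long %>% group_by(.data$compound_id) %>%
    summarise(all_in_range = all(.data$in_range), .groups = "drop")
  left_join(long, summary, by = "compound_id")
}

#' Combined druglikeness report
#'
#' @param descriptors Data frame with the Lipinski and Veber columns
#'   (`compound_id`, `mw`, `hbd`, `hba`, `clogp`, `tpsa`, `nrb`).
#' @return Tibble joining [lipinski()] and [veber()] results.
#' @export
druglikeness_report <- function(descriptors) {
  l <- lipinski(descriptors)
  v <- veber(descriptors) %>% rename(veber_pass = "pass")
  left_join(l, v, by = "compound_id")
}
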