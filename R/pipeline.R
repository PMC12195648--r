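#' Configuration for an end-to-end QSAR run
#'
#' Defaults encode the conventional grid-field settings: 2 Angstrom spacing,
#' 4 Angstrom margin, sp3-carbon probe, 30 kcal/mol cutoff, Gaussian
#' attenuation 0.3, column filter 2.0, components selected by LOO q^2 up to
#' 10, 50 scrambling iterations, 80/20 contour percentiles.
#'
#' @param method `"comfa"` or `"comsia"`.
#' @param fields Field labels searched (default all for the method).
#' @param spacing,margin Lattice geometry, Angstrom.
#' @param max_components Largest component count scanned.
#' @param column_filter_sigma Column filter threshold (single value or named
#'   per-block vector, see [column_filter()]).
#' @param n_randomizations Y-randomization iterations.
#' @param contour_pct Upper/lower contour percentiles, length 2.
#' @param split_seed,test_fraction Fallback stratified split (used only when
#'   the activity table has no test compounds and `auto_split = TRUE`).
#' @param auto_split Whether to split when no test labels are present.
#' @param seed Seed for the stochastic stages (randomization, splitting).
#' @return A `qsar_config` list.
#' @export
qsar_config <- function(method = "comfa", fields = NULL, spacing = 2,
                        margin = 4, max_components = 10,
                        column_filter_sigma = 2, n_randomizations = 50,
                        contour_pct = c(80, 20), split_seed = 1,
                        test_fraction = 0.2, auto_split = TRUE, seed = 1) {
  structure(list(method = method, fields = fields, spacing = spacing,
                 margin = margin, max_components = max_components,
                 column_filter_sigma = column_filter_sigma,
                 n_randomizations = n_randomizations,
                 contour_pct = contour_pct, split_seed = split_seed,
                 test_fraction = test_fraction, auto_split = auto_split,
                 seed = seed),
            class = "qsar_config")
}

# row subset of a field matrix
subset_compounds <- function(fm, ids) {
  keep <- rownames(fm$values) %in% ids
  fm$values <- fm$values[keep, , drop = FALSE]
  fm
}

#' Run the full field-QSAR pipeline
#'
#' From aligned molecules and activities to a ranked model-search table, the
#' best model's internal and external validation, Y-randomization, an
#' applicability-domain report, contour maps and (optionally) a druglikeness
#' table.  Models are trained on the `train` subset only; `test` compounds
#' are used solely for external validation.
#'
#' @param molecules Atom table or path to an aligned SDF.
#' @param activities Activity tibble or CSV path (see [activity_table()]).
#' @param config A [qsar_config()].
#' @param descriptors Optional druglikeness descriptor table (or CSV path).
#' @param out_dir Optional directory; when given, all report artifacts are
#'   written there (CSV/JSON/YAML, `.dx` grids, contour PDB) together with a
#'   JSONL event log.
#' @return A `qsar_run` list: `search`, `fit`, `external`, `conditions`,
#'   `randomization`, `ad`, `contours`, `predictions`, `druglikeness`,
#'   `config`.
#' @export
qsar_run <- function(molecules, activities, config = qsar_config(),
                     descriptors = NULL, out_dir = NULL) {
  t0 <- Sys.time()
  log <- list()
  note <- function(stage, ...) {
    entry <- list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), ...)
    log[[length(log) + 1]] <<- entry
  }
  note("start", package_version = as.character(utils::packageVersion("fieldqsar")),
       seed = config$seed)

  mols <- if (is.character(molecules)) read_aligned_sdf(molecules) else as_molecule_tbl(molecules)
  act <- activity_table(activities)
  if (!setequal(act$compound_id, molecule_ids(mols))) {
    abort("stage molecules_io: activity table and molecule set cover different compounds.")
  }
  if (!any(act$subset == "test") && config$auto_split) {
    warn("No test compounds labelled; applying the seeded stratified split.")
    act <- split_train_test(act, config$test_fraction, config$split_seed)
  }
  note("molecules_io", n_compounds = length(molecule_ids(mols)),
       n_train = sum(act$subset == "train"), n_test = sum(act$subset == "test"))

  lattice <- build_lattice(mols, spacing = config$spacing, margin = config$margin)
  fm <- assemble_fields(mols, lattice, method = config$method,
                        fields = config$fields)
  fm <- column_filter(fm, config$column_filter_sigma)
  note("field_engine", n_descriptors = ncol(fm$values), n_retained = sum(fm$mask))

  train_ids <- act$compound_id[act$subset == "train"]
  test_ids <- act$compound_id[act$subset == "test"]
  fm_train <- subset_compounds(fm, train_ids)
  y_train <- setNames(act$pic50[match(train_ids, act$compound_id)], train_ids)

  search <- model_search(fm_train, y_train, max_n = config$max_components)
  best <- search$fit[[1]]
  cv <- loo_q2(subset_fields(fm_train, best$fields), y_train, best$n_components)
  best$q2 <- cv$q2; best$press <- cv$press; best$loo_pred <- cv$predictions
  note("pls_qsar", best_combination = search$combination[1],
       q2 = best$q2, r2_ncv = best$r2_ncv, n_components = best$n_components)

  external <- NULL; conditions <- NULL
  fm_best <- subset_fields(fm, best$fields)
  if (length(test_ids) >= 3) {
    y_test <- setNames(act$pic50[match(test_ids, act$compound_id)], test_ids)
    pred_test <- predict(best, subset_compounds(fm_best, test_ids))
    external <- external_metrics(y_test, pred_test)
    conditions <- gt_conditions(external, best$q2)
    note("validation_suite", r2_test = external$r2_test, rm2 = external$rm2,
         verdict = attr(conditions, "verdict"))
  } else {
    warn("Fewer than 3 test compounds; external-validation stage skipped.")
    note("validation_suite", skipped = TRUE)
  }

  randomization <- y_randomization(
    subset_fields(fm_train, best$fields), y_train, best$n_components,
    n_iterations = config$n_randomizations, seed = config$seed)
  note("y_randomization", pass = randomization$pass,
       max_q2 = max(randomization$iterations$q2))

  ad <- applicability_domain(best, newdata = fm_best)
  ad$subset <- act$subset[match(ad$compound_id, act$compound_id)]
  note("applicability_domain", n_outside = sum(ad$verdict == "outside"))

  contours <- contour_grid(best, config$contour_pct[1], config$contour_pct[2])
  note("contours", n_points = nrow(contours))

  all_pred <- predict(best, fm_best)
  predictions <- tibble(
    compound_id = rownames(fm_best$values),
    subset = act$subset[match(rownames(fm_best$values), act$compound_id)],
    observed = act$pic50[match(rownames(fm_best$values), act$compound_id)],
    predicted = all_pred
  ) %>% mutate(residual = .data$observed - .data$predicted,
               outlier = abs(.data$residual) > 1)

  drug <- if (!is.null(descriptors)) {
    d <- if (is.character(descriptors)) readr::read_csv(descriptors, show_col_types = FALSE) else descriptors
    druglikeness_report(d)
  }
  note("done", elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(search = search, fit = best, external = external,
                        conditions = conditions, randomization = randomization,
                        ad = ad, contours = contours, predictions = predictions,
                        druglikeness = drug, activities = act, fields = fm,
                        config = config, log = log),
                   class = "qsar_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("<qsar_run>\n")
  cat(sprintf("  best model: %s | N = %d, q2 = %.3f, r2_ncv = %.3f, SEE = %.3f\n",
              x$search$combination[1], x$fit$n_components, x$fit$q2,
              x$fit$r2_ncv, x$fit$see))
  if (!is.null(x$external)) {
    cat(sprintf("  external: r2_test = %.3f, rm2 = %.3f, verdict %s\n",
                x$external$r2_test, x$external$rm2,
                if (attr(x$conditions, "verdict")) "PASS" else "FAIL"))
  }
  cat(sprintf("  y-randomization: %s | AD: %d/%d inside\n",
              if (x$randomization$pass) "PASS" else "FAIL",
              sum(x$ad$verdict == "inside"), nrow(x$ad)))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  search_tbl <- as_tibble(run$search) %>%
    mutate(fractions = purrr::map_chr(.data$fractions, function(fr) {
      if (is.null(fr)) return(NA_character_)
      paste(sprintf("%s=%.1f", names(fr), fr), collapse = ";")
    })) %>%
    select(-"fit")
  readr::write_csv(search_tbl, p("model_search.csv"))
  readr::write_csv(run$predictions, p("predictions.csv"))
  readr::write_csv(run$ad, p("ad_report.csv"))
  readr::write_csv(as_tibble(run$contours), p("contours.csv"))
  write_contour_pdb(run$contours, p("contours.pdb"))
  # one dx grid per field block: the coefficient*sd product over the lattice
  prod_tbl <- tidy(run$fit)
  for (b in unique(prod_tbl$block)) {
    vals <- rep(0, prod(run$fit$lattice$dims))
    sub <- prod_tbl %>% filter(.data$block == b)
    vals[sub$point] <- sub$product
    write_dx(vals, run$fit$lattice, p(paste0("contour_", b, ".dx")))
  }
  val <- list(
    best_model = run$search$combination[1],
    statistics = as.list(glance(run$fit)),
    randomization = as.list(glance(run$randomization))
  )
  if (!is.null(run$external)) {
    val$external <- as.list(glance(run$external))
    val$conditions <- run$conditions
    val$verdict <- attr(run$conditions, "verdict")
  }
  jsonlite::write_json(val, p("validation.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(run$druglikeness)) {
    dl <- run$druglikeness %>%
      mutate(across(dplyr::where(is.list),
                    ~purrr::map_chr(.x, paste, collapse = ";")))
    readr::write_csv(dl, p("druglikeness.csv"))
  }
  yaml::write_yaml(unclass(run$config), p("config.yaml"))
  writeLines(vapply(run$log, function(e) jsonlite::toJSON(e, auto_unbox = TRUE),
                    character(1)), p("log.jsonl"))
  invisible(out_dir)
}

#' Predict new compounds with a fitted run
#'
#' Builds the model's field descriptors for new aligned molecules on the
#' stored lattice and returns predictions with applicability-domain
#' verdicts.  Compounds extending beyond the training lattice are refused
#' unless `allow_outside_lattice = TRUE` (the grid carries no information
#' out there).
#'
#' @param run A `qsar_run` or `qsar_pls` object.
#' @param molecules Atom table or SDF path of new molecules aligned to the
#'   training frame.
#' @param allow_outside_lattice Override the lattice containment check.
#' @return Tibble: `compound_id`, `predicted`, `s_max`, `s_min`, `s_new`,
#'   `ad_verdict`.
#' @export
qsar_predict <- function(run, molecules, allow_outside_lattice = FALSE) {
  fit <- if (inherits(run, "qsar_run")) run$fit else run
  stopifnot(inherits(fit, "qsar_pls"))
  mols <- if (is.character(molecules)) read_aligned_sdf(molecules) else as_molecule_tbl(molecules)
  inside <- lattice_contains(fit$lattice, mols)
  if (!all(inside) && !allow_outside_lattice) {
    abort(paste0("Compound(s) outside the training lattice: ",
                 paste(unique(mols$compound_id[!inside]), collapse = ", "),
                 ". Align to the training frame or set allow_outside_lattice = TRUE."))
  }
  fm_new <- assemble_fields(mols, fit$lattice, method = fit$method,
                            fields = fit$fields, probe = fit$probe,
                            cfg = fit$cfg, check_bounds = FALSE)
  pred <- predict(fit, fm_new)
  ad <- applicability_domain(fit, newdata = fm_new)
  tibble(compound_id = names(pred), predicted = unname(pred)) %>%
    left_join(ad %>% rename(ad_verdict = "verdict"), by = "compound_id")
}
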