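#' Build the rectilinear lattice enclosing an aligned molecule set
#'
#' Grid points are laid at `origin + k * spacing` along each axis, where the
#' box is the union bounding box of all atoms expanded by `margin` on every
#' side.  The conventional spacing for grid-field QSAR is 2 Angstrom.
#'
#' @param mols Atom table (see [as_molecule_tbl()]).
#' @param spacing Grid spacing, Angstrom (default 2).
#' @param margin Extension beyond the atom bounding box, Angstrom (default 4).
#' @return An object of class `qsar_lattice`: origin, spacing, dims.
#' @export
build_lattice <- function(mols, spacing = 2, margin = 4) {
  mols <- as_molecule_tbl(mols)
  if (!is.numeric(spacing) || spacing <= 0) abort("`spacing` must be > 0.")
  if (margin < 0) abort("`margin` must be >= 0.")
  lo <- c(min(mols$x), min(mols$y), min(mols$z)) - margin
  hi <- c(max(mols$x), max(mols$y), max(mols$z)) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "qsar_lattice")
}

#' @export
print.qsar_lattice <- function(x, ...) {
  cat(sprintf("<qsar_lattice> %d x %d x %d points, spacing %.3g A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Enumerate lattice points
#'
#' @param lattice A `qsar_lattice`.
#' @return Tibble with linear index `point` (x fastest) and coordinates.
#' @export
lattice_points <- function(lattice) {
  stopifnot(inherits(lattice, "qsar_lattice"))
  g <- expand.grid(ix = seq_len(lattice$dims[1]) - 1L,
                   iy = seq_len(lattice$dims[2]) - 1L,
                   iz = seq_len(lattice$dims[3]) - 1L)
  tibble(point = seq_len(nrow(g)),
         x = lattice$origin[1] + g$ix * lattice$spacing,
         y = lattice$origin[2] + g$iy * lattice$spacing,
         z = lattice$origin[3] + g$iz * lattice$spacing)
}

lattice_contains <- function(lattice, mols) {
  pts <- lattice_points(lattice)
  lo <- lattice$origin - 1e-9
  hi <- lattice$origin + (lattice$dims - 1L) * lattice$spacing + 1e-9
  mols$x >= lo[1] & mols$x <= hi[1] &
    mols$y >= lo[2] & mols$y <= hi[2] &
    mols$z >= lo[3] & mols$z <= hi[3]
}

#' Probe specifications for field calculations
#'
#' `comfa_probe()` is the standard sp3-carbon probe: van der Waals radius
#' 1.52 Angstrom, charge +1 e, with a Lennard-Jones well depth (default
#' 0.1 kcal/mol, combined geometrically with the per-atom depth).
#' `comsia_probe()` is the standard similarity probe: radius 1 Angstrom and
#' unit charge, hydrophobicity, donor and acceptor weights.
#'
#' @param radius Probe radius, Angstrom.
#' @param charge Probe charge, e.
#' @param steric_eps Lennard-Jones well depth, kcal/mol (CoMFA only).
#' @param hydrophobicity,hbd,hba Probe property weights (CoMSIA only).
#' @return A `qsar_probe` list.
#' @export
comfa_probe <- function(radius = 1.52, charge = 1.0, steric_eps = 0.1) {
  if (radius <= 0) abort("Probe radius must be positive.")
  structure(list(kind = "comfa", radius = radius, charge = charge,
                 steric_eps = steric_eps), class = "qsar_probe")
}

#' @rdname comfa_probe
#' @export
comsia_probe <- function(radius = 1.0, charge = 1.0, hydrophobicity = 1.0,
                         hbd = 1.0, hba = 1.0) {
  if (radius <= 0) abort("Probe radius must be positive.")
  structure(list(kind = "comsia", radius = radius, charge = charge,
                 hydrophobicity = hydrophobicity, hbd = hbd, hba = hba),
            class = "qsar_probe")
}

#' Field-calculation configuration
#'
#' @param energy_cutoff Truncation for interaction energies, kcal/mol
#'   (default 30, the conventional value).
#' @param attenuation_alpha Gaussian attenuation for similarity fields,
#'   1/Angstrom^2 (default 0.3).
#' @param column_filter_sigma Minimum column standard deviation retained for
#'   modelling (default 2 kcal/mol; see [column_filter()]).
#' @param atom_eps Default per-atom Lennard-Jones well depth, kcal/mol.
#' @param coulomb_constant Electrostatic prefactor, kcal A / (mol e^2).
#' @param electrostatic_fill How electrostatic values at sterically capped
#'   points are treated when a descriptor matrix is assembled:
#'   `"column-mean"` (replace by the mean over uncapped compounds, the
#'   conventional treatment) or `"none"`.
#' @return A `qsar_field_config` list.
#' @export
field_config <- function(energy_cutoff = 30, attenuation_alpha = 0.3,
                         column_filter_sigma = 2, atom_eps = 0.1,
                         coulomb_constant = 332.0636,
                         electrostatic_fill = c("column-mean", "none")) {
  if (energy_cutoff <= 0) abort("`energy_cutoff` must be > 0.")
  if (attenuation_alpha <= 0) abort("`attenuation_alpha` must be > 0.")
  structure(list(energy_cutoff = energy_cutoff,
                 attenuation_alpha = attenuation_alpha,
                 column_filter_sigma = column_filter_sigma,
                 atom_eps = atom_eps,
                 coulomb_constant = coulomb_constant,
                 electrostatic_fill = match.arg(electrostatic_fill)),
            class = "qsar_field_config")
}

# squared distances, grid points (m x 3) to atoms (n x 3) -> m x n
dist2_grid_atoms <- function(pts, at) {
  outer(pts$x, at$x, "-")^2 + outer(pts$y, at$y, "-")^2 + outer(pts$z, at$z, "-")^2
}

#' Steric (Lennard-Jones) probe interaction field
#'
#' At each lattice point the 6-12 interaction energy with every atom is
#' summed: `eps * ((r*/r)^12 - 2 (r*/r)^6)` with `r* = r_vdw + r_probe` and
#' `eps` the geometric mean of atom and probe well depths.  Values are
#' truncated to the configured cutoff, which absorbs the singularity at atom
#' centres.
#'
#' @param mol Atom table for one molecule (single compound id).
#' @param lattice A `qsar_lattice`.
#' @param probe A CoMFA probe, see [comfa_probe()].
#' @param cfg A [field_config()].
#' @return Numeric vector, kcal/mol, one value per lattice point.
#' @export
comfa_steric <- function(mol, lattice, probe = comfa_probe(), cfg = field_config()) {
  if (probe$kind != "comfa") abort("comfa_steric() needs a CoMFA probe.")
  pts <- lattice_points(lattice)
  r2 <- dist2_grid_atoms(pts, mol)
  rstar <- mol$vdw_radius + probe$radius
  eps <- sqrt(cfg$atom_eps * probe$steric_eps)
  # clamp the minimum distance so the 12-power cannot overflow; anything that
  # close is far beyond the energy cap anyway
  s6 <- sweep(1 / pmax(r2, 1e-4), 2, rstar^2, "*")^3  # (r*/r)^6
  e <- rowSums(eps * (s6^2 - 2 * s6))
  pmin(pmax(e, -cfg$energy_cutoff), cfg$energy_cutoff)
}

#' Electrostatic (Coulomb) probe interaction field
#'
#' Coulomb energy with a distance-dependent dielectric `D(r) = r`, i.e.
#' `332.0636 * q_i * q_probe / r^2`, summed over atoms and clamped to the
#' energy cutoff.  Treatment of points buried inside the molecule (where the
#' steric field is capped) happens at matrix assembly, where the column mean
#' over uncapped compounds is substituted.
#'
#' @inheritParams comfa_steric
#' @return Numeric vector, kcal/mol, one value per lattice point.
#' @export
comfa_electrostatic <- function(mol, lattice, probe = comfa_probe(),
                                cfg = field_config()) {
  if (probe$kind != "comfa") abort("comfa_electrostatic() needs a CoMFA probe.")
  if (!"charge" %in% names(mol) || any(is.na(mol$charge))) {
    abort("Atoms must carry partial charges for the electrostatic field.")
  }
  pts <- lattice_points(lattice)
  r2 <- dist2_grid_atoms(pts, mol)
  e <- rowSums(sweep(1 / pmax(r2, 1e-300), 2,
                     cfg$coulomb_constant * mol$charge * probe$charge, "*"))
  pmin(pmax(e, -cfg$energy_cutoff), cfg$energy_cutoff)
}

#' Gaussian similarity-index field
#'
#' The similarity field for property `k` at lattice point `q` is
#' `-sum_i w_probe * w_ik * exp(-alpha * r_iq^2)`; the Gaussian distance
#' dependence needs no cutoff.  Atom weights: steric `S` uses the cube of the
#' van der Waals radius, electrostatic `E` the partial charge, `H`/`D`/`A` the
#' typed hydrophobic/donor/acceptor weights.  The negative-similarity sign
#' convention is fixed by the single-atom value at zero distance being -1 for
#' unit weights.
#'
#' @inheritParams comfa_steric
#' @param property One of `"S"`, `"E"`, `"H"`, `"D"`, `"A"`.
#' @param probe A CoMSIA probe, see [comsia_probe()].
#' @return Numeric vector of (dimensionless) similarity indices per point.
#' @export
comsia_field <- function(mol, lattice, property, probe = comsia_probe(),
                         cfg = field_config()) {
  if (probe$kind != "comsia") abort("comsia_field() needs a CoMSIA probe.")
  if (!property %in% c("S", "E", "H", "D", "A")) {
    abort("`property` must be one of S, E, H, D, A.")
  }
  w_atom <- switch(property,
                   S = mol$vdw_radius^3,
                   E = mol$charge,
                   H = mol$w_hydrophobic,
                   D = mol$w_donor,
                   A = mol$w_acceptor)
  w_probe <- switch(property,
                    S = probe$radius^3,
                    E = probe$charge,
                    H = probe$hydrophobicity,
                    D = probe$hbd,
                    A = probe$hba)
  pts <- lattice_points(lattice)
  r2 <- dist2_grid_atoms(pts, mol)
  -rowSums(sweep(exp(-cfg$attenuation_alpha * r2), 2, w_probe * w_atom, "*"))
}

#' Assemble a compound-by-descriptor field matrix
#'
#' Computes the requested field blocks for every compound on a shared lattice
#' and concatenates them column-wise.  Column metadata retains the lattice
#' point and 3D position behind every descriptor.  Per-block scale factors
#' (the standard deviation of all centred entries in the block) are recorded;
#' they put blocks on a common footing before PLS so that no field dominates
#' by units alone, and are undone when coefficients are reported.
#'
#' @param mols Aligned atom table.
#' @param lattice A `qsar_lattice`; every atom must fall inside it.
#' @param method `"comfa"` (Lennard-Jones + Coulomb energies) or `"comsia"`
#'   (Gaussian similarity indices).
#' @param fields Field labels: subset of `c("S","E")` for CoMFA, of
#'   `c("S","E","H","D","A")` for CoMSIA.
#' @param probe Probe spec; defaults to the method's standard probe.
#' @param cfg A [field_config()].
#' @param check_bounds Error when atoms fall outside the lattice (default
#'   TRUE; prediction with an explicit override may disable it).
#' @return A `qsar_fields` object: `values` (numeric matrix, compounds by
#'   descriptors), `columns` (metadata tibble), `block_scale`, `mask`,
#'   `lattice`, `method`, `probe`, `cfg`.
#' @export
assemble_fields <- function(mols, lattice, method = c("comfa", "comsia"),
                            fields = NULL, probe = NULL, cfg = field_config(),
                            check_bounds = TRUE) {
  method <- match.arg(method)
  mols <- as_molecule_tbl(mols)
  if (is.null(fields)) fields <- if (method == "comfa") c("S", "E") else c("S", "E", "H", "D", "A")
  allowed <- if (method == "comfa") c("S", "E") else c("S", "E", "H", "D", "A")
  if (!length(fields) || !all(fields %in% allowed)) {
    abort(paste0("`fields` must be a non-empty subset of ",
                 paste(allowed, collapse = ", "), " for method '", method, "'."))
  }
  if (is.null(probe)) probe <- if (method == "comfa") comfa_probe() else comsia_probe()
  inside <- lattice_contains(lattice, mols)
  if (check_bounds && !all(inside)) {
    abort(paste0("Atoms outside the lattice for compound(s): ",
                 paste(unique(mols$compound_id[!inside]), collapse = ", ")))
  }
  ids <- molecule_ids(mols)
  by_mol <- split(mols, factor(mols$compound_id, levels = ids))
  npts <- prod(lattice$dims)

  block_values <- lapply(fields, function(f) {
    m <- t(vapply(by_mol, function(mol) {
      if (method == "comfa") {
        if (f == "S") comfa_steric(mol, lattice, probe, cfg)
        else comfa_electrostatic(mol, lattice, probe, cfg)
      } else {
        comsia_field(mol, lattice, f, probe, cfg)
      }
    }, numeric(npts)))
    rownames(m) <- ids
    m
  })
  names(block_values) <- fields

  # conventional treatment of electrostatics buried inside the union surface:
  # where a compound's steric energy is capped, substitute the column mean of
  # the uncapped compounds (the raw Coulomb value there is meaningless)
  if (method == "comfa" && "E" %in% fields && "S" %in% fields &&
      cfg$electrostatic_fill == "column-mean") {
    capped <- block_values$S >= cfg$energy_cutoff - 1e-9
    E <- block_values$E
    for (j in which(colSums(capped) > 0)) {
      ok <- !capped[, j]
      E[!ok, j] <- if (any(ok)) mean(E[ok, j]) else 0
    }
    block_values$E <- E
  }

  blocks <- paste0(method, "_", fields)
  values <- do.call(cbind, block_values)
  colnames(values) <- unlist(lapply(blocks, function(b) paste0(b, ":", seq_len(npts))))
  pts <- lattice_points(lattice)
  columns <- tibble(
    column = colnames(values),
    block = rep(blocks, each = npts),
    point = rep(pts$point, length(blocks)),
    x = rep(pts$x, length(blocks)),
    y = rep(pts$y, length(blocks)),
    z = rep(pts$z, length(blocks))
  )
  block_scale <- vapply(seq_along(blocks), function(i) {
    v <- scale(block_values[[i]], center = TRUE, scale = FALSE)
    s <- stats::sd(as.vector(v))
    if (!is.finite(s) || s < 1e-12) 1 else s
  }, numeric(1))
  names(block_scale) <- blocks
  structure(list(values = values, columns = columns, block_scale = block_scale,
                 mask = setNames(rep(TRUE, ncol(values)), colnames(values)),
                 lattice = lattice, method = method, fields = fields,
                 probe = probe, cfg = cfg),
            class = "qsar_fields")
}

#' @export
print.qsar_fields <- function(x, ...) {
  cat(sprintf("<qsar_fields> %d compounds x %d descriptors (%s: %s), %d retained after filtering\n",
              nrow(x$values), ncol(x$values), x$method,
              paste(x$fields, collapse = ""), sum(x$mask)))
  invisible(x)
}

#' @export
as_tibble.qsar_fields <- function(x, ...) {
  vals <- as_tibble(x$values)
  vals$compound_id <- rownames(x$values)
  tidyr::pivot_longer(vals, -"compound_id", names_to = "column",
                      values_to = "value") %>%
    left_join(x$columns, by = "column")
}

#' Mask low-variance descriptor columns
#'
#' Columns whose standard deviation across compounds falls below `sigma` are
#' masked out of modelling (they carry little but noise) while remaining in
#' the object for contour export.  The threshold is applied to raw column
#' standard deviations, i.e. kcal/mol for energy blocks; for dimensionless
#' similarity blocks supply a proportionate value via a named vector, e.g.
#' `c(comsia_S = 0.3)`.
#'
#' @param fm A `qsar_fields` object.
#' @param sigma Threshold (default from the field config, 2 kcal/mol).
#'   Either a single value or a named per-block vector.
#' @return The `qsar_fields` object with an updated mask.
#' @export
column_filter <- function(fm, sigma = NULL) {
  stopifnot(inherits(fm, "qsar_fields"))
  sigma <- sigma %||% fm$cfg$column_filter_sigma
  if (any(sigma < 0)) abort("`sigma` must be >= 0.")
  sds <- apply(fm$values, 2, stats::sd)
  thr <- if (is.null(names(sigma))) {
    rep(sigma[[1]], ncol(fm$values))
  } else {
    blocks <- fm$columns$block
    out <- rep(fm$cfg$column_filter_sigma, ncol(fm$values))
    for (b in names(sigma)) out[blocks == b] <- sigma[[b]]
    out
  }
  fm$mask <- setNames(sds >= thr | thr == 0, colnames(fm$values))
  fm
}

# retained, centred, block-scaled matrix used for modelling
model_matrix_scaled <- function(fm) {
  X <- fm$values[, fm$mask, drop = FALSE]
  sc <- fm$block_scale[fm$columns$block[fm$mask]]
  list(X = X, scale = sc, columns = fm$columns[fm$mask, ])
}

#' Construct a field-matrix object from a plain descriptor matrix
#'
#' Wraps an arbitrary compounds-by-descriptors matrix in the container the
#' modelling functions consume, with unit block scaling and no lattice
#' geometry (so contour extraction is unavailable).  Useful for modelling
#' precomputed descriptors and for raw-space applicability-domain input.
#'
#' @param X Numeric matrix; row names are compound ids.
#' @param block Block label assigned to all columns (default "custom").
#' @return A `qsar_fields` object.
#' @export
as_field_matrix <- function(X, block = "custom") {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("cpd_", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0(block, ":", seq_len(ncol(X)))
  structure(list(
    values = X,
    columns = tibble(column = colnames(X), block = block,
                     point = seq_len(ncol(X)),
                     x = NA_real_, y = NA_real_, z = NA_real_),
    block_scale = setNames(1, block),
    mask = setNames(rep(TRUE, ncol(X)), colnames(X)),
    lattice = NULL, method = "custom", fields = block,
    probe = NULL, cfg = field_config()), class = "qsar_fields")
}

#' Write / read a field matrix as CSV with a JSON sidecar
#'
#' The descriptor values go to `<path>.csv` (compounds by columns) and the
#' column metadata, mask, block scales and lattice geometry to
#' `<path>.json`, so a computed matrix can be reused without recomputing
#' fields.
#'
#' @param fm A `qsar_fields` object.
#' @param path Base path (without extension).
#' @return `write_fields()` returns `path` invisibly; `read_fields()`
#'   returns the reconstructed `qsar_fields`.
#' @export
write_fields <- function(fm, path) {
  stopifnot(inherits(fm, "qsar_fields"))
  vals <- as_tibble(fm$values)
  vals <- bind_cols(tibble(compound_id = rownames(fm$values)), vals)
  readr::write_csv(vals, paste0(path, ".csv"))
  meta <- list(columns = fm$columns, block_scale = as.list(fm$block_scale),
               mask = unname(fm$mask), method = fm$method, fields = fm$fields,
               lattice = if (!is.null(fm$lattice)) unclass(fm$lattice),
               probe = if (!is.null(fm$probe)) unclass(fm$probe),
               cfg = unclass(fm$cfg))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fields
#' @export
read_fields <- function(path) {
  vals <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(vals[, -1])
  rownames(X) <- vals$compound_id
  lattice <- if (!is.null(meta$lattice)) {
    structure(list(origin = meta$lattice$origin, spacing = meta$lattice$spacing,
                   dims = as.integer(meta$lattice$dims)), class = "qsar_lattice")
  }
  cfg <- do.call(field_config, meta$cfg[setdiff(names(meta$cfg), "")])
  probe <- if (!is.null(meta$probe)) {
    structure(as.list(meta$probe), class = "qsar_probe")
  }
  structure(list(values = X, columns = as_tibble(meta$columns),
                 block_scale = unlist(meta$block_scale),
                 mask = setNames(meta$mask, colnames(X)),
                 lattice = lattice, method = meta$method, fields = meta$fields,
                 probe = probe, cfg = cfg), class = "qsar_fields")
}
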