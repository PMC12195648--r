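# Plain-text grid and contour exporters for molecular viewers.  No installed
# R package writes OpenDX or Gaussian cube grids, so the (tiny, line-oriented)
# formats are emitted directly.

# reorder an x-fastest linear grid vector to z-fastest (dx/cube convention)
grid_z_fastest <- function(values, dims) {
  as.vector(aperm(array(values, dim = dims), c(3, 2, 1)))
}

#' Export a per-lattice-point field as an OpenDX grid
#'
#' @param values Numeric vector, one value per lattice point (x fastest, as
#'   produced by [lattice_points()]).
#' @param lattice The `qsar_lattice` the values live on.
#' @param path Output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(values, lattice, path) {
  d <- lattice$dims
  if (length(values) != prod(d)) abort("`values` length must equal the lattice size.")
  flat <- grid_z_fastest(values, d)
  chunks <- split(flat, ceiling(seq_along(flat) / 3))
  data_lines <- vapply(chunks, function(ch) paste(sprintf("%.6e", ch), collapse = " "),
                       character(1))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", lattice$origin[1], lattice$origin[2],
            lattice$origin[3]),
    sprintf("delta %.6f 0 0", lattice$spacing),
    sprintf("delta 0 %.6f 0", lattice$spacing),
    sprintf("delta 0 0 %.6f", lattice$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", prod(d)),
    data_lines,
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'), path)
  invisible(path)
}

#' Export a per-lattice-point field as a Gaussian cube file
#'
#' Atom positions of one (reference) molecule may be included for context.
#'
#' @inheritParams write_dx
#' @param mol Optional atom table of a single molecule to embed.
#' @return `path`, invisibly.
#' @export
write_cube <- function(values, lattice, path, mol = NULL) {
  d <- lattice$dims
  if (length(values) != prod(d)) abort("`values` length must equal the lattice size.")
  bohr <- 1 / 0.52917721092
  lines <- c("fieldqsar grid", "interaction field",
             sprintf("%5d %11.6f %11.6f %11.6f", if (is.null(mol)) 1L else nrow(mol),
                     lattice$origin[1] * bohr, lattice$origin[2] * bohr,
                     lattice$origin[3] * bohr),
             sprintf("%5d %11.6f %11.6f %11.6f", d[1], lattice$spacing * bohr, 0, 0),
             sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, lattice$spacing * bohr, 0),
             sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, lattice$spacing * bohr))
  if (is.null(mol)) {
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 6, 0, 0, 0, 0))
  } else {
    zmap <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17, Br = 35, I = 53)
    zn <- unname(zmap[mol$element]); zn[is.na(zn)] <- 6
    lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f", zn, mol$charge,
                              mol$x * bohr, mol$y * bohr, mol$z * bohr))
  }
  flat <- grid_z_fastest(values, d)
  chunks <- split(flat, ceiling(seq_along(flat) / 6))
  data_lines <- vapply(chunks, function(ch) paste(sprintf("%13.5e", ch), collapse = ""),
                       character(1))
  writeLines(c(lines, data_lines), path)
  invisible(path)
}

#' Write contour points as PDB pseudo-atoms
#'
#' Favoured points become HETATM records with residue name `FAV`,
#' disfavoured `DIS`, for overlay in a molecular viewer.
#'
#' @param contours A `qsar_contours` tibble.
#' @param path Output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_contour_pdb <- function(contours, path) {
  if (nrow(contours) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  res <- ifelse(contours$class == "favored", "FAV", "DIS")
  lines <- sprintf("HETATM%5d  X   %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   seq_len(nrow(contours)), res, seq_len(nrow(contours)) %% 10000,
                   contours$x, contours$y, contours$z, 1, abs(contours$product))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
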