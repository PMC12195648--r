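#' Default atom-typing table for field properties
#'
#' Per-element van der Waals radii (Bondi) and the property weights that enter
#' similarity-index fields: hydrophobicity, hydrogen-bond donor and acceptor
#' strength.  These are deliberately coarse element-level defaults — a
#' congeneric grid-field analysis is driven by where atoms are and how big or
#' charged they are, not by subtle typing — and the table is meant to be
#' edited and passed back in by the user.  Elements missing from the table get
#' carbon-like defaults.
#'
#' @return Tibble with columns `element`, `vdw_radius` (Angstrom),
#'   `w_hydrophobic`, `w_donor`, `w_acceptor` (dimensionless).
#' @export
atom_typing <- function() {
  tibble(
    element       = c("H",  "C",  "N",  "O",  "F",  "P",  "S",  "Cl", "Br", "I"),
    vdw_radius    = c(1.20, 1.70, 1.55, 1.52, 1.47, 1.80, 1.80, 1.75, 1.85, 1.98),
    w_hydrophobic = c(0,    1,    0,    0,    1,    0,    1,    1,    1,    1),
    w_donor       = c(0,    0,    1,    1,    0,    0,    0,    0,    0,    0),
    w_acceptor    = c(0,    0,    1,    1,    1,    0,    0,    0,    0,    0)
  )
}

atom_cols <- c("compound_id", "atom", "element", "x", "y", "z", "charge",
               "vdw_radius", "w_hydrophobic", "w_donor", "w_acceptor")

#' Validate an aligned-molecule atom table
#'
#' A molecule set is a tidy atom table: one row per atom, with compound id,
#' element, 3D coordinates (Angstrom, one shared frame — the set is assumed
#' pre-superimposed), partial charge and per-atom property weights.
#'
#' @param mols A data frame with columns `compound_id`, `atom`, `element`,
#'   `x`, `y`, `z`, `charge`, `vdw_radius`, `w_hydrophobic`, `w_donor`,
#'   `w_acceptor`.
#' @return The validated tibble (invisibly the same data).
#' @export
as_molecule_tbl <- function(mols) {
  mols <- as_tibble(mols)
  missing <- setdiff(atom_cols, names(mols))
  if (length(missing)) {
    abort(paste0("Molecule table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(mols) == 0) abort("Molecule table has no atoms.")
  num <- c("x", "y", "z", "charge", "vdw_radius",
           "w_hydrophobic", "w_donor", "w_acceptor")
  bad <- !vapply(mols[num], function(v) all(is.finite(v)), logical(1))
  if (any(bad)) {
    abort(paste0("Non-finite values in: ", paste(num[bad], collapse = ", ")))
  }
  if (any(mols$vdw_radius <= 0)) abort("van der Waals radii must be positive.")
  mols$compound_id <- as.character(mols$compound_id)
  mols
}

molecule_ids <- function(mols) unique(mols$compound_id)

#' Read a set of pre-aligned molecules from an SDF (V2000) file
#'
#' One record per compound, 3D coordinates in a common frame (the set must be
#' superimposed upstream; alignment is an input precondition, not something
#' this package performs).  Per-atom partial charges are read from a
#' `PARTIAL_CHARGES` SD data field containing one space-separated value per
#' atom.  Property weights (hydrophobic/donor/acceptor) and van der Waals
#' radii are assigned from `typing`; elements absent from the table fall back
#' to carbon-like values with zero weights.
#'
#' @param path SDF file path.
#' @param charge_policy `"from-file"` (default) requires the charge field and
#'   errors without it; `"compute"` assigns Gasteiger-type charges through
#'   OpenBabel (needs the ChemmineOB package) as a fallback when the upstream
#'   charge model is unavailable; `"zero"` assigns zero charges
#'   (electrostatic fields will then be flat).  The charge source is recorded
#'   in the `charge_source` attribute for provenance.
#' @param typing Atom-typing tibble, see [atom_typing()].
#' @return A tidy atom table (see [as_molecule_tbl()]) with a `bonds`
#'   attribute retaining the bond blocks for round-tripping.
#' @export
read_aligned_sdf <- function(path, charge_policy = c("from-file", "compute", "zero"),
                             typing = atom_typing()) {
  charge_policy <- match.arg(charge_policy)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
    warn("Empty SDF file; returning an empty molecule set.")
    out <- tibble(!!!setNames(rep(list(logical()), length(atom_cols)), atom_cols))
    return(out)
  }
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  if (!all(valid)) {
    abort(paste0("Unparsable SDF record(s) at index: ",
                 paste(which(!valid), collapse = ", ")))
  }
  ids <- ChemmineR::sdfid(sdfset)
  ids[is.na(ids) | ids == ""] <- paste0("mol_", which(is.na(ids) | ids == ""))
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  computed <- if (charge_policy == "compute") gasteiger_charges(path)
  recs <- purrr::map2(seq_along(sdfset), ids, function(i, id) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    hdr <- ChemmineR::header(sdf)
    if (any(grepl("2D", hdr)) && all(abs(ab[, 3]) < 1e-8)) {
      abort(paste0("Record ", i, " (", id, ") has 2D coordinates; ",
                   "aligned 3D conformers are required."))
    }
    element <- gsub("_.*$", "", rownames(ab))
    db <- ChemmineR::datablock(sdf)
    charge <- rep(0, nrow(ab))
    if (charge_policy == "compute") {
      charge <- computed[[i]]
      if (length(charge) != nrow(ab) || any(!is.finite(charge))) {
        abort(paste0("Record ", i, " (", id, "): computed charge count does ",
                     "not match the atom count."))
      }
    } else if ("PARTIAL_CHARGES" %in% names(db)) {
      charge <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]), "\\s+")[[1]])
      if (length(charge) != nrow(ab) || any(!is.finite(charge))) {
        abort(paste0("Record ", i, " (", id, "): PARTIAL_CHARGES field does ",
                     "not hold one finite value per atom."))
      }
    } else if (charge_policy == "from-file") {
      abort(paste0("Record ", i, " (", id, "): no PARTIAL_CHARGES data field ",
                   "(required under charge_policy = 'from-file')."))
    }
    bb <- ChemmineR::bondblock(sdf)
    atoms <- tibble(
      compound_id = id, atom = seq_len(nrow(ab)), element = element,
      x = unname(ab[, 1]), y = unname(ab[, 2]), z = unname(ab[, 3]),
      charge = charge
    )
    bonds <- tibble(compound_id = id,
                    a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                    order = as.integer(bb[, 3]))
    list(atoms = atoms, bonds = bonds)
  })
  atoms <- bind_rows(purrr::map(recs, "atoms")) %>%
    left_join(typing, by = "element") %>%
    mutate(
      vdw_radius = dplyr::coalesce(.data$vdw_radius, 1.70),
      w_hydrophobic = dplyr::coalesce(.data$w_hydrophobic, 0),
      w_donor = dplyr::coalesce(.data$w_donor, 0),
      w_acceptor = dplyr::coalesce(.data$w_acceptor, 0)
    ) %>%
    select(dplyr::all_of(atom_cols))
  out <- as_molecule_tbl(atoms)
  attr(out, "bonds") <- bind_rows(purrr::map(recs, "bonds"))
  attr(out, "charge_source") <- switch(charge_policy,
                                       "from-file" = "input file",
                                       compute = "gasteiger (OpenBabel)",
                                       zero = "zeroed")
  out
}

# Gasteiger-type charges for every record of an SDF file, via OpenBabel
gasteiger_charges <- function(path) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("charge_policy = 'compute' needs the ChemmineOB package.")
  }
  mol2 <- ChemmineOB::convertFormat(
    "SDF", "MOL2", paste(readLines(path, warn = FALSE), collapse = "\n"),
    options = data.frame(names = "partialcharge", args = "gasteiger"))
  blocks <- strsplit(mol2, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]][-1]
  lapply(blocks, function(b) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    i <- which(lines == "@<TRIPOS>ATOM")[1]
    ends <- grep("^@<TRIPOS>", lines)
    j <- c(ends[ends > i], length(lines) + 1L)[1]
    at <- lines[(i + 1):(j - 1)]
    vapply(strsplit(trimws(at), "\\s+"), function(f) {
      as.numeric(f[length(f)])
    }, numeric(1))
  })
}

#' Write an aligned molecule set to SDF (V2000)
#'
#' Coordinates are written at four-decimal precision; partial charges go into
#' a `PARTIAL_CHARGES` data field.  Bond blocks are taken from the `bonds`
#' attribute when present; otherwise a trivial serial chain is emitted (field
#' descriptors never use connectivity, but well-formed records need bonds).
#'
#' @param mols Atom table (see [as_molecule_tbl()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_sdf <- function(mols, path) {
  mols <- as_molecule_tbl(mols)
  bonds <- attr(mols, "bonds")
  sdfs <- lapply(molecule_ids(mols), function(id) {
    at <- mols[mols$compound_id == id, ]
    na <- nrow(at)
    b <- if (!is.null(bonds)) bonds[bonds$compound_id == id, c("a1", "a2", "order")]
    if (is.null(b) || nrow(b) == 0) {
      b <- if (na > 1) {
        tibble(a1 = seq_len(na - 1), a2 = seq_len(na - 1) + 1L, order = 1L)
      } else {
        tibble(a1 = 1L, a2 = 1L, order = 1L)[0, ]
      }
    }
    atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          at$x, at$y, at$z, at$element)
    bond_lines <- sprintf("%3d%3d%3d  0", b$a1, b$a2, b$order)
    c(id, "  fieldqsar          3D", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nrow(b)),
      atom_lines, bond_lines, "M  END",
      "> <PARTIAL_CHARGES>",
      paste(sprintf("%.6f", at$charge), collapse = " "),
      "", "$$$$")
  })
  writeLines(unlist(sdfs), path)
  invisible(path)
}
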