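#' Generate a synthetic aligned congeneric series with a planted
#' field-activity relationship
#'
#' Emulates the kind of data a grid-field QSAR is built on: a congeneric,
#' perfectly superimposed series sharing a rigid bicyclic (purine-like)
#' scaffold, with three substituent sites (mimicking 2-, 6- and
#' 9-substitution) whose atom properties — van der Waals radius, partial
#' charge, hydrophobic/donor/acceptor weights — vary per compound while
#' positions stay fixed.  Activity is a planted linear function of the
#' *actual assembled field descriptors* at designated lattice points next to
#' the sites, affinely calibrated to the pIC50 span typical of kinase
#' inhibitor series (about 4.0-7.8), plus Gaussian noise.  Because the
#' response is linear in descriptors that the pipeline itself computes, PLS
#' on fields is the correctly specified estimator and parameter/contour
#' recovery is a meaningful test.
#'
#' The default planted coefficients put a *positive* steric weight at site 1
#' (bulk there raises activity), a negative steric weight at site 2, and a
#' positive electrostatic weight at site 3.
#'
#' @param n_compounds Number of compounds (default 58, a typical series
#'   size; minimum 8).
#' @param noise_sd Gaussian noise on the activity, log units (default 0.3).
#' @param seed Integer seed; the whole series is reproducible from it.
#' @param beta Planted coefficients: named vector over the six
#'   (site, property) features `S1, S2, S3, E1, E2, E3` (defaults
#'   `c(S1 = 2, S2 = -1.5, S3 = 0, E1 = 0, E2 = 0, E3 = 1)`).
#' @param activity_range Target span of the noiseless activities.
#' @param test_fraction Held-out fraction for the stratified split.
#' @param spacing,margin Lattice geometry used to define the planted
#'   descriptors (and the natural choice downstream).
#' @return A list with `molecules` (tidy atom table), `activities`
#'   (activity tibble with train/test labels) and `truth`: planted `beta`
#'   (in calibrated units), `feature_columns` (descriptor names carrying the
#'   signal), `beneficial_points` (steric lattice columns in the designated
#'   probe shell of positive-steric sites), `sites`, `lattice`.
#' @export
synthetic_series <- function(n_compounds = 58, noise_sd = 0.3, seed = 1,
                             beta = NULL, activity_range = c(4.0, 7.8),
                             test_fraction = 0.2, spacing = 2, margin = 4) {
  if (n_compounds < 8) abort("`n_compounds` must be at least 8.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  beta <- beta %||% c(S1 = 2, S2 = -1.5, S3 = 0, E1 = 0, E2 = 0, E3 = 1)
  need <- c("S1", "S2", "S3", "E1", "E2", "E3")
  if (!all(need %in% names(beta)) || length(beta) != 6) {
    abort("`beta` must be a named vector over S1,S2,S3,E1,E2,E3.")
  }
  beta <- beta[need]

  scaf <- scaffold_atoms()
  sites <- scaffold_sites()

  withr::with_seed(seed, {
    ids <- sprintf("syn%02d", seq_len(n_compounds))
    subst <- purrr::map(seq_len(n_compounds), function(i) {
      tibble(
        compound_id = ids[i],
        atom = nrow(scaf) + seq_len(nrow(sites)),
        element = sample(c("C", "N", "O", "S", "Cl", "Br"), nrow(sites), replace = TRUE),
        x = sites$x, y = sites$y, z = sites$z,
        charge = runif(nrow(sites), -0.5, 0.5),
        vdw_radius = runif(nrow(sites), 1.2, 2.2),
        w_hydrophobic = runif(nrow(sites), 0, 1),
        w_donor = runif(nrow(sites), 0, 1),
        w_acceptor = runif(nrow(sites), 0, 1)
      )
    })
    mols <- bind_rows(purrr::map(seq_len(n_compounds), function(i) {
      bind_rows(scaf %>% mutate(compound_id = ids[i], .before = 1), subst[[i]])
    }))
    mols <- as_molecule_tbl(mols)

    lattice <- build_lattice(mols, spacing = spacing, margin = margin)
    fm <- assemble_fields(mols, lattice, method = "comfa", fields = c("S", "E"))

    # designated descriptor columns, one steric and one electrostatic point
    # per site.  Steric features sit in the shell where the Lennard-Jones
    # wall sweeps through as substituent radii vary (strong, retainable
    # variance); electrostatic features sit farther out, where neither the
    # energy cap nor the buried-point treatment ever engages, so the column
    # is a clean linear image of the substituent charge.
    pts <- lattice_points(lattice)
    nearest_in_shell <- function(s, offset, dmin, dmax) {
      target <- c(sites$x[s] + offset * sites$ux[s],
                  sites$y[s] + offset * sites$uy[s],
                  sites$z[s] + offset * sites$uz[s])
      d_site <- sqrt((pts$x - sites$x[s])^2 + (pts$y - sites$y[s])^2 +
                       (pts$z - sites$z[s])^2)
      ok <- d_site >= dmin & d_site <= dmax
      d_t <- (pts$x - target[1])^2 + (pts$y - target[2])^2 + (pts$z - target[3])^2
      pts$point[ok][which.min(d_t[ok])]
    }
    pt_s <- vapply(seq_len(nrow(sites)), nearest_in_shell, integer(1),
                   offset = 2.0, dmin = 1.8, dmax = 2.4)
    pt_e <- vapply(seq_len(nrow(sites)), nearest_in_shell, integer(1),
                   offset = 3.5, dmin = 2.8, dmax = 4.5)
    feature_columns <- c(paste0("comfa_S:", pt_s), paste0("comfa_E:", pt_e))
    Xf <- fm$values[, feature_columns, drop = FALSE]
    z <- drop(Xf %*% beta)

    span <- max(z) - min(z)
    if (span < 1e-8) abort("Degenerate planted signal; adjust `beta`.")
    a <- (activity_range[2] - activity_range[1]) / span
    y0 <- activity_range[1] + a * (z - min(z))
    y <- y0 + rnorm(n_compounds, 0, noise_sd)

    activities <- tibble(compound_id = ids, ic50_uM = ic50_from_pic50(y),
                         pic50 = y, subset = "train")
    # stratified split done inside the same seeded stream
    strata <- cut(rank(y, ties.method = "first"), breaks = 3, labels = FALSE)
    n_test <- max(1L, round(test_fraction * n_compounds))
    test_idx <- unlist(lapply(split(seq_len(n_compounds), strata), function(idx) {
      k <- round(length(idx) / n_compounds * n_test)
      if (k >= 1) sample(idx, min(k, length(idx))) else integer()
    }))
    short <- n_test - length(test_idx)
    if (short > 0) test_idx <- c(test_idx, sample(setdiff(seq_len(n_compounds), test_idx), short))
    if (short < 0) test_idx <- sample(test_idx, n_test)
    activities$subset[test_idx] <- "test"

    # lattice columns carrying the planted positive steric signal: points in
    # the designated probe shell (within 2.2 A, about one grid spacing) of
    # positive-steric substituent atoms — the region a correct contour
    # analysis should mark as favoured
    pos_sites <- which(beta[c("S1", "S2", "S3")] > 0)
    ben <- unique(unlist(lapply(pos_sites, function(s) {
      d2 <- (pts$x - sites$x[s])^2 + (pts$y - sites$y[s])^2 + (pts$z - sites$z[s])^2
      pts$point[d2 <= 2.2^2]
    })))

    list(
      molecules = mols,
      activities = activities,
      truth = list(beta = setNames(a * beta, need),
                   feature_columns = feature_columns,
                   beneficial_points = ben,
                   sites = sites, lattice = lattice, seed = seed,
                   noise_sd = noise_sd)
    )
  })
}

# rigid purine-like bicycle in the z = 0 plane (idealised geometry; bond
# lengths ~1.39 A), with small alternating charges
scaffold_atoms <- function() {
  hex <- purrr::map(0:5, function(k) {
    ang <- pi / 6 + k * pi / 3
    c(1.39 * cos(ang), 1.39 * sin(ang))
  })
  hx <- vapply(hex, `[`, numeric(1), 1)
  hy <- vapply(hex, `[`, numeric(1), 2)
  # fused five-ring sharing the hexagon edge between vertices 1 and 6
  px <- c(2.45, 3.25, 2.45)
  py <- c(1.15, 0.00, -1.15)
  tibble(
    atom = 1:9,
    element = c("N", "C", "N", "C", "C", "C", "N", "C", "N"),
    x = c(hx, px), y = c(hy, py), z = 0,
    charge = rep(c(-0.1, 0.1, -0.1), 3),
    vdw_radius = rep(c(1.55, 1.70, 1.55), 3),
    w_hydrophobic = 0, w_donor = 0, w_acceptor = 0
  )
}

# attachment sites analogous to the 2-, 6- and 9-positions: fixed positions
# 1.5 A outward from ring atoms, with in-plane outward unit vectors
scaffold_sites <- function() {
  scaf <- scaffold_atoms()
  anchors <- c(2, 5, 8)
  centre <- c(mean(scaf$x), mean(scaf$y))
  purrr::map(anchors, function(a) {
    v <- c(scaf$x[a] - centre[1], scaf$y[a] - centre[2])
    u <- v / sqrt(sum(v^2))
    tibble(site = match(a, anchors), anchor = a,
           x = scaf$x[a] + 1.5 * u[1], y = scaf$y[a] + 1.5 * u[2], z = 0,
           ux = u[1], uy = u[2], uz = 0)
  }) %>% bind_rows()
}

#' Rigidly misalign a molecule set to a target RMSD
#'
#' Each molecule is rotated about its centroid and translated so that the
#' coordinate RMSD to its original pose hits `rmsd_target` (to well under
#' 5%).  Used as a negative control: grid-field models assume superposition,
#' and misalignment should degrade cross-validated performance.
#'
#' @param mols Aligned atom table.
#' @param rmsd_target Target per-molecule RMSD, Angstrom.
#' @param seed Integer seed for the random rotation axes and directions.
#' @return The perturbed atom table.
#' @export
perturb_alignment <- function(mols, rmsd_target, seed = 1) {
  mols <- as_molecule_tbl(mols)
  if (rmsd_target < 0) abort("`rmsd_target` must be non-negative.")
  if (rmsd_target == 0) return(mols)
  withr::with_seed(seed, {
    out <- lapply(split(mols, factor(mols$compound_id, levels = molecule_ids(mols))),
                  function(mol) {
      P <- as.matrix(mol[, c("x", "y", "z")])
      ctr <- colMeans(P)
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      tdir <- rnorm(3); tdir <- tdir / sqrt(sum(tdir^2))
      move <- function(s) {
        R <- rotation_matrix(axis, s * 0.2)
        sweep(sweep(P, 2, ctr) %*% t(R), 2, -ctr) +
          matrix(s * rmsd_target * tdir, nrow(P), 3, byrow = TRUE)
      }
      rmsd_of <- function(s) sqrt(mean(rowSums((move(s) - P)^2)))
      s_star <- stats::uniroot(function(s) rmsd_of(s) - rmsd_target,
                               lower = 0, upper = 2, tol = 1e-10,
                               extendInt = "upX")$root
      Q <- move(s_star)
      mol$x <- Q[, 1]; mol$y <- Q[, 2]; mol$z <- Q[, 3]
      mol
    })
    bind_rows(out)
  })
}

rotation_matrix <- function(axis, angle) {
  c1 <- cos(angle); s1 <- sin(angle); t1 <- 1 - c1
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(t1 * x * x + c1, t1 * x * y - s1 * z, t1 * x * z + s1 * y,
           t1 * x * y + s1 * z, t1 * y * y + c1, t1 * y * z - s1 * x,
           t1 * x * z - s1 * y, t1 * y * z + s1 * x, t1 * z * z + c1),
         3, 3, byrow = TRUE)
}

#' Jaccard overlap between recovered and planted favourable regions
#'
#' Compares the favoured steric contour points of a fitted model with the
#' planted beneficial lattice points of a synthetic series, restricted to
#' the columns that survived filtering (only modelled points can appear in a
#' contour).
#'
#' @param contours A `qsar_contours` tibble from [contour_grid()].
#' @param fit The `qsar_pls` fit the contours came from.
#' @param truth The `truth` element of [synthetic_series()].
#' @return Jaccard index in \[0, 1\].
#' @export
contour_recovery <- function(contours, fit, truth) {
  fav <- contours %>%
    filter(.data$block == "comfa_S", .data$class == "favored") %>%
    pull("point")
  retained <- fit$columns %>% filter(.data$block == "comfa_S") %>% pull("point")
  ben <- intersect(truth$beneficial_points, retained)
  if (!length(fav) && !length(ben)) return(1)
  length(intersect(fav, ben)) / length(union(fav, ben))
}
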