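test_that("lattice construction covers the set with the requested margin", {
  lat <- build_lattice(one_atom(), spacing = 2, margin = 4)
  expect_equal(lat$dims, c(5L, 5L, 5L))
  pts <- lattice_points(lat)
  expect_equal(range(pts$x), c(-4, 4))
  expect_equal(nrow(pts), 125)
  expect_error(build_lattice(one_atom(), spacing = 0), "spacing")
  # every atom of a two-molecule set falls inside the box
  mols <- dplyr::bind_rows(one_atom(id = "a"),
                           one_atom(x = 3.7, y = -2.1, z = 1.9, id = "b"))
  lat2 <- build_lattice(mols, spacing = 2, margin = 3)
  expect_true(all(fieldqsar:::lattice_contains(lat2, mols)))
})

test_that("steric field has the analytic minimum, far-field decay and cap", {
  probe <- comfa_probe()
  # point exactly at r* = vdw + probe radius: energy is -eps
  at <- one_atom(vdw = 1.7)
  e_min <- comfa_steric(at, point_lattice(1.7 + probe$radius), probe)
  expect_equal(e_min, -sqrt(0.1 * 0.1), tolerance = 1e-12)
  # 50 A away the interaction is negligible
  expect_lt(abs(comfa_steric(at, point_lattice(50))), 1e-6)
  # a point coincident with the atom hits the cap
  expect_equal(comfa_steric(at, point_lattice(0)), 30.0)
})

test_that("electrostatic field matches the Coulomb form with D(r) = r and clamps", {
  at <- one_atom(charge = 1)
  # 332.0636 / (2 * 2) = 83.016 before the cap
  raw <- comfa_electrostatic(at, point_lattice(2), cfg = field_config(energy_cutoff = 1000))
  expect_equal(raw, 332.0636 / 4, tolerance = 1e-9)
  expect_equal(comfa_electrostatic(at, point_lattice(2)), 30.0)
  # antisymmetric in the atom charge
  neg <- comfa_electrostatic(one_atom(charge = -1), point_lattice(2),
                             cfg = field_config(energy_cutoff = 1000))
  expect_equal(neg, -raw)
  # zero charges give a zero vector
  expect_equal(comfa_electrostatic(one_atom(charge = 0), point_lattice(2)), 0)
})

test_that("similarity field follows the Gaussian closed form and adds over atoms", {
  at <- one_atom(w_h = 1)
  expect_equal(comsia_field(at, point_lattice(0), "H"), -1.0, tolerance = 1e-12)
  expect_equal(comsia_field(at, point_lattice(1), "H"), -exp(-0.3), tolerance = 1e-12)
  # steric weight is the cubed van der Waals radius
  at2 <- one_atom(vdw = 1.5)
  expect_equal(comsia_field(at2, point_lattice(0), "S"), -1.5^3, tolerance = 1e-12)
  # two identical atoms give exactly twice the single-atom value
  twin <- dplyr::bind_rows(at, at)
  twin$atom <- 1:2
  expect_equal(comsia_field(twin, point_lattice(1), "H"),
               2 * comsia_field(at, point_lattice(1), "H"), tolerance = 1e-12)
  expect_error(comsia_field(at, point_lattice(0), "Q"), "property")
})

test_that("field values respect translation equivariance and bounds", {
  syn <- small_synthetic()
  mols <- syn$molecules
  lat <- build_lattice(mols, spacing = 2, margin = 3)
  fm <- assemble_fields(mols, lat)
  shift <- c(3.17, -1.42, 0.77)
  mols2 <- dplyr::mutate(mols, x = x + shift[1], y = y + shift[2], z = z + shift[3])
  lat2 <- lat; lat2$origin <- lat$origin + shift
  fm2 <- assemble_fields(mols2, lat2)
  expect_equal(fm$values, fm2$values, tolerance = 1e-8)
  # CoMFA energies stay within the cutoff band
  expect_true(all(fm$values >= -30 - 1e-12 & fm$values <= 30 + 1e-12))
  # CoMSIA indices are finite and non-positive for all-positive weights
  cs <- assemble_fields(mols, lat, method = "comsia", fields = c("S", "H"))
  expect_true(all(is.finite(cs$values)))
  expect_true(all(cs$values <= 1e-12))
})

test_that("widening the lattice margin leaves shared points unchanged", {
  syn <- small_synthetic()
  mols <- syn$molecules
  lat1 <- build_lattice(mols, spacing = 2, margin = 2)
  lat2 <- build_lattice(mols, spacing = 2, margin = 4)
  f1 <- comfa_steric(mols[mols$compound_id == mols$compound_id[1], ], lat1)
  f2 <- comfa_steric(mols[mols$compound_id == mols$compound_id[1], ], lat2)
  p1 <- lattice_points(lat1); p2 <- lattice_points(lat2)
  key1 <- paste(p1$x, p1$y, p1$z); key2 <- paste(p2$x, p2$y, p2$z)
  shared <- intersect(key1, key2)
  expect_gt(length(shared), 0)
  expect_equal(f1[match(shared, key1)], f2[match(shared, key2)], tolerance = 1e-10)
})

test_that("assembled matrices have block structure and per-compound rows", {
  syn <- small_synthetic()
  mols <- syn$molecules
  lat <- build_lattice(mols)
  fm <- assemble_fields(mols, lat)
  npts <- prod(lat$dims)
  n <- length(unique(mols$compound_id))
  expect_equal(dim(fm$values), c(n, 2 * npts))
  expect_false(anyNA(fm$values))
  # identical molecules produce identical rows
  dup <- dplyr::bind_rows(
    dplyr::mutate(mols[mols$compound_id == mols$compound_id[1], ], compound_id = "cpy1"),
    dplyr::mutate(mols[mols$compound_id == mols$compound_id[1], ], compound_id = "cpy2"))
  fm_dup <- assemble_fields(dup, lat)
  expect_equal(fm_dup$values["cpy1", ], fm_dup$values["cpy2", ])
  # removing a field block removes exactly one block of columns
  fm_s <- assemble_fields(mols, lat, fields = "S")
  expect_equal(ncol(fm_s$values), npts)
  # molecules outside the lattice are reported by compound
  far <- dplyr::mutate(dup, x = x + 100)
  expect_error(assemble_fields(far, lat), "cpy1")
})

test_that("column filtering masks low-variance columns as specified", {
  X <- matrix(c(1.0, 1.5, 2.0,   0, 3, 6), ncol = 2)  # column sds 0.5 and 3
  fm <- fake_fields(X)
  expect_equal(apply(X, 2, sd), c(0.5, 3.0))
  filtered <- column_filter(fm, sigma = 2)
  expect_equal(sum(filtered$mask), 1)
  expect_true(unname(filtered$mask[2]))
  # sigma 0 keeps everything, constant columns are masked for sigma > 0
  expect_equal(sum(column_filter(fm, 0)$mask), 2)
  Xc <- cbind(X, 5)
  expect_equal(unname(column_filter(fake_fields(Xc), 0.1)$mask[3]), FALSE)
})

test_that("field matrices round-trip through the CSV + JSON sidecar", {
  syn <- small_synthetic()
  lat <- build_lattice(syn$molecules)
  fm <- column_filter(assemble_fields(syn$molecules, lat))
  base <- withr::local_tempfile()
  write_fields(fm, base)
  back <- read_fields(base)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_equal(back$mask, fm$mask)
  expect_equal(back$block_scale, fm$block_scale, tolerance = 1e-12)
  expect_equal(back$lattice$dims, fm$lattice$dims)
})

test_that("grid exports are well-formed", {
  syn <- small_synthetic()
  lat <- build_lattice(syn$molecules)
  mol1 <- syn$molecules[syn$molecules$compound_id == "syn01", ]
  v <- comfa_steric(mol1, lat)
  dx <- withr::local_tempfile(fileext = ".dx")
  write_dx(v, lat, dx)
  lines <- readLines(dx)
  expect_match(lines[1], sprintf("counts %d %d %d", lat$dims[1], lat$dims[2], lat$dims[3]))
  expect_equal(sum(unlist(lapply(grep("^[ -]?[0-9]", lines[8:20], value = TRUE), function(l)
    length(strsplit(trimws(l), "\\s+")[[1]])))) > 0, TRUE)
  cube <- withr::local_tempfile(fileext = ".cube")
  write_cube(v, lat, cube, mol = mol1)
  expect_equal(as.integer(strsplit(trimws(readLines(cube)[3]), "\\s+")[[1]][1]), nrow(mol1))
})
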