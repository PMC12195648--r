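test_that("SDF round trip preserves counts, elements, coordinates and charges", {
  syn <- small_synthetic()
  path <- withr::local_tempfile(fileext = ".sdf")
  write_aligned_sdf(syn$molecules, path)
  back <- read_aligned_sdf(path)
  expect_equal(length(unique(back$compound_id)),
               length(unique(syn$molecules$compound_id)))
  expect_equal(nrow(back), nrow(syn$molecules))
  expect_equal(back$element, syn$molecules$element)
  expect_equal(back$x, syn$molecules$x, tolerance = 1e-4)
  expect_equal(back$y, syn$molecules$y, tolerance = 1e-4)
  expect_equal(back$z, syn$molecules$z, tolerance = 1e-4)
  expect_equal(back$charge, syn$molecules$charge, tolerance = 1e-5)
})

test_that("record count and titles are preserved from the SDF", {
  two_atoms <- function(id, dx = 0) dplyr::bind_rows(
    one_atom(x = dx, id = id),
    dplyr::mutate(one_atom(x = dx + 1.4, z = 0.2, id = id), atom = 2L))
  mols <- dplyr::bind_rows(two_atoms("alpha"), two_atoms("beta", 1),
                           two_atoms("gamma", 2))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_aligned_sdf(mols, path)
  back <- read_aligned_sdf(path)
  expect_equal(unique(back$compound_id), c("alpha", "beta", "gamma"))
})

test_that("empty files, missing charges and 2D records are handled", {
  empty <- withr::local_tempfile(fileext = ".sdf")
  file.create(empty)
  expect_warning(out <- read_aligned_sdf(empty), "Empty")
  expect_equal(nrow(out), 0)

  # a record without the charge field errors under the default policy
  no_q <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("molx", "", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.1000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "    1.4000    0.0000    0.3000 N   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  2  1  0", "M  END", "$$$$"), no_q)
  expect_error(read_aligned_sdf(no_q), "PARTIAL_CHARGES")
  zeroed <- read_aligned_sdf(no_q, charge_policy = "zero")
  expect_equal(zeroed$charge, c(0, 0))
  # property weights come from the typing table
  expect_equal(zeroed$w_donor, c(0, 1))

  flat <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("flat", "  prog            2D", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "    1.4000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  2  1  0", "M  END", "$$$$"), flat)
  expect_error(read_aligned_sdf(flat, charge_policy = "zero"), "2D")
})

test_that("computed fallback charges are plausible and conserve totals", {
  skip_if_not_installed("ChemmineOB")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("water", "", "",
               "  3  2  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
               "    0.9600    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
               "   -0.2400    0.9300    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  2  1  0", "  1  3  1  0", "M  END", "$$$$"), path)
  mols <- read_aligned_sdf(path, charge_policy = "compute")
  expect_lt(mols$charge[1], 0)                 # oxygen carries negative charge
  # neutral overall, to the 4-decimal precision of the interchange format
  expect_lt(abs(sum(mols$charge)), 5e-4)
  expect_match(attr(mols, "charge_source"), "gasteiger")
})

test_that("molecule validation rejects malformed atom tables", {
  m <- one_atom()
  expect_silent(as_molecule_tbl(m))
  bad <- m; bad$vdw_radius <- -1
  expect_error(as_molecule_tbl(bad), "radii")
  bad2 <- m; bad2$x <- Inf
  expect_error(as_molecule_tbl(bad2), "Non-finite")
  expect_error(as_molecule_tbl(m[, -3]), "missing columns")
})
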