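test_that("pIC50 conversion reproduces worked values and is invertible", {
  expect_equal(pic50_from_ic50(86.46), 4.063)
  expect_equal(pic50_from_ic50(1.0), 6.000)
  expect_equal(pic50_from_ic50(0.33), 6.481)
  # strictly decreasing in IC50, and round-trip accurate to 3 significant figures
  ic <- c(0.015, 0.33, 1, 10, 86.46, 500)
  p <- pic50_from_ic50(ic, digits = NULL)
  expect_true(all(diff(p) < 0))
  expect_equal(signif(ic50_from_pic50(pic50_from_ic50(ic)), 3), signif(ic, 3))
  expect_error(pic50_from_ic50(0), "positive")
  expect_error(pic50_from_ic50(-3), "positive")
})

test_that("selectivity index reproduces worked values and reciprocal identity", {
  si <- selectivity_index(25, 0.30, censored = TRUE)
  expect_equal(round(si$si), 83)
  expect_equal(si$si_display, ">=83")
  expect_equal(round(selectivity_index(25, 1.54)$si), 16)
  expect_equal(selectivity_index(10, 10)$si, 1.0)
  # reciprocal pairs multiply to one before rounding
  a <- runif(5, 0.1, 30); b <- runif(5, 0.1, 30)
  expect_equal(selectivity_index(a, b)$si * selectivity_index(b, a)$si,
               rep(1, 5))
  expect_error(selectivity_index(-1, 2), "positive")
})

test_that("potency ratios round to the printed fold-changes", {
  expect_equal(round(potency_ratio(4.04, 0.30)), 13)
  expect_equal(round(potency_ratio(13.05, 1.54), 1), 8.5)
  expect_error(potency_ratio(0, 1), "positive")
})

test_that("activity_table fills pIC50, checks consistency and flags conflicts", {
  tbl <- activity_table(tibble::tibble(
    compound_id = c("a", "b"), ic50_uM = c(1, 86.46), subset = "train"))
  expect_equal(tbl$pic50, c(6, -log10(86.46e-6)))
  # the printed-pair conflict case: IC50 and pIC50 that disagree at 3 decimals
  expect_warning(
    bad <- activity_table(tibble::tibble(
      compound_id = "cpd51", ic50_uM = 0.015, pic50 = 7.833, subset = "train")),
    "disagree")
  expect_false(bad$consistent)
  # a consistent pair is not flagged
  ok <- activity_table(tibble::tibble(
    compound_id = "x", ic50_uM = 86.46, pic50 = 4.063, subset = "test"))
  expect_true(ok$consistent)
  expect_error(activity_table(tibble::tibble(compound_id = "a", subset = "train")),
               "at least one")
  expect_error(activity_table(tibble::tibble(
    compound_id = c("a", "a"), pic50 = c(5, 6), subset = "train")), "unique")
})

test_that("cytotoxicity tables parse censored bounds", {
  tbl <- cytotox_table(tibble::tibble(
    compound_id = c("7c", "7b"), cell_line = "HEK-293T",
    gi50_uM = c(">25", "14.75")))
  expect_equal(tbl$gi50_uM, c(25, 14.75))
  expect_equal(tbl$censored, c(TRUE, FALSE))
})

test_that("stratified splitting is seeded and spans the activity range", {
  act <- tibble::tibble(compound_id = sprintf("c%02d", 1:30),
                        pic50 = seq(4, 7.8, length.out = 30), subset = "train")
  s1 <- split_train_test(act, 0.2, seed = 5)
  s2 <- split_train_test(act, 0.2, seed = 5)
  expect_identical(s1, s2)
  expect_equal(sum(s1$subset == "test"), 6)
  # held-out compounds are not concentrated in one activity tertile
  tert <- cut(rank(s1$pic50), 3, labels = FALSE)
  expect_true(all(table(tert[s1$subset == "test"]) >= 1))
})
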