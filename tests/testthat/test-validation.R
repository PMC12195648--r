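test_that("perfect predictions pass every external-validation condition", {
  y <- c(4.2, 5.1, 5.9, 6.4, 7.1, 7.8)
  ev <- external_metrics(y, y)
  expect_equal(ev$k, 1); expect_equal(ev$k_prime, 1)
  expect_equal(ev$r2_test, 1); expect_equal(ev$r2_0, 1); expect_equal(ev$r2_0_prime, 1)
  flags <- gt_conditions(ev, q2 = 0.9)
  expect_true(all(flags$pass))
  expect_true(attr(flags, "verdict"))
})

test_that("a doubled prediction fails the through-origin slope condition", {
  y <- c(4.2, 5.1, 5.9, 6.4, 7.1, 7.8)
  ev <- external_metrics(y, 2 * y)
  expect_equal(ev$k, 0.5, tolerance = 1e-12)
  flags <- gt_conditions(ev, q2 = 0.9)
  expect_false(flags$pass[4])
  expect_false(attr(flags, "verdict"))
})

test_that("swapping observed and predicted swaps the slope pair exactly", {
  set.seed(5)
  y <- rnorm(8, 6); p <- y + rnorm(8, sd = 0.4)
  a <- external_metrics(y, p); b <- external_metrics(p, y)
  expect_equal(a$k, b$k_prime); expect_equal(a$k_prime, b$k)
  expect_equal(a$r2_0, b$r2_0_prime); expect_equal(a$r2_0_prime, b$r2_0)
  # and the metrics are order-invariant over compound pairs
  o <- sample(8)
  c2 <- external_metrics(y[o], p[o])
  expect_equal(glance(a), glance(c2), tolerance = 1e-12)
})

test_that("rm2 matches hand evaluation and its fixed-point identity", {
  expect_equal(rm2(0.8, 0.7), 0.8 * (1 - sqrt(0.1)), tolerance = 1e-12)
  expect_equal(round(rm2(0.8, 0.7), 3), 0.547)
  for (r in c(0, 0.25, 0.5, 0.9, 1)) expect_equal(rm2(r, r), r)
  expect_error(rm2(1.2, 0.5), "r2_test")
  # a single internal q2 below 0.5 sinks the verdict even with perfect externals
  y <- c(4.2, 5.1, 5.9, 6.4, 7.1, 7.8)
  flags <- gt_conditions(external_metrics(y, y), q2 = 0.4)
  expect_false(attr(flags, "verdict"))
})

test_that("random predictions almost never pass the battery", {
  set.seed(17)
  verdicts <- vapply(1:50, function(i) {
    y <- rnorm(10, 6)
    p <- sample(y)
    ev <- try(external_metrics(y, p), silent = TRUE)
    if (inherits(ev, "try-error")) return(FALSE)
    isTRUE(attr(gt_conditions(ev, q2 = 0.9), "verdict"))
  }, logical(1))
  expect_gte(mean(!verdicts), 0.95)
})

test_that("response scrambling is seeded, reproducible and null on noise", {
  syn <- small_synthetic()
  fm <- column_filter(assemble_fields(syn$molecules, syn$truth$lattice))
  y <- setNames(syn$activities$pic50, syn$activities$compound_id)
  r1 <- y_randomization(fm, y, ncomp = 3, n_iterations = 10, seed = 4)
  r2 <- y_randomization(fm, y, ncomp = 3, n_iterations = 10, seed = 4)
  expect_identical(r1$iterations, r2$iterations)
  expect_equal(nrow(tidy(r1)), 10)
  expect_true(r1$pass)
  expect_error(y_randomization(fm, y, 3, n_iterations = 0), "n_iterations")
})

test_that("scrambled and genuine q2 are indistinguishable when X is pure noise", {
  set.seed(31)
  X <- matrix(rnorm(12 * 8), 12, 8)
  fmn <- fake_fields(X)
  real_q2 <- vapply(1:12, function(i) loo_q2(fmn, rnorm(12), 2)$q2, numeric(1))
  scram <- y_randomization(fmn, rnorm(12), 2, n_iterations = 12, seed = 8)
  p <- stats::wilcox.test(real_q2, scram$iterations$q2)$p.value
  expect_gt(p, 0.05)
})

test_that("outlier flagging uses a strict one-log-unit threshold", {
  obs <- c(a = 5.0, b = 6.0, c = 7.0)
  expect_equal(flag_outliers(obs, c(6.2, 6.0, 6.0)), "a")   # residual 1.2
  expect_equal(flag_outliers(obs, obs), character())        # residual 0
  expect_equal(flag_outliers(obs, c(4.0, 6.0, 7.0)), character())  # exactly 1.0
})
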