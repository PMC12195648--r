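test_that("PLS recovers an exact single-column relation at one component", {
  set.seed(42)
  X <- cbind(seq(1, 6), matrix(rnorm(18, sd = 0.01), 6, 3))
  y <- 2 + 0.5 * X[, 1]
  fit <- fit_pls(fake_fields(X), y, ncomp = 1, cv = FALSE)
  expect_gte(fit$r2_ncv, 0.999)
})

test_that("full-rank PLS predictions equal ordinary least squares", {
  set.seed(7)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8, mean = 5)
  fit <- fit_pls(fake_fields(X), y, ncomp = 3, cv = FALSE)
  ols <- lm(y ~ X)
  expect_equal(unname(fit$fitted), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("NIPALS score vectors are mutually orthogonal", {
  set.seed(1)
  X <- matrix(rnorm(60), 10, 6)
  y <- rnorm(10)
  fit <- fit_pls(fake_fields(X), y, ncomp = 4, cv = FALSE)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("LOO q2 equals the independent brute-force oracle", {
  h <- hand_matrix()
  for (nc in 1:3) {
    got <- loo_q2(fake_fields(h$X), h$y, nc)
    expect_equal(got$q2, oracle_loo_q2(h$X, h$y, nc), tolerance = 1e-10)
  }
  # and the q2 formula applied to the stored LOO predictions is exact
  got <- loo_q2(fake_fields(h$X), h$y, 2)
  expect_identical(got$q2,
                   1 - sum((h$y - got$predictions)^2) / sum((h$y - mean(h$y))^2))
})

test_that("in-sample predictions match the Krylov-space reference", {
  h <- hand_matrix()
  for (nc in 1:3) {
    fit <- fit_pls(fake_fields(h$X), h$y, nc, cv = FALSE)
    expect_equal(unname(fit$fitted),
                 oracle_pls_predict(h$X, h$y, h$X, nc), tolerance = 1e-8)
  }
})

test_that("permuted scrambles of y rarely reach the q2 of a real relation", {
  set.seed(99)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- drop(X %*% c(1, -0.5, 0.3, 0, 0, 0)) + rnorm(20, sd = 0.2)
  low <- vapply(1:50, function(i) {
    loo_q2(fake_fields(X), sample(y), 2)$q2 < 0.5
  }, logical(1))
  expect_gte(mean(low), 0.95)
})

test_that("component selection maximises q2 with small-N tie-breaking", {
  set.seed(3)
  # two planted latent factors
  T2 <- matrix(rnorm(40), 20, 2)
  X <- T2 %*% matrix(rnorm(16), 2, 8) + matrix(rnorm(160, sd = 0.02), 20, 8)
  y <- drop(T2 %*% c(1, -1)) + rnorm(20, sd = 0.05)
  sel <- select_components(fake_fields(X), y, max_n = 6)
  expect_true(abs(sel$n_components - 2) <= 1)
  expect_equal(nrow(sel$profile), 6)
  expect_equal(sel$profile$q2[sel$n_components], max(sel$profile$q2))
  # max_n = 1 forces a single component
  expect_equal(select_components(fake_fields(X), y, max_n = 1)$n_components, 1)
  # pure-noise responses are still reported, with a typically poor q2
  sel_null <- select_components(fake_fields(X), rnorm(20), max_n = 3)
  expect_true(is.finite(sel_null$profile$q2[sel_null$n_components]))
})

test_that("model statistics are invariant to compound order and masked columns", {
  h <- hand_matrix()
  fm <- fake_fields(h$X)
  fit <- fit_pls(fm, h$y, 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  Xp <- h$X[perm, ]
  rownames(Xp) <- rownames(fm$values)[perm]
  fit_p <- fit_pls(fake_fields(Xp), h$y[perm], 2)
  expect_equal(fit_p$q2, fit$q2, tolerance = 1e-8)
  expect_equal(fit_p$r2_ncv, fit$r2_ncv, tolerance = 1e-8)
  expect_equal(fit_p$see, fit$see, tolerance = 1e-8)
  expect_equal(unname(fit_p$coefficients), unname(fit$coefficients), tolerance = 1e-8)
  # adding a column that the mask excludes changes nothing
  fm_extra <- fake_fields(cbind(h$X, junk = rnorm(6)))
  fm_extra$mask[5] <- FALSE
  fit_m <- fit_pls(fm_extra, h$y, 2)
  expect_equal(fit_m$q2, fit$q2, tolerance = 1e-12)
  expect_equal(fit_m$r2_ncv, fit$r2_ncv, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  h <- hand_matrix()
  expect_error(fit_pls(fake_fields(h$X), rep(5, 6), 2), "zero variance")
  expect_error(fit_pls(fake_fields(h$X), h$y, 9), "ncomp")
  expect_error(loo_q2(fake_fields(h$X[1:2, ]), h$y[1:2], 1), "at least 3")
})

test_that("model search enumerates field subsets and ranks by q2", {
  syn <- small_synthetic()
  fm <- column_filter(assemble_fields(syn$molecules, syn$truth$lattice))
  res <- model_search(fm, syn$activities$pic50, max_n = 4)
  expect_equal(nrow(res), 3)  # S, E, SE
  expect_setequal(res$combination, c("S", "E", "SE"))
  expect_true(all(diff(res$q2) <= 1e-12))
  expect_s3_class(res$fit[[1]], "qsar_pls")
  # five similarity fields would give 31 combinations
  expect_equal(sum(choose(5, 1:5)), 31)
})

test_that("field contributions are normalised and split evenly for duplicated blocks", {
  h <- hand_matrix()
  fit1 <- fit_pls(fake_fields(h$X), h$y, 2, cv = FALSE)
  expect_equal(unname(field_fraction(fit1)), 100, tolerance = 1e-9)
  # duplicate the same block under two labels: contributions must split 50/50
  X2 <- cbind(h$X, h$X)
  colnames(X2) <- c(paste0("comfa_S:", 1:4), paste0("comfa_E:", 1:4))
  fm2 <- as_field_matrix(X2)
  fm2$columns$block <- rep(c("comfa_S", "comfa_E"), each = 4)
  fm2$block_scale <- c(comfa_S = 1, comfa_E = 1)
  fit2 <- fit_pls(fm2, h$y, 2, cv = FALSE)
  expect_equal(unname(field_fraction(fit2)), c(50, 50), tolerance = 0.1)
  expect_equal(sum(field_fraction(fit2)), 100, tolerance = 1e-9)
})

test_that("contour extraction honours the percentile thresholds and sign flips", {
  set.seed(21)
  X <- matrix(rnorm(12 * 100), 12, 100)
  y <- drop(X[, 1:5] %*% c(2, 1, -1, 0.5, -0.5)) + rnorm(12, sd = 0.1)
  fit <- fit_pls(fake_fields(X), y, 2, cv = FALSE)
  ct <- contour_grid(fit, 80, 20)
  expect_equal(sum(ct$class == "favored"), 20)
  expect_equal(sum(ct$class == "disfavored"), 20)
  # negating the response exactly swaps favoured and disfavoured points
  fit_neg <- fit_pls(fake_fields(X), -y, 2, cv = FALSE)
  ct_neg <- contour_grid(fit_neg, 80, 20)
  expect_setequal(ct$point[ct$class == "favored"],
                  ct_neg$point[ct_neg$class == "disfavored"])
  expect_setequal(ct$point[ct$class == "disfavored"],
                  ct_neg$point[ct_neg$class == "favored"])
})

test_that("broom accessors expose coefficients, summaries and residuals", {
  h <- hand_matrix()
  fit <- fit_pls(fake_fields(h$X), h$y, 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(c("estimate", "product", "block") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 6)
  expect_equal(gl$see, fit$see)
  au <- augment(fit)
  expect_equal(au$residual, au$observed - au$fitted)
  expect_true("loo_predicted" %in% names(au))
})
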