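# Independent reference implementations used as oracles.
#
# Univariate PLS admits a Krylov-subspace characterisation: the N-component
# prediction is the least-squares fit of y restricted to coefficient vectors
# in span{X'y, (X'X)X'y, ..., (X'X)^(N-1) X'y} (on centred data).  This is a
# completely different computation from the NIPALS recursion the package
# uses, so agreement is a meaningful cross-check.
oracle_pls_predict <- function(X_train, y_train, X_new, ncomp) {
  xc <- colMeans(X_train)
  yc <- mean(y_train)
  Xc <- sweep(X_train, 2, xc)
  yc_v <- y_train - yc
  v <- drop(crossprod(Xc, yc_v))
  K <- matrix(0, ncol(Xc), ncomp)
  for (k in seq_len(ncomp)) {
    K[, k] <- v
    v <- drop(crossprod(Xc, Xc %*% v))
  }
  Q <- qr.Q(qr(K))
  Z <- Xc %*% Q
  g <- qr.coef(qr(Z), yc_v)
  g[is.na(g)] <- 0
  beta <- drop(Q %*% g)
  drop(sweep(as.matrix(X_new), 2, xc) %*% beta) + yc
}

# brute-force leave-one-out loop around the reference PLS
oracle_loo_q2 <- function(X, y, ncomp) {
  pred <- vapply(seq_along(y), function(i) {
    oracle_pls_predict(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE], ncomp)
  }, numeric(1))
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

# wrap a plain matrix as a field-matrix container with unit block scaling
fake_fields <- function(X, block = "comfa_S") {
  as_field_matrix(X, block = block)
}

# fixed 6 x 4 hand matrix and response used across the PLS oracle tests
hand_matrix <- function() {
  X <- matrix(c(
    0.52, 1.21, -0.33, 2.04,
    1.04, 0.87, 0.41, -1.02,
    -0.77, 0.35, 1.29, 0.66,
    2.11, -0.54, 0.08, 1.13,
    0.33, 1.67, -1.21, -0.47,
    -1.25, 0.91, 0.77, 0.29), nrow = 6, byrow = TRUE)
  y <- c(4.8, 5.6, 6.1, 5.0, 6.9, 5.4)
  list(X = X, y = y)
}

# one-atom molecule table at a given position
one_atom <- function(x = 0, y = 0, z = 0, charge = 0, vdw = 1.7, id = "m1",
                     w_h = 0, w_d = 0, w_a = 0, element = "C") {
  tibble::tibble(compound_id = id, atom = 1L, element = element,
                 x = x, y = y, z = z, charge = charge, vdw_radius = vdw,
                 w_hydrophobic = w_h, w_donor = w_d, w_acceptor = w_a)
}

# single-point lattice at a given position
point_lattice <- function(x, y = 0, z = 0) {
  structure(list(origin = c(x, y, z), spacing = 1, dims = c(1L, 1L, 1L)),
            class = "qsar_lattice")
}

# small cached synthetic series shared by several test files
small_synthetic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_series(n_compounds = 24, seed = 11)
    cache
  }
})
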