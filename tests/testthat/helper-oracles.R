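# Independent PLS1 oracle: fitted values equal the least-squares projection
# of centered y onto the Krylov subspace span{X'y, (X'X)X'y, ...} of the
# centered cross-product matrices — an algebraic characterization of PLS1
# that shares no code with the NIPALS deflation path.
krylov_pls <- function(X, y, n_factors) {
  X <- as.matrix(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  v <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(Xc), n_factors)
  K[, 1] <- v
  if (n_factors > 1) {
    for (a in 2:n_factors) {
      K[, a] <- drop(crossprod(Xc, Xc %*% K[, a - 1]))
    }
  }
  # normalize columns for numerical stability, then solve LS in the subspace
  K <- sweep(K, 2, sqrt(colSums(K^2)), "/")
  Z <- Xc %*% K
  alpha <- qr.solve(crossprod(Z), crossprod(Z, yc))
  B <- drop(K %*% alpha)
  list(
    fitted = drop(Xc %*% B) + y_mean,
    predict = function(X_new) {
      drop(sweep(as.matrix(X_new), 2, x_mean) %*% B) + y_mean
    }
  )
}

# small spectra_set with named standards for one analyte
toy_standards <- function(n = 8, p = 30, analyte = "SA", seed = 1,
                          conc = NULL) {
  set.seed(seed)
  grid <- seq(4000, 4000 + 2 * (p - 1), by = 2)
  if (is.null(conc)) conc <- seq(1, 100, length.out = n)
  base <- exp(-(grid - grid[p %/% 2])^2 / (2 * 8^2))
  A <- outer(conc, base) + matrix(rnorm(n * p, 0, 0.01), n, p)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(A) <- ids
  meta <- data.frame(sample_id = ids, role = "standard", analyte = analyte,
                     concentration_uM = conc, population = NA,
                     replicate = NA)
  spectra_set(grid, A, meta)
}

# quiet noise model with only gain + offset (for MSC recovery checks)
affine_only_noise <- function(sigma_b = 0.05, sigma_a = 0.01) {
  noise_model(sigma_b = sigma_b, sigma_a = sigma_a, sigma_tilt = 0,
              sigma_white = 0)
}
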