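#' Fit a PLS1 calibration by NIPALS
#'
#' Extracts latent factors one at a time from the column-centered spectral
#' matrix and centered response, deflating X after each factor. For a
#' single response NIPALS converges in one pass per factor; the iteration
#' guard (tolerance `1e-12`, 500 iterations) covers numerically degenerate
#' windows. Columns of X are centered but not autoscaled: absorbance
#' columns share units, the standard convention in NIR calibration.
#'
#' Factor extraction stops early (with a warning) if the requested count
#' exceeds `min(n_samples - 1, n_variables)` or if the deflated X carries
#' no remaining variance; the achieved count is recorded in `n_factors`.
#'
#' @param X Numeric matrix of preprocessed spectra, samples in rows.
#' @param y Numeric vector of responses (concentrations, uM), not constant.
#' @param n_factors Number of latent factors to extract (>= 0; 0 gives the
#'   mean-only null model).
#' @param tol NIPALS weight-vector convergence tolerance.
#' @param max_iter NIPALS iteration cap per factor.
#' @return An object of class `pls_model`: `x_mean`, `y_mean`, `weights`
#'   (W, p x A, orthonormal columns), `x_loadings` (P), `y_loadings` (q),
#'   `scores_ss` (per-factor score sum of squares), `x_ss_total` (total
#'   centered-X sum of squares), `coefficients` (folded regression vector
#'   for the full factor count), `coef_path` (p x A, coefficients for each
#'   truncated factor count), `n_factors`, and slots `preprocess`,
#'   `msc_fit`, `analyte` filled in by the calibration layer.
#' @export
fit_pls <- function(X, y, n_factors, tol = 1e-12, max_iter = 500L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("parameter error: need >= 2 samples", call. = FALSE)
  if (length(y) != n) {
    stop("dimension error: length(y) != nrow(X)", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("degenerate-response error: y is constant", call. = FALSE)
  }
  n_factors <- as.integer(n_factors)
  if (n_factors < 0L) {
    stop("parameter error: n_factors must be >= 0", call. = FALSE)
  }
  a_max <- min(n - 1L, p)
  if (n_factors > a_max) {
    warning("n_factors reduced to maximum ", a_max)
    n_factors <- a_max
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  x_ss_total <- sum(Xc^2)
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  q <- numeric(n_factors)
  scores_ss <- numeric(n_factors)
  scores <- matrix(0, n, n_factors)
  achieved <- 0L
  for (a in seq_len(n_factors)) {
    u <- yc
    w <- crossprod(Xc, u)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) break  # no covariance left to extract
    w <- w / wn
    for (it in seq_len(max_iter)) {
      tt <- Xc %*% w
      qq <- sum(u * tt) / sum(tt^2)
      # for PLS1 u is fixed at yc, so the weight is stationary after one
      # pass; recompute and test for movement anyway
      w_new <- crossprod(Xc, u)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta < tol) break
    }
    if (delta >= tol) {
      warning("NIPALS factor ", a, " stopped at ", max_iter,
              " iterations (delta ", format(delta), ")")
    }
    tt <- drop(Xc %*% w)
    tss <- sum(tt^2)
    if (tss < 1e-14) break
    pp <- drop(crossprod(Xc, tt)) / tss
    qa <- sum(yc * tt) / tss
    Xc <- Xc - tcrossprod(tt, pp)
    yc <- yc - qa * tt
    W[, a] <- w; P[, a] <- pp; q[a] <- qa
    scores[, a] <- tt; scores_ss[a] <- tss
    achieved <- a
  }
  if (achieved < n_factors) {
    warning("stopped after ", achieved,
            " factors: no X variance left to deflate")
    W <- W[, seq_len(achieved), drop = FALSE]
    P <- P[, seq_len(achieved), drop = FALSE]
    q <- q[seq_len(achieved)]
    scores <- scores[, seq_len(achieved), drop = FALSE]
    scores_ss <- scores_ss[seq_len(achieved)]
  }
  coef_path <- matrix(0, p, achieved)
  if (achieved > 0L) {
    # folded coefficients B_a = W_a (P_a' W_a)^{-1} q_a for each truncation
    for (a in seq_len(achieved)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      coef_path[, a] <- drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
    }
  }
  structure(list(x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q,
                 scores_ss = scores_ss, x_ss_total = x_ss_total,
                 coefficients = if (achieved > 0L)
                   coef_path[, achieved] else numeric(p),
                 coef_path = coef_path,
                 n_factors = achieved,
                 preprocess = NULL, msc_fit = NULL, analyte = NULL),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d factor(s), %d variables%s\n", x$n_factors,
              length(x$x_mean),
              if (!is.null(x$analyte)) paste0(", analyte ", x$analyte)
              else ""))
  invisible(x)
}

#' Predict concentrations from a fitted PLS model
#'
#' `yhat = (X_new - x_mean) %*% B + y_mean`, using the folded regression
#' coefficients for the requested factor count. Deterministic.
#'
#' @param model A `pls_model`.
#' @param X_new Numeric matrix (or vector) with columns matching the model
#'   training grid.
#' @param n_factors Factor count to use, `0..model$n_factors` (default the
#'   full fitted count).
#' @return Numeric vector of predicted responses.
#' @export
pls_predict <- function(model, X_new, n_factors = model$n_factors) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_mean)) {
    stop("dimension error: X_new has ", ncol(X_new),
         " columns; model expects ", length(model$x_mean), call. = FALSE)
  }
  n_factors <- as.integer(n_factors)
  if (n_factors < 0L || n_factors > model$n_factors) {
    stop("parameter error: n_factors outside fitted range", call. = FALSE)
  }
  if (n_factors == 0L) {
    return(rep(model$y_mean, nrow(X_new)))
  }
  B <- model$coef_path[, n_factors]
  drop(sweep(X_new, 2L, model$x_mean) %*% B) + model$y_mean
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  pls_predict(object, newdata, ...)
}

#' Per-factor explained X-variance of a PLS model
#'
#' Percentage of the centered calibration-spectra sum of squares captured
#' by each factor's score-loading outer product,
#' `100 * ||t_a p_a'||^2 / ||X_c||^2`. Because deflation makes the factor
#' contributions orthogonal, the entries are nonnegative and sum to at
#' most 100.
#'
#' @param model A fitted `pls_model`.
#' @return Numeric vector of percentages, one per factor.
#' @export
explained_x_variance <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$n_factors == 0L) return(numeric(0))
  load_ss <- colSums(model$x_loadings^2)
  100 * model$scores_ss * load_ss / model$x_ss_total
}
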