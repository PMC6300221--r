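# run expr with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Split standards into calibration and external-validation sets
#'
#' Concentration-stratified 70/30 split: standards of the analyte are
#' sorted by concentration, the extreme (minimum and maximum) levels are
#' forced into the training set so the model never extrapolates during
#' validation, and one test sample is drawn at random from each of
#' `n_test` consecutive concentration blocks. Deterministic given `seed`.
#'
#' @param standards A `spectra_set` of standards.
#' @param analyte Hormone name (`"IAA"`, `"GA"`, `"SA"`, `"kinetin"`).
#' @param fraction Training fraction in (0, 1); default 0.7. The training
#'   size is `round(fraction * n)` with halves rounded up (70% of 65
#'   standards gives 46 train / 19 test).
#' @param seed Integer seed for the within-block draws.
#' @return An object of class `split_design`: `train_ids`, `test_ids`,
#'   `analyte`, `seed`.
#' @export
split_standards <- function(standards, analyte, fraction = 0.7, seed = 1L) {
  stopifnot(inherits(standards, "spectra_set"))
  if (!(fraction > 0 && fraction < 1)) {
    stop("parameter error: fraction must be in (0, 1)", call. = FALSE)
  }
  meta <- standards$meta
  sel <- meta$role == "standard" & !is.na(meta$analyte) &
    meta$analyte == analyte
  if (sum(sel) < 5L) {
    stop("parameter error: need >= 5 standards of ", analyte, call. = FALSE)
  }
  ids <- meta$sample_id[sel]
  conc <- meta$concentration_uM[sel]
  ord <- order(conc, ids)
  ids <- ids[ord]
  n <- length(ids)
  n_train <- floor(fraction * n + 0.5)  # round-half-up
  n_test <- n - n_train
  if (n_test == 0L) {
    return(structure(list(train_ids = ids, test_ids = character(0),
                          analyte = analyte, seed = as.integer(seed)),
                     class = "split_design"))
  }
  interior <- seq_len(n)[-c(1L, n)]  # extremes always train
  blocks <- split(interior,
                  cut(seq_along(interior), breaks = n_test, labels = FALSE))
  test_idx <- with_local_seed(seed, {
    vapply(blocks, function(b) if (length(b) == 1L) b else
      b[sample.int(length(b), 1L)], integer(1))
  })
  structure(list(train_ids = ids[-test_idx], test_ids = ids[test_idx],
                 analyte = analyte, seed = as.integer(seed)),
            class = "split_design")
}

#' Root-mean-square error
#'
#' `sqrt(mean((y_true - y_pred)^2))` — the common core of RMSEC (training
#' residuals), RMSECV (cross-validation residuals) and RMSEP (external test
#' residuals).
#'
#' @param y_true,y_pred Equal-length numeric vectors (uM).
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("length error: need equal nonzero lengths", call. = FALSE)
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. Can be negative when the model predicts worse
#' than the mean, which is exactly what flags invalid external validations.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` not
#'   constant.
#' @return Dimensionless R-squared (<= 1, possibly negative).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) == 0L || length(y_true) != length(y_pred)) {
    stop("length error: need equal nonzero lengths", call. = FALSE)
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("degenerate error: y_true is constant", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

# preprocessing-aware fit on a training subset: returns X, y and frozen state
preprocess_train <- function(set, spec) {
  res <- apply_preprocess(set, spec)
  list(X = res$set$absorbance, wavenumbers = res$set$wavenumbers,
       msc_fit = res$msc_fit)
}

preprocess_frozen <- function(set, spec, msc_fit) {
  ref <- if (!is.null(msc_fit)) msc_fit$reference else NULL
  apply_preprocess(set, spec, msc_reference = ref)$set$absorbance
}

# RMSECV for every factor count 1..max_factors in a single pass over folds.
# Fold-dependent statistics (MSC reference, centering) are refit inside
# each fold; the SG derivative is per-sample and computed by
# apply_preprocess on each subset anyway.
cv_rmsecv_curve <- function(train_set, y, spec, max_factors = 7L,
                            scheme = c("kfold", "loo"), k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- n_spectra(train_set)
  if (scheme == "loo") k <- n
  k <- as.integer(k)
  if (k > n) stop("parameter error: k > n", call. = FALSE)
  if (k < 2L) stop("parameter error: k must be >= 2", call. = FALSE)
  fold <- with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  ids <- rownames(train_set$absorbance)
  pred <- matrix(NA_real_, n, max_factors)
  for (f in seq_len(k)) {
    in_f <- fold == f
    fit_set <- subset_samples(train_set, ids[!in_f])
    out_set <- subset_samples(train_set, ids[in_f])
    tr <- preprocess_train(fit_set, spec)
    a_fit <- min(max_factors, nrow(tr$X) - 1L, ncol(tr$X))
    m <- suppressWarnings(fit_pls(tr$X, y[!in_f], a_fit))
    X_out <- preprocess_frozen(out_set, spec, tr$msc_fit)
    for (a in seq_len(max_factors)) {
      aa <- min(a, m$n_factors)
      pred[in_f, a] <- pls_predict(m, X_out, n_factors = aa)
    }
  }
  sqrt(colMeans((pred - y)^2))
}

#' Cross-validated RMSE of a PLS calibration
#'
#' Internal validation per the RMSECV definition: each left-out sample is
#' predicted by a model refit without it, including refitting the
#' preprocessing statistics (MSC reference, centering) inside the fold.
#'
#' @param train_set A `spectra_set` of calibration standards.
#' @param y Concentrations (uM) in the row order of `train_set`.
#' @param spec A [preprocess_spec()].
#' @param n_factors Factor count to score.
#' @param scheme `"kfold"` (seeded random folds, default k = 10) or
#'   `"loo"` (leave-one-out).
#' @param k Number of folds for `"kfold"`.
#' @param seed Integer seed for the fold assignment.
#' @return RMSECV in uM.
#' @export
cross_validate <- function(train_set, y, spec, n_factors,
                           scheme = c("kfold", "loo"), k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  curve <- cv_rmsecv_curve(train_set, y, spec, max_factors = n_factors,
                           scheme = scheme, k = k, seed = seed)
  curve[n_factors]
}

# parsimonious factor count from an RMSECV curve: the smallest count whose
# RMSECV is statistically indistinguishable from the minimum, judged by the
# F-ratio on cross-validated squared errors (the Haaland-Thomas convention,
# alpha = 0.25); a plain argmin overfits whenever the curve is flat
select_n_factors <- function(rmsecv_curve, n_obs, alpha_f = 0.25) {
  a_min <- which.min(rmsecv_curve)
  limit <- rmsecv_curve[a_min] * sqrt(stats::qf(1 - alpha_f, n_obs, n_obs))
  which(rmsecv_curve <= limit)[1L]
}

#' Evaluate one candidate preprocessing recipe
#'
#' Fits the candidate on the training standards with the factor count
#' chosen from the RMSECV curve over `1..max_factors`: the fewest factors
#' whose RMSECV is statistically indistinguishable from the curve minimum
#' (F-ratio test on the cross-validated squared errors at alpha = 0.25),
#' so extra factors are only admitted when they demonstrably help — the
#' parsimony the selection philosophy asks for. RMSEC and calibration
#' R-squared are then scored on
#' the training set and RMSEP and prediction R-squared on the external
#' test set. The MSC reference and centering terms used on the test set
#' are frozen from the training fit — the external validation never
#' refits them.
#'
#' @param standards `spectra_set` containing the analyte's standards.
#' @param design A [split_standards()] design.
#' @param spec A [preprocess_spec()].
#' @param max_factors Largest factor count considered (default 7).
#' @param scheme,k,seed Cross-validation controls, see [cross_validate()].
#' @return One-row data frame (a candidate report) with columns `analyte`,
#'   `method`, `window_low`, `window_high`, `rmsec`, `r2_cal`, `rmsecv`,
#'   `rmsep`, `r2_pred`, `n_factors`.
#' @export
evaluate_candidate <- function(standards, design, spec, max_factors = 7L,
                               scheme = "kfold", k = 10L, seed = 1L) {
  stopifnot(inherits(design, "split_design"))
  train_set <- subset_samples(standards, design$train_ids)
  y_train <- train_set$meta$concentration_uM
  k <- min(as.integer(k), n_spectra(train_set))  # k-fold caps at n (LOO)
  curve <- cv_rmsecv_curve(train_set, y_train, spec, max_factors,
                           scheme = scheme, k = k, seed = seed)
  a_star <- select_n_factors(curve, n_spectra(train_set))
  tr <- preprocess_train(train_set, spec)
  model <- suppressWarnings(fit_pls(tr$X, y_train, a_star))
  yhat_train <- pls_predict(model, tr$X)
  rmsec <- rmse(y_train, yhat_train)
  r2_cal <- r_squared(y_train, yhat_train)
  if (length(design$test_ids)) {
    test_set <- subset_samples(standards, design$test_ids)
    y_test <- test_set$meta$concentration_uM
    X_test <- preprocess_frozen(test_set, spec, tr$msc_fit)
    yhat_test <- pls_predict(model, X_test)
    rmsep <- rmse(y_test, yhat_test)
    r2_pred <- r_squared(y_test, yhat_test)
  } else {
    rmsep <- NA_real_; r2_pred <- NA_real_
  }
  data.frame(analyte = design$analyte, method = spec$method,
             window_low = spec$window_low, window_high = spec$window_high,
             rmsec = rmsec, r2_cal = r2_cal, rmsecv = curve[a_star],
             rmsep = rmsep, r2_pred = r2_pred,
             n_factors = model$n_factors)
}

#' Default preprocessing-by-window candidate grid
#'
#' Six candidates per hormone: each of `none`, `msc` and `sg1d` (13-point
#' Savitzky-Golay first derivative) on the full 4000-10000 cm^-1 range and
#' on a hormone-specific reduced window. The reduced windows differ by
#' method for IAA (4000-6000 for none/MSC, 4000-5000 for the derivative)
#' and kinetin (4000-6000 for none/MSC, 4000-7000 for the derivative).
#'
#' @param analyte Hormone name.
#' @return List of [preprocess_spec()] objects.
#' @export
default_candidate_grid <- function(analyte) {
  analyte <- match.arg(analyte, HORMONES)
  reduced <- switch(analyte,
    IAA = list(none = c(4000, 6000), msc = c(4000, 6000),
               sg1d = c(4000, 5000)),
    GA = list(none = c(4000, 7000), msc = c(4000, 7000),
              sg1d = c(4000, 7000)),
    SA = list(none = c(4000, 6000), msc = c(4000, 6000),
              sg1d = c(4000, 6000)),
    kinetin = list(none = c(4000, 6000), msc = c(4000, 6000),
                   sg1d = c(4000, 7000)))
  grid <- list()
  for (m in c("none", "msc", "sg1d")) {
    grid[[length(grid) + 1L]] <- preprocess_spec(m, 4000, 10000)
    rw <- reduced[[m]]
    grid[[length(grid) + 1L]] <- preprocess_spec(m, rw[1], rw[2])
  }
  grid
}

#' Select the optimum candidate from a report table
#'
#' The selection rule: (1) validity filter — drop candidates whose
#' prediction R-squared is not above `r2_min` (default 0), because a low
#' RMSEP is meaningless when the external validation fits worse than the
#' mean; (2) among the valid candidates choose the minimal RMSEP, treating
#' candidates within a factor `rmsep_tol` of the minimum as statistical
#' ties (RMSEP is itself estimated on a small external test set — an
#' F-ratio at roughly the 0.25 level for a ~19-sample test set gives the
#' default 1.2); (3) break ties toward fewer factors, then toward smaller
#' RMSEP, then smaller RMSEC. If the filter removes every candidate, the
#' overall minimal-RMSEP row is returned with a validity warning and
#' `valid = FALSE`.
#'
#' @param candidates Data frame of candidate reports (rows as produced by
#'   [evaluate_candidate()]).
#' @param r2_min Validity threshold on `r2_pred`; default 0.
#' @param rmsep_tol Relative tolerance defining an RMSEP tie; default 1.2.
#'   Set to 1 for strict minimal-RMSEP selection.
#' @return The winning one-row data frame, with an added logical column
#'   `valid`.
#' @export
select_model <- function(candidates, r2_min = 0, rmsep_tol = 1.2) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0L) {
    stop("parameter error: empty candidate list", call. = FALSE)
  }
  need <- c("rmsep", "r2_pred", "n_factors", "rmsec")
  missing <- setdiff(need, names(candidates))
  if (length(missing)) {
    stop("parameter error: candidate table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  valid <- !is.na(candidates$r2_pred) & candidates$r2_pred > r2_min
  pool <- candidates[valid, , drop = FALSE]
  was_valid <- TRUE
  if (nrow(pool) == 0L) {
    warning("no candidate passed the prediction-R2 validity filter; ",
            "returning overall minimum RMSEP")
    pool <- candidates
    was_valid <- FALSE
  }
  tied <- pool$rmsep <= min(pool$rmsep) * rmsep_tol
  pool <- pool[tied, , drop = FALSE]
  ord <- order(pool$n_factors, pool$rmsep, pool$rmsec)
  out <- pool[ord[1L], , drop = FALSE]
  out$valid <- was_valid
  rownames(out) <- NULL
  out
}

#' Calibrate one hormone end to end
#'
#' Convenience wrapper for the full calibration workflow on one analyte:
#' split the standards 70/30, evaluate every candidate in the grid, select
#' the optimum, and refit the final model on the training set with the
#' selected recipe and factor count. The returned model carries its frozen
#' preprocessing recipe and MSC reference for later prediction of
#' unknowns.
#'
#' @param standards `spectra_set` of standards (may contain several
#'   analytes).
#' @param analyte Hormone to calibrate.
#' @param grid List of [preprocess_spec()] candidates; default
#'   [default_candidate_grid()].
#' @param fraction,seed Split controls, see [split_standards()].
#' @param max_factors,scheme,k Evaluation controls, see
#'   [evaluate_candidate()].
#' @param r2_min Validity threshold for [select_model()].
#' @return List with `model` (a `pls_model` ready for
#'   [predict_unknowns()]), `report` (all candidate rows), `selected`
#'   (winning row) and `design` (the split).
#' @export
calibrate_analyte <- function(standards, analyte,
                              grid = default_candidate_grid(analyte),
                              fraction = 0.7, max_factors = 7L,
                              scheme = "kfold", k = 10L, seed = 1L,
                              r2_min = 0) {
  design <- split_standards(standards, analyte, fraction, seed)
  report <- do.call(rbind, lapply(grid, function(spec) {
    evaluate_candidate(standards, design, spec, max_factors,
                       scheme = scheme, k = k, seed = seed)
  }))
  selected <- select_model(report, r2_min = r2_min)
  spec <- preprocess_spec(selected$method, selected$window_low,
                          selected$window_high)
  train_set <- subset_samples(standards, design$train_ids)
  tr <- preprocess_train(train_set, spec)
  model <- suppressWarnings(
    fit_pls(tr$X, train_set$meta$concentration_uM, selected$n_factors))
  model$preprocess <- spec
  model$msc_fit <- tr$msc_fit
  model$analyte <- analyte
  list(model = model, report = report, selected = selected, design = design)
}
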