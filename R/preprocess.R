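#' Define a spectral preprocessing recipe
#'
#' One cell of the preprocessing-by-window candidate grid: a wavenumber
#' window plus one of three pre-treatments — `"none"`, multiplicative
#' scatter correction (`"msc"`), or a Savitzky-Golay smoothed first
#' derivative (`"sg1d"`). The window is always applied first, so each
#' (window, treatment) pair is a single self-contained candidate.
#'
#' @param method One of `"none"`, `"msc"`, `"sg1d"`.
#' @param window_low,window_high Window bounds in cm^-1.
#' @param sg_points Odd Savitzky-Golay window length (points); default 13.
#' @param sg_polyorder Savitzky-Golay polynomial order, `< sg_points`;
#'   default 2 (the standard chemometric choice for first derivatives).
#' @param label Optional human-readable label.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "msc", "sg1d"),
                            window_low = 4000, window_high = 10000,
                            sg_points = 13L, sg_polyorder = 2L,
                            label = NULL) {
  method <- match.arg(method)
  sg_points <- as.integer(sg_points)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_points < 5L || sg_points %% 2L == 0L) {
    stop("parameter error: sg_points must be odd and >= 5", call. = FALSE)
  }
  if (sg_polyorder < 1L || sg_polyorder >= sg_points) {
    stop("parameter error: sg_polyorder must be in [1, sg_points)",
         call. = FALSE)
  }
  if (!(window_low < window_high)) {
    stop("parameter error: window_low must be < window_high", call. = FALSE)
  }
  if (is.null(label)) {
    label <- sprintf("%s %g-%g", method, window_low, window_high)
  }
  structure(list(method = method, window_low = window_low,
                 window_high = window_high, sg_points = sg_points,
                 sg_polyorder = sg_polyorder, label = label),
            class = "preprocess_spec")
}

#' @export
print.preprocess_spec <- function(x, ...) {
  cat(sprintf("preprocess_spec: %s, window %g-%g cm^-1", x$method,
              x$window_low, x$window_high))
  if (x$method == "sg1d") {
    cat(sprintf(" (SG %d pts, order %d)", x$sg_points, x$sg_polyorder))
  }
  cat("\n")
  invisible(x)
}

#' Mean reference spectrum for multiplicative scatter correction
#'
#' @param calibration A `spectra_set` with at least two spectra (the
#'   calibration standards of the analyte being modeled).
#' @return Numeric vector: the pointwise mean calibration spectrum.
#' @export
msc_fit_reference <- function(calibration) {
  stopifnot(inherits(calibration, "spectra_set"))
  if (n_spectra(calibration) < 2L) {
    stop("insufficient-data error: MSC reference needs >= 2 spectra",
         call. = FALSE)
  }
  colMeans(calibration$absorbance)
}

#' Multiplicative scatter correction of one spectrum
#'
#' Regresses the spectrum on the reference by ordinary least squares,
#' `x = a + b * reference + e`, and returns `(x - a) / b`. Removes the
#' additive offset and multiplicative gain caused by scattering from
#' un-smooth sample surfaces.
#'
#' @param spectrum Numeric vector of absorbance values.
#' @param reference Numeric reference spectrum of equal length (not
#'   constant).
#' @return List with `corrected`, `a` (intercept) and `b` (slope).
#' @export
msc_correct <- function(spectrum, reference) {
  if (length(spectrum) != length(reference)) {
    stop("dimension error: spectrum and reference lengths differ",
         call. = FALSE)
  }
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss < 1e-12 * length(reference)) {
    stop("degenerate-fit error: constant reference spectrum", call. = FALSE)
  }
  b <- sum(rc * spectrum) / ss
  a <- mean(spectrum) - b * mean(reference)
  if (abs(b) < 1e-12) {
    stop("degenerate-fit error: MSC slope ~ 0", call. = FALSE)
  }
  list(corrected = (spectrum - a) / b, a = a, b = b)
}

# MSC over all rows of a spectra_set; returns corrected set plus msc_fit
msc_correct_set <- function(set, reference) {
  n <- n_spectra(set)
  a <- numeric(n); b <- numeric(n)
  A <- set$absorbance
  for (i in seq_len(n)) {
    res <- msc_correct(A[i, ], reference)
    A[i, ] <- res$corrected
    a[i] <- res$a; b[i] <- res$b
  }
  names(a) <- names(b) <- rownames(set$absorbance)
  set$absorbance <- A
  list(set = set,
       fit = structure(list(reference = reference, a = a, b = b),
                       class = "msc_fit"))
}

#' Savitzky-Golay first derivative of a spectrum
#'
#' Local polynomial least-squares first derivative with respect to
#' wavenumber on the ascending grid. The convolution is applied only where
#' the full window fits, so `(sg_points - 1) / 2` points are dropped at
#' each edge rather than padded — padding would fabricate data at the
#' spectral edges where scatter is worst.
#'
#' @param absorbance Numeric vector (or matrix, samples in rows).
#' @param wavenumbers Ascending uniform grid matching the columns.
#' @param sg_points Odd window length; default 13.
#' @param sg_polyorder Polynomial order; default 2.
#' @return List with `wavenumbers` (interior grid) and `absorbance`
#'   (derivative values, AU per cm^-1; matrix if the input was a matrix).
#' @export
sg_first_derivative <- function(absorbance, wavenumbers, sg_points = 13L,
                                sg_polyorder = 2L) {
  vec_in <- is.null(dim(absorbance))
  A <- if (vec_in) matrix(absorbance, nrow = 1) else as.matrix(absorbance)
  p <- ncol(A)
  if (p != length(wavenumbers)) {
    stop("dimension error: absorbance/grid length mismatch", call. = FALSE)
  }
  if (p < sg_points) {
    stop("length error: spectrum shorter than the SG window", call. = FALSE)
  }
  step <- check_uniform_grid(wavenumbers)
  h <- (sg_points - 1L) %/% 2L
  Fm <- signal::sgolay(p = sg_polyorder, n = sg_points, m = 1, ts = step)
  coefs <- Fm[h + 1L, ]  # central-row filter: exact interior derivative
  idx <- (h + 1L):(p - h)
  D <- matrix(0, nrow = nrow(A), ncol = length(idx),
              dimnames = list(rownames(A), NULL))
  for (j in seq_along(idx)) {
    D[, j] <- A[, (idx[j] - h):(idx[j] + h), drop = FALSE] %*% coefs
  }
  out_w <- wavenumbers[idx]
  if (vec_in) D <- drop(D)
  list(wavenumbers = out_w, absorbance = D)
}

#' Apply a preprocessing recipe to a spectra set
#'
#' Order of operations is window restriction first, then the pre-treatment.
#' For `method = "msc"`, the reference is the mean of this set when
#' `msc_reference` is `NULL` (calibration use); for validation and unknown
#' sets the reference frozen from calibration must be supplied so that no
#' information leaks from test spectra into the correction.
#'
#' @param set A `spectra_set`.
#' @param spec A [preprocess_spec()].
#' @param msc_reference Optional frozen MSC reference spectrum (on the
#'   windowed grid) from the calibration set.
#' @return List with `set` (the transformed `spectra_set`) and `msc_fit`
#'   (an `msc_fit` object for `method = "msc"`, otherwise `NULL`).
#' @export
apply_preprocess <- function(set, spec, msc_reference = NULL) {
  stopifnot(inherits(set, "spectra_set"), inherits(spec, "preprocess_spec"))
  out <- restrict_window(set, spec$window_low, spec$window_high)
  msc_fit <- NULL
  if (spec$method == "msc") {
    ref <- if (is.null(msc_reference)) msc_fit_reference(out) else
      msc_reference
    if (length(ref) != length(out$wavenumbers)) {
      stop("dimension error: MSC reference does not match windowed grid",
           call. = FALSE)
    }
    res <- msc_correct_set(out, ref)
    out <- res$set
    msc_fit <- res$fit
  } else if (spec$method == "sg1d") {
    d <- sg_first_derivative(out$absorbance, out$wavenumbers,
                             spec$sg_points, spec$sg_polyorder)
    out$wavenumbers <- d$wavenumbers
    out$absorbance <- d$absorbance
  }
  list(set = out, msc_fit = msc_fit)
}
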