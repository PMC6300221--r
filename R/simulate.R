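#' Default instrument wavenumber grid
#'
#' 4000 to 10000 cm^-1 at 2 cm^-1 resolution (3001 points), the FT-NIR
#' absorption-mode configuration the pipeline assumes.
#'
#' @return Ascending numeric vector of wavenumbers.
#' @export
default_grid <- function() seq(4000, 10000, by = 2)

#' Construct a Gaussian absorption band
#'
#' @param center Band center, cm^-1 (inside 4000-10000).
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param amplitude Peak absorbance per uM (>= 0).
#' @return A `band` object.
#' @export
band <- function(center, width, amplitude) {
  if (width <= 0 || amplitude < 0 || center < 4000 || center > 10000) {
    stop("domain error: invalid band parameters", call. = FALSE)
  }
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band")
}

#' Construct an analyte spectral signature
#'
#' @param hormone Hormone name (`"IAA"`, `"GA"`, `"SA"`, `"kinetin"`) or
#'   `"interferent"`.
#' @param bands List of [band()] objects (at least one).
#' @return An `analyte_signature` object.
#' @export
analyte_signature <- function(hormone, bands) {
  if (!hormone %in% c(HORMONES, "interferent")) {
    stop("domain error: unknown analyte '", hormone, "'", call. = FALSE)
  }
  if (!length(bands)) {
    stop("domain error: signature needs >= 1 band", call. = FALSE)
  }
  structure(list(hormone = hormone, bands = bands),
            class = "analyte_signature")
}

# build a signature from parallel vectors and normalize so that the pure
# spectrum at `at_conc` uM peaks at `peak_au` absorbance units
make_signature <- function(hormone, centers, widths, rel_amps,
                           at_conc = 250, peak_au = 1.0) {
  sig <- analyte_signature(hormone, Map(band, centers, widths, rel_amps))
  peak <- max(pure_spectrum(sig, at_conc, default_grid())$absorbance)
  scale <- peak_au / peak
  sig$bands <- lapply(sig$bands, function(b) {
    b$amplitude <- b$amplitude * scale
    b
  })
  sig
}

#' Built-in spectral signatures of the four hormones and the matrix
#'
#' Band centers follow the assigned NIR combination and overtone bands of
#' each hormone (e.g. the 4500 cm^-1 C-H/N-H combination bands, the
#' salicylic acid O-H combination at 5000 cm^-1, the kinetin N-H first
#' overtone at 6700 cm^-1). Widths default to a 40 cm^-1 sigma for
#' combination-region bands and for each hormone's dominant band, and
#' 80 cm^-1 for the minor overtone-region bands. Relative
#' amplitudes are design constants: each hormone has one dominant band
#' that no other analyte shares (relative amplitude 1 — IAA 5900, GA
#' 4700, SA 5000, kinetin 6700 cm^-1) while every other assigned band,
#' being shared with or adjacent to another analyte's bands, enters at
#' 0.005, so that the normalized between-analyte spectral cross-talk
#' stays well below 1% and single-analyte calibrations remain valid
#' on mixtures.
#' Each hormone signature is scaled so a 250 uM pure solution peaks at
#' ~1.0 AU. A broad methanol/matrix interferent signature (bands near
#' 4300, 5150 and 6900 cm^-1, peak 0.1 AU at unit level) is included.
#'
#' @return Named list of `analyte_signature` objects
#'   (`IAA`, `GA`, `SA`, `kinetin`, `interferent`).
#' @export
default_signatures <- function() {
  list(
    IAA = make_signature("IAA",
      centers = c(4150, 4500, 5200, 5900, 7100, 9100),
      widths = c(40, 40, 40, 40, 80, 80),
      rel_amps = c(0.005, 0.005, 0.005, 1.0, 0.005, 0.005)),
    GA = make_signature("GA",
      centers = c(4500, 4700, 5200, 7150),
      widths = c(40, 40, 40, 80),
      rel_amps = c(0.005, 1.0, 0.005, 0.005)),
    SA = make_signature("SA",
      centers = c(4150, 5000, 5200, 7100),
      widths = c(40, 40, 40, 80),
      rel_amps = c(0.005, 1.0, 0.005, 0.005)),
    kinetin = make_signature("kinetin",
      centers = c(4400, 5100, 6700, 8800),
      widths = c(40, 40, 40, 80),
      rel_amps = c(0.005, 0.005, 1.0, 0.005)),
    interferent = make_signature("interferent",
      centers = c(4300, 5150, 6900),
      widths = c(200, 200, 250),
      rel_amps = c(1.0, 0.8, 0.6),
      at_conc = 1, peak_au = 0.1))
}

#' Noise and scatter model for simulated spectra
#'
#' Each simulated spectrum x is transformed as
#' `b * x + a + drift(v) + e`, with per-spectrum multiplicative gain
#' `b ~ lognormal(0, sigma_b)` (scattering from un-smooth surfaces),
#' additive offset `a ~ N(0, sigma_a)` AU, a smooth random baseline
#' drift of pointwise standard deviation `sigma_tilt` AU (a zero-mean
#' Gaussian-process-like curve: a random linear tilt plus band-limited
#' curvature with ~130 cm^-1 correlation length — instrument baselines
#' and fringing wander smoothly, they are not straight lines), and white
#' noise `e ~ N(0, sigma_white)` AU per point. The defaults make the
#' smooth baseline drift the dominant structured corruption: it is too
#' high-dimensional for a 7-factor model on raw spectra to reject, while
#' the first derivative suppresses it structurally, so derivative
#' pre-treatment measurably improves external prediction over both no
#' pre-treatment and plain scatter correction.
#'
#' @param sigma_b Lognormal sigma of the multiplicative gain; default
#'   0.002.
#' @param sigma_a Sigma of the additive offset, AU; default 0.002.
#' @param sigma_tilt Pointwise standard deviation of the smooth baseline
#'   drift, AU; default 0.005.
#' @param sigma_white Sigma of per-point white noise, AU; default 0.003.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sigma_b = 0.002, sigma_a = 0.002,
                        sigma_tilt = 0.005, sigma_white = 0.003) {
  vals <- c(sigma_b, sigma_a, sigma_tilt, sigma_white)
  if (any(vals < 0)) {
    stop("parameter error: noise sigmas must be >= 0", call. = FALSE)
  }
  structure(list(sigma_b = sigma_b, sigma_a = sigma_a,
                 sigma_tilt = sigma_tilt, sigma_white = sigma_white),
            class = "noise_model")
}

#' Zero-noise model
#' @return A `noise_model` with every sigma 0.
#' @export
noise_none <- function() noise_model(0, 0, 0, 0)

# smooth baseline drift basis: a linear ramp plus cosine curvature terms
# with Gaussian spectral decay, approximating a squared-exponential
# Gaussian process with ~130 cm^-1 correlation length over the default
# range; columns scaled so N(0, 1) coefficients give unit pointwise sd
drift_basis <- function(wavenumbers, kmax = 60L, k0 = 29) {
  x <- (wavenumbers - min(wavenumbers)) / diff(range(wavenumbers))
  cols <- lapply(seq_len(kmax), function(k) cos(pi * k * x))
  B <- do.call(cbind, c(list(x - mean(x)), cols))
  B <- sweep(B, 2L, apply(B, 2L, stats::sd), "/")
  amp <- c(1, exp(-(seq_len(kmax) / k0)^2))
  B <- sweep(B, 2L, amp, "*")
  B / sqrt(sum(amp^2))
}

# apply the noise model to a matrix of clean spectra (rows = samples);
# draws from the current RNG stream
apply_noise <- function(A, wavenumbers, noise) {
  n <- nrow(A); p <- ncol(A)
  if (n == 0L) return(A)
  b <- stats::rlnorm(n, 0, noise$sigma_b)
  a <- stats::rnorm(n, 0, noise$sigma_a)
  basis <- drift_basis(wavenumbers)
  drift_coef <- matrix(stats::rnorm(n * ncol(basis), 0, noise$sigma_tilt),
                       n, ncol(basis))
  A * b + a + tcrossprod(drift_coef, basis) +
    matrix(stats::rnorm(n * p, 0, noise$sigma_white), n, p)
}

#' Noise-free Beer-Lambert spectrum of one analyte
#'
#' `A(v) = conc * sum_b amplitude_b * exp(-(v - center_b)^2 /
#' (2 width_b^2))` — absorbance linear in concentration.
#'
#' @param signature An `analyte_signature`.
#' @param concentration Concentration in uM (>= 0).
#' @param grid Wavenumber grid; default [default_grid()].
#' @return List with `wavenumbers` and `absorbance`.
#' @export
pure_spectrum <- function(signature, concentration, grid = default_grid()) {
  stopifnot(inherits(signature, "analyte_signature"))
  if (concentration < 0) {
    stop("domain error: negative concentration", call. = FALSE)
  }
  a <- numeric(length(grid))
  for (b in signature$bands) {
    a <- a + b$amplitude * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }
  list(wavenumbers = grid, absorbance = concentration * a)
}

#' Simulate standard-solution calibration spectra
#'
#' Per hormone, `levels` distinct concentrations spaced log-uniformly
#' (default) or linearly over `[c_min, c_max]` uM. Each standard spectrum
#' is the pure Beer-Lambert spectrum plus the matrix interferent at a
#' fixed level plus one noise realization. Reproducible: the same seed
#' gives bit-identical output.
#'
#' @param signatures Named signature list; default [default_signatures()].
#'   Entries named after hormones are simulated; an `interferent` entry is
#'   added to every spectrum at `interferent_level`.
#' @param levels Concentration levels per hormone; default 65.
#' @param c_min,c_max Concentration range in uM; defaults 0.1 and 250.
#' @param noise A [noise_model()]; default the standard model.
#' @param grid Wavenumber grid; default [default_grid()].
#' @param seed Integer seed.
#' @param spacing `"log"` (default) or `"linear"`.
#' @param interferent_level Fixed interferent level; default 1.
#' @return A `spectra_set` of `levels * n_hormones` standards with filled
#'   metadata (role `"standard"`).
#' @export
generate_standards <- function(signatures = default_signatures(),
                               levels = 65L, c_min = 0.1, c_max = 250,
                               noise = noise_model(), grid = default_grid(),
                               seed = 1L, spacing = c("log", "linear"),
                               interferent_level = 1) {
  spacing <- match.arg(spacing)
  if (levels < 2L) {
    stop("parameter error: need >= 2 levels", call. = FALSE)
  }
  if (spacing == "log" && c_min <= 0) {
    stop("parameter error: log spacing needs c_min > 0", call. = FALSE)
  }
  conc <- if (spacing == "log") {
    exp(seq(log(c_min), log(c_max), length.out = levels))
  } else {
    seq(c_min, c_max, length.out = levels)
  }
  hormones <- intersect(names(signatures), HORMONES)
  if (!length(hormones)) {
    stop("parameter error: no hormone signatures supplied", call. = FALSE)
  }
  interf <- if ("interferent" %in% names(signatures)) {
    interferent_level *
      pure_spectrum(signatures$interferent, 1, grid)$absorbance
  } else numeric(length(grid))
  rows <- list(); meta <- list()
  with_local_seed(seed, {
    for (h in hormones) {
      base <- pure_spectrum(signatures[[h]], 1, grid)$absorbance
      A <- outer(conc, base) + matrix(interf, levels, length(grid),
                                      byrow = TRUE)
      A <- apply_noise(A, grid, noise)
      ids <- sprintf("std_%s_%02d", h, seq_len(levels))
      rownames(A) <- ids
      rows[[h]] <- A
      meta[[h]] <- data.frame(sample_id = ids, role = "standard",
                              analyte = h, concentration_uM = conc,
                              population = NA, replicate = NA)
    }
  })
  spectra_set(grid, do.call(rbind, rows), do.call(rbind, meta))
}

#' Simulate population extract spectra with known ground truth
#'
#' Each replicate spectrum is the Beer-Lambert sum of all hormones at the
#' population's true concentrations, plus the matrix interferent and one
#' noise realization — a multi-analyte "leaf extract" panel.
#'
#' @param truth Numeric matrix of true concentrations in uM, populations
#'   in rows (named), hormones in columns (named subset of
#'   `IAA, GA, SA, kinetin`); all nonnegative.
#' @param replicates Replicate spectra per population; default 3.
#' @param noise,grid,seed,signatures,interferent_level As in
#'   [generate_standards()].
#' @return A `spectra_set` of `nrow(truth) * replicates` unknowns with
#'   population and replicate metadata.
#' @export
generate_extracts <- function(truth, replicates = 3L,
                              noise = noise_model(), grid = default_grid(),
                              seed = 1L,
                              signatures = default_signatures(),
                              interferent_level = 1) {
  truth <- as.matrix(truth)
  if (any(truth < 0)) {
    stop("domain error: truth concentrations must be nonnegative",
         call. = FALSE)
  }
  if (is.null(rownames(truth))) {
    rownames(truth) <- sprintf("POP%d", seq_len(nrow(truth)))
  }
  hs <- colnames(truth)
  if (is.null(hs) || !all(hs %in% HORMONES)) {
    stop("parameter error: truth columns must be named after hormones",
         call. = FALSE)
  }
  bases <- vapply(hs, function(h)
    pure_spectrum(signatures[[h]], 1, grid)$absorbance,
    numeric(length(grid)))
  interf <- if ("interferent" %in% names(signatures)) {
    interferent_level *
      pure_spectrum(signatures$interferent, 1, grid)$absorbance
  } else numeric(length(grid))
  clean <- truth %*% t(bases) + matrix(interf, nrow(truth), length(grid),
                                       byrow = TRUE)
  n <- nrow(truth) * replicates
  A <- clean[rep(seq_len(nrow(truth)), each = replicates), , drop = FALSE]
  A <- with_local_seed(seed, apply_noise(A, grid, noise))
  pop <- rep(rownames(truth), each = replicates)
  rep_id <- rep(seq_len(replicates), times = nrow(truth))
  ids <- sprintf("unk_%s_r%d", pop, rep_id)
  rownames(A) <- ids
  meta <- data.frame(sample_id = ids, role = "unknown", analyte = NA,
                     concentration_uM = NA, population = pop,
                     replicate = rep_id)
  spectra_set(grid, A, meta)
}
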