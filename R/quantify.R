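#' Default molar masses of the four phytohormones
#'
#' Standard constants in g/mol: indole-3-acetic acid 175.18, gibberellic
#' acid (GA3) 346.37, salicylic acid 138.12, kinetin 215.21.
#'
#' @return Named numeric vector.
#' @export
hormone_molar_masses <- function() {
  c(IAA = 175.18, GA = 346.37, SA = 138.12, kinetin = 215.21)
}

#' Unit-conversion context for extract concentrations
#'
#' Holds the quantities that connect a solution concentration (uM) to a
#' tissue content (ug per g fresh weight): molar masses, the methanol
#' extract volume and the extracted fresh tissue mass. The extract volume
#' is the one quantity a report must always state alongside converted
#' values — change it here if your extraction used a different volume.
#'
#' @param molar_mass Named g/mol vector per hormone; default
#'   [hormone_molar_masses()].
#' @param extract_volume_L Extract volume in liters; default 0.010.
#' @param tissue_mass_g Fresh tissue mass in grams; default 1.0.
#' @return An object of class `unit_context`.
#' @export
unit_context <- function(molar_mass = hormone_molar_masses(),
                         extract_volume_L = 0.010, tissue_mass_g = 1.0) {
  if (any(molar_mass <= 0) || extract_volume_L <= 0 || tissue_mass_g <= 0) {
    stop("parameter error: unit context values must be positive",
         call. = FALSE)
  }
  structure(list(molar_mass = molar_mass,
                 extract_volume_L = extract_volume_L,
                 tissue_mass_g = tissue_mass_g),
            class = "unit_context")
}

#' Convert a solution concentration to tissue mass per fresh weight
#'
#' `ug/g FW = conc_uM * 1e-6 mol/L * molar_mass g/mol * extract_volume_L
#' * 1e6 ug/g / tissue_mass_g`.
#'
#' @param conc_uM Concentration(s) in uM.
#' @param ctx A [unit_context()].
#' @param hormone Hormone name used to pick the molar mass.
#' @return Content in ug per g fresh weight.
#' @seealso [from_mass_per_fw()] for the inverse.
#' @export
to_mass_per_fw <- function(conc_uM, ctx, hormone) {
  stopifnot(inherits(ctx, "unit_context"))
  mm <- ctx$molar_mass[[hormone]]
  conc_uM * mm * ctx$extract_volume_L / ctx$tissue_mass_g
}

#' Convert tissue content back to solution concentration
#'
#' Inverse of [to_mass_per_fw()]; used to turn reported ug/g FW profiles
#' into the uM ground truth of simulated extracts.
#'
#' @param mass_ug_per_g Content in ug per g fresh weight.
#' @param ctx A [unit_context()].
#' @param hormone Hormone name.
#' @return Concentration in uM.
#' @export
from_mass_per_fw <- function(mass_ug_per_g, ctx, hormone) {
  stopifnot(inherits(ctx, "unit_context"))
  mm <- ctx$molar_mass[[hormone]]
  mass_ug_per_g * ctx$tissue_mass_g / (mm * ctx$extract_volume_L)
}

#' Predict unknown extract spectra with a calibrated model
#'
#' Applies the model's frozen preprocessing recipe (window, SG derivative
#' parameters, MSC reference from calibration) to the unknown spectra and
#' predicts concentrations. Negative predictions are returned as-is with a
#' flag rather than clipped, so extrapolation below the calibration range
#' stays visible; set `clip_negative = TRUE` to truncate at zero.
#'
#' @param model A `pls_model` carrying `preprocess` (and `msc_fit` when the
#'   recipe uses MSC), as produced by [calibrate_analyte()].
#' @param unknowns `spectra_set` of unknown samples (role `"unknown"`).
#' @param clip_negative Truncate negative predictions at zero? Default
#'   `FALSE`.
#' @return Data frame with `sample_id`, `population`, `replicate`,
#'   `analyte`, `conc_uM`, `flag_negative`.
#' @export
predict_unknowns <- function(model, unknowns, clip_negative = FALSE) {
  stopifnot(inherits(model, "pls_model"), inherits(unknowns, "spectra_set"))
  if (is.null(model$preprocess)) {
    stop("parameter error: model carries no preprocessing recipe",
         call. = FALSE)
  }
  spec <- model$preprocess
  if (min(unknowns$wavenumbers) > spec$window_low ||
      max(unknowns$wavenumbers) < spec$window_high) {
    stop("dimension error: unknown grid does not cover the model window",
         call. = FALSE)
  }
  X <- preprocess_frozen(unknowns, spec, model$msc_fit)
  if (ncol(X) != length(model$x_mean)) {
    stop("dimension error: preprocessed unknowns do not match the model ",
         "grid", call. = FALSE)
  }
  conc <- pls_predict(model, X)
  flag <- conc < 0
  if (clip_negative) conc <- pmax(conc, 0)
  data.frame(sample_id = unknowns$meta$sample_id,
             population = unknowns$meta$population,
             replicate = unknowns$meta$replicate,
             analyte = if (is.null(model$analyte)) NA_character_ else
               model$analyte,
             conc_uM = conc, flag_negative = flag)
}

#' Aggregate replicate predictions into population hormone profiles
#'
#' Per population and hormone: the mean over replicates and the standard
#' error `sd / sqrt(n)`. A population with a single replicate gets SE 0
#' and is flagged.
#'
#' @param values Data frame with columns `population`, `replicate`,
#'   `analyte` and a value column (default `value`; predictions from
#'   [predict_unknowns()] use `conc_uM`).
#' @param value_col Name of the value column.
#' @return Data frame with `population`, `analyte`, `mean`, `se`, `n`,
#'   `flag_single_replicate`, ordered by population then analyte.
#' @export
aggregate_population <- function(values, value_col = "value") {
  values <- as.data.frame(values)
  if (!value_col %in% names(values)) {
    if ("conc_uM" %in% names(values)) value_col <- "conc_uM" else
      stop("parameter error: no value column '", value_col, "'",
           call. = FALSE)
  }
  if (any(is.na(values$population))) {
    stop("metadata error: every value needs a population label",
         call. = FALSE)
  }
  key <- interaction(values$population, values$analyte, drop = TRUE)
  rows <- lapply(split(values, key), function(d) {
    v <- d[[value_col]]
    n <- length(v)
    data.frame(population = d$population[1], analyte = d$analyte[1],
               mean = mean(v),
               se = if (n > 1L) stats::sd(v) / sqrt(n) else 0,
               n = n, flag_single_replicate = n == 1L)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$population, out$analyte), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hormone profiles in wide matrix form
#'
#' @param profiles Long data frame from [aggregate_population()] (or any
#'   frame with `population`, `analyte` and a value column).
#' @param value_col Column to spread; default `"mean"`.
#' @return Numeric matrix, populations in rows, hormones in columns
#'   (ordered IAA, GA, SA, kinetin where present).
#' @export
profile_matrix <- function(profiles, value_col = "mean") {
  profiles <- as.data.frame(profiles)
  pops <- unique(profiles$population)
  hs <- intersect(HORMONES, unique(profiles$analyte))
  if (!length(hs)) hs <- unique(profiles$analyte)
  M <- matrix(NA_real_, length(pops), length(hs),
              dimnames = list(pops, hs))
  for (i in seq_len(nrow(profiles))) {
    M[profiles$population[i], profiles$analyte[i]] <-
      profiles[[value_col]][i]
  }
  M
}
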