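MODEL_FORMAT_VERSION <- 1L

#' Save a fitted PLS model to a JSON file
#'
#' Serializes every model component — centering terms, weights, loadings,
#' folded coefficients, the preprocessing recipe and the frozen MSC
#' reference — with full double precision and a format version, so a
#' saved calibration predicts identically after reload.
#'
#' @param model A `pls_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    analyte = model$analyte,
    n_factors = model$n_factors,
    x_mean = model$x_mean,
    y_mean = model$y_mean,
    weights = model$weights,
    x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    scores_ss = model$scores_ss,
    x_ss_total = model$x_ss_total,
    coefficients = model$coefficients,
    coef_path = model$coef_path,
    preprocess = if (!is.null(model$preprocess))
      unclass(model$preprocess) else NULL,
    msc_fit = if (!is.null(model$msc_fit))
      list(reference = model$msc_fit$reference) else NULL)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor", null = "null")
  invisible(path)
}

#' Load a PLS model saved by [save_pls_model()]
#'
#' @param path Path to the JSON model file.
#' @return A `pls_model`.
#' @export
load_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version > MODEL_FORMAT_VERSION) {
    stop("format error: unsupported model file version", call. = FALSE)
  }
  as_mat <- function(m, p) {
    if (is.null(m) || !length(m)) return(matrix(0, p, 0))
    matrix(as.numeric(m), nrow = p)
  }
  p <- length(obj$x_mean)
  model <- structure(list(
    x_mean = as.numeric(obj$x_mean),
    y_mean = as.numeric(obj$y_mean),
    weights = as_mat(obj$weights, p),
    x_loadings = as_mat(obj$x_loadings, p),
    y_loadings = as.numeric(obj$y_loadings),
    scores_ss = as.numeric(obj$scores_ss),
    x_ss_total = as.numeric(obj$x_ss_total),
    coefficients = as.numeric(obj$coefficients),
    coef_path = as_mat(obj$coef_path, p),
    n_factors = as.integer(obj$n_factors),
    preprocess = NULL, msc_fit = NULL,
    analyte = obj$analyte), class = "pls_model")
  if (!is.null(obj$preprocess)) {
    pp <- obj$preprocess
    model$preprocess <- preprocess_spec(pp$method, pp$window_low,
                                        pp$window_high, pp$sg_points,
                                        pp$sg_polyorder, pp$label)
  }
  if (!is.null(obj$msc_fit)) {
    model$msc_fit <- structure(
      list(reference = as.numeric(obj$msc_fit$reference),
           a = NULL, b = NULL), class = "msc_fit")
  }
  model
}

#' Reference candidate-metrics grid
#'
#' The six-candidate preprocessing comparison for each of the four
#' hormones from a reference FT-NIR phytohormone calibration study of
#' *Boswellia sacra* leaf extracts: per candidate the preprocessing
#' method, wavenumber window, RMSEC, calibration R-squared, RMSEP,
#' prediction R-squared and factor count. Used as the worked example for
#' [select_model()] and as a regression fixture for the selection rule.
#'
#' @param analyte Optional hormone name to filter to one block.
#' @return Data frame of candidate reports (`rmsecv` is `NA`: the source
#'   table reports no cross-validation column).
#' @export
reference_candidate_metrics <- function(analyte = NULL) {
  path <- system.file("extdata", "candidate_metrics.csv",
                      package = "phytoNIR", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$rmsecv <- NA_real_
  if (!is.null(analyte)) {
    analyte_ <- match.arg(analyte, HORMONES)
    df <- df[df$analyte == analyte_, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Reference population hormone profiles
#'
#' Mean and standard error (n = 3 replicates) of the four hormone
#' contents, in ug per g fresh weight, for thirteen *B. sacra*
#' populations from the same reference study. Used as ground truth for
#' the closed-loop simulation study and as the worked example for the
#' population statistics.
#'
#' @return Data frame with columns `population`, `analyte`, `mean`, `se`,
#'   `n`.
#' @export
reference_profiles <- function() {
  path <- system.file("extdata", "population_profiles.csv",
                      package = "phytoNIR", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
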