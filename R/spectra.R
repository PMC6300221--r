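#' @keywords internal
"_PACKAGE"

HORMONES <- c("IAA", "GA", "SA", "kinetin")

META_COLUMNS <- c("sample_id", "role", "analyte", "concentration_uM",
                  "population", "replicate")

#' Construct a set of NIR spectra on a shared wavenumber grid
#'
#' A `spectra_set` is the container every stage of the pipeline operates on:
#' an absorbance matrix (one row per sample) on a common, strictly ascending,
#' uniformly spaced wavenumber grid, plus a per-sample metadata table.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1. May be given
#'   descending (instrument order); it is normalized to ascending and the
#'   absorbance columns are reordered to match. Spacing must be uniform to a
#'   relative tolerance of 1e-6.
#' @param absorbance Numeric matrix, `n_samples x length(wavenumbers)`, with
#'   row names giving the sample ids (or supply `meta$sample_id` in matching
#'   order). All values must be finite.
#' @param meta Data frame with columns `sample_id`, `role` (`"standard"` or
#'   `"unknown"`), `analyte`, `concentration_uM`, `population`, `replicate`.
#'   Standards must carry `analyte` and a nonnegative `concentration_uM`;
#'   unknowns must carry `population`. Missing optional columns are added
#'   as `NA`.
#' @return An object of class `spectra_set` with elements `wavenumbers`,
#'   `absorbance` and `meta`.
#' @examples
#' grid <- seq(4000, 4020, by = 2)
#' A <- matrix(runif(22), nrow = 2,
#'             dimnames = list(c("s1", "s2"), NULL))
#' meta <- data.frame(sample_id = c("s1", "s2"), role = "standard",
#'                    analyte = "SA", concentration_uM = c(1, 10))
#' spectra_set(grid, A, meta)
#' @export
spectra_set <- function(wavenumbers, absorbance, meta) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.null(dim(absorbance))) {
    absorbance <- matrix(absorbance, nrow = 1)
  }
  absorbance <- as.matrix(absorbance)
  if (length(wavenumbers) < 2L) {
    stop("grid error: need at least two wavenumber points", call. = FALSE)
  }
  if (is.unsorted(wavenumbers, strictly = TRUE)) {
    if (is.unsorted(rev(wavenumbers), strictly = TRUE)) {
      stop("grid error: wavenumbers must be strictly monotonic", call. = FALSE)
    }
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  check_uniform_grid(wavenumbers)
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("format error: absorbance has ", ncol(absorbance),
         " columns but grid has ", length(wavenumbers), " points",
         call. = FALSE)
  }
  if (nrow(absorbance) > 0 && !all(is.finite(absorbance))) {
    stop("format error: non-finite absorbance values", call. = FALSE)
  }
  meta <- normalize_meta(meta)
  if (is.null(rownames(absorbance))) {
    if (nrow(absorbance) != nrow(meta)) {
      stop("metadata error: ", nrow(absorbance), " spectra but ",
           nrow(meta), " metadata rows", call. = FALSE)
    }
    rownames(absorbance) <- meta$sample_id
  }
  ids <- rownames(absorbance)
  if (anyDuplicated(ids)) {
    stop("metadata error: duplicate sample_id", call. = FALSE)
  }
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing)) {
    stop("metadata error: no metadata for sample(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  validate_meta(meta)
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "spectra_set")
}

check_uniform_grid <- function(w, rel_tol = 1e-6) {
  d <- diff(w)
  step <- stats::median(d)
  if (any(abs(d - step) > rel_tol * abs(step))) {
    stop("grid error: wavenumber spacing is not uniform", call. = FALSE)
  }
  invisible(step)
}

normalize_meta <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("metadata error: missing sample_id column", call. = FALSE)
  }
  for (col in META_COLUMNS) {
    if (!col %in% names(meta)) meta[[col]] <- rep(NA, nrow(meta))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$role <- as.character(meta$role)
  meta$analyte <- as.character(meta$analyte)
  meta$analyte[!is.na(meta$analyte) & meta$analyte == ""] <- NA
  meta$population <- as.character(meta$population)
  meta$population[!is.na(meta$population) & meta$population == ""] <- NA
  meta$concentration_uM <- as.numeric(meta$concentration_uM)
  meta$replicate <- as.integer(meta$replicate)
  meta[, META_COLUMNS, drop = FALSE]
}

validate_meta <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    stop("metadata error: duplicate sample_id", call. = FALSE)
  }
  bad_role <- !meta$role %in% c("standard", "unknown")
  if (any(bad_role)) {
    stop("metadata error: role must be 'standard' or 'unknown'",
         call. = FALSE)
  }
  std <- meta$role == "standard"
  if (any(std & (is.na(meta$analyte) | is.na(meta$concentration_uM)))) {
    stop("metadata error: standards need analyte and concentration_uM",
         call. = FALSE)
  }
  if (any(std & meta$concentration_uM < 0)) {
    stop("metadata error: negative concentration_uM", call. = FALSE)
  }
  unk <- meta$role == "unknown"
  if (any(unk & is.na(meta$population))) {
    stop("metadata error: unknowns need a population label", call. = FALSE)
  }
  invisible(meta)
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra, %d points (%.0f-%.0f cm^-1, step %g)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers),
              stats::median(diff(x$wavenumbers))))
  roles <- table(x$meta$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$absorbance)

#' Subset a spectra set by sample id
#' @param set A `spectra_set`.
#' @param ids Character vector of sample ids (all must be present).
#' @return A `spectra_set` with the selected samples, in the given order.
#' @export
subset_samples <- function(set, ids) {
  missing <- setdiff(ids, rownames(set$absorbance))
  if (length(missing)) {
    stop("metadata error: unknown sample_id ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  spectra_set(set$wavenumbers,
              set$absorbance[ids, , drop = FALSE],
              set$meta[match(ids, set$meta$sample_id), , drop = FALSE])
}

#' Read spectra and sample metadata from CSV files
#'
#' The spectra file is wide-format: first column `wavenumber_cm1`, one column
#' per sample. Rows may be written ascending or descending in wavenumber;
#' both orders yield the identical in-memory set. The metadata file carries
#' one row per sample with the `spectra_set` metadata columns.
#'
#' @param spectra_path Path to the wide-format spectra CSV.
#' @param meta_path Path to the metadata CSV.
#' @return A validated `spectra_set`.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(spectra_path, meta_path) {
  sp <- utils::read.csv(spectra_path, check.names = FALSE)
  if (ncol(sp) < 1L || names(sp)[1] != "wavenumber_cm1") {
    stop("format error: first column must be 'wavenumber_cm1'",
         call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  w <- as.numeric(sp[[1]])
  ids <- names(sp)[-1]
  if (anyDuplicated(ids)) {
    stop("metadata error: duplicate sample_id column", call. = FALSE)
  }
  A <- t(as.matrix(sp[, -1, drop = FALSE]))
  if (nrow(A) > 0 && !all(is.finite(A))) {
    stop("format error: missing or non-numeric absorbance", call. = FALSE)
  }
  rownames(A) <- ids
  spectra_set(w, A, meta)
}

#' Write spectra and sample metadata to CSV files
#'
#' Inverse of [read_spectra()]: a write/read round trip reproduces the
#' absorbance values to full double precision (values are serialized with
#' 17 significant digits).
#'
#' @param set A `spectra_set`.
#' @param spectra_path Output path for the wide-format spectra CSV.
#' @param meta_path Output path for the metadata CSV.
#' @return Invisibly, `set`.
#' @export
write_spectra <- function(set, spectra_path, meta_path) {
  stopifnot(inherits(set, "spectra_set"))
  df <- data.frame(wavenumber_cm1 = set$wavenumbers, check.names = FALSE)
  A <- t(set$absorbance)
  for (i in seq_len(nrow(set$absorbance))) {
    df[[rownames(set$absorbance)[i]]] <- A[, i]
  }
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     spectra_path, row.names = FALSE, quote = FALSE)
    utils::write.csv(set$meta, meta_path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop("I/O error: ", conditionMessage(e), call. = FALSE)
  })
  invisible(set)
}

#' Restrict a spectra set to a wavenumber window
#'
#' Keeps exactly the grid points inside the closed interval
#' `[low, high]` cm^-1 — no interpolation, matching the use of whole
#' instrument-native ranges when comparing calibration windows.
#'
#' @param set A `spectra_set`.
#' @param low,high Window bounds in cm^-1, `low < high`.
#' @return A `spectra_set` on the restricted grid; metadata unchanged.
#' @export
restrict_window <- function(set, low, high) {
  stopifnot(inherits(set, "spectra_set"))
  if (!(low < high)) {
    stop("window error: low must be < high", call. = FALSE)
  }
  keep <- set$wavenumbers >= low & set$wavenumbers <= high
  if (!any(keep)) {
    stop("window error: window [", low, ", ", high,
         "] does not intersect the grid", call. = FALSE)
  }
  out <- set
  out$wavenumbers <- set$wavenumbers[keep]
  out$absorbance <- set$absorbance[, keep, drop = FALSE]
  out
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for uncompressed `##XYDATA=(X++(Y..Y))` blocks in AFFN
#' form (each line: an X start value followed by Y values). Abscissa and
#' ordinate scaling honour `##XFACTOR`/`##YFACTOR` when present.
#'
#' @param path Path to a JCAMP-DX file.
#' @param sample_id Sample id for the resulting spectrum (default: the
#'   `##TITLE` record, or the file name).
#' @return A `spectra_set` holding the one spectrum (role `"unknown"`,
#'   population `"jcamp"` placeholder; adjust the metadata as needed).
#' @export
read_jcamp <- function(path, sample_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  getval <- function(key, default) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
  }
  xfac <- getval("XFACTOR", 1)
  yfac <- getval("YFACTOR", 1)
  start <- grep("^##XYDATA=\\(X\\+\\+\\(Y\\.\\.Y\\)\\)", lines)
  if (!length(start)) {
    stop("format error: no ##XYDATA=(X++(Y..Y)) block", call. = FALSE)
  }
  end <- grep("^##", lines)
  end <- c(end[end > start[1]], length(lines) + 1L)[1] - 1L
  body <- lines[(start[1] + 1L):end]
  body <- body[nzchar(trimws(body))]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:]]+")[[1]])
    if (any(is.na(vals)) || length(vals) < 2) {
      stop("format error: non-numeric JCAMP data line", call. = FALSE)
    }
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  # reconstruct per-point X from line-start values and the implied uniform step
  n <- length(ys)
  first_line_ny <- length(strsplit(trimws(body[1]), "[[:space:]]+")[[1]]) - 1L
  if (length(xs) > 1) {
    step <- (xs[2] - xs[1]) / first_line_ny
  } else {
    lastx <- getval("LASTX", NA)
    step <- (lastx / xfac - xs[1]) / (n - 1)
  }
  w <- (xs[1] + step * (seq_len(n) - 1L)) * xfac
  if (is.null(sample_id)) {
    title <- grep("^##TITLE=", lines, value = TRUE)
    sample_id <- if (length(title)) sub("^##TITLE=", "", title[1]) else
      basename(path)
  }
  meta <- data.frame(sample_id = sample_id, role = "unknown",
                     analyte = NA, concentration_uM = NA,
                     population = "jcamp", replicate = 1L)
  A <- matrix(ys * yfac, nrow = 1, dimnames = list(sample_id, NULL))
  spectra_set(w, A, meta)
}
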