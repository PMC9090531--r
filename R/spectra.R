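#' Spectrum set container
#'
#' A `spectrum_set` bundles a wavelength grid, an absorbance matrix
#' (rows = tablet scans, columns = wavelength channels) and per-sample
#' metadata. It is the currency passed between every pipeline stage.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing.
#' @param absorbance Numeric matrix, one row per sample, `ncol` equal to
#'   `length(wavelengths)`. No missing values allowed.
#' @param metadata Data frame with one row per sample and columns
#'   `sample_id` (unique), `brand`, `batch_id`, `channel`
#'   (`"licit"` or `"illicit"`) and `falsified` (logical).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, absorbance, metadata) {
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths) || is.unsorted(wavelengths, strictly = TRUE)) {
    stop("wavelengths must be a strictly increasing numeric vector", call. = FALSE)
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(wavelengths)) {
    stop(sprintf("absorbance has %d columns but the grid has %d wavelengths",
                 ncol(absorbance), length(wavelengths)), call. = FALSE)
  }
  if (anyNA(absorbance) || any(!is.finite(absorbance))) {
    stop("absorbance matrix contains missing or non-finite values", call. = FALSE)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  required <- c("sample_id", "brand", "batch_id", "channel", "falsified")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(metadata) != nrow(absorbance)) {
    stop("metadata rows do not match absorbance rows", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  metadata$falsified <- as.logical(metadata$falsified)
  rownames(absorbance) <- metadata$sample_id
  structure(
    list(wavelengths = wavelengths, absorbance = absorbance,
         metadata = metadata[, required, drop = FALSE]),
    class = "spectrum_set"
  )
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d channels (%.1f-%.1f nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  tab <- table(x$metadata$brand)
  cat("  brands:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (any(x$metadata$falsified)) {
    cat(sprintf("  falsified spectra: %d\n", sum(x$metadata$falsified)))
  }
  invisible(x)
}

#' Number of samples / channels in a spectrum set
#' @param x A `spectrum_set`.
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$absorbance)

#' @rdname n_samples
#' @export
n_channels <- function(x) length(x$wavelengths)

#' Subset a spectrum set by sample
#'
#' @param x A `spectrum_set`.
#' @param i Row index, logical mask over samples, or character vector of
#'   `sample_id`s.
#' @return A `spectrum_set` with the selected samples.
#' @export
subset_samples <- function(x, i) {
  if (is.character(i)) {
    i <- match(i, x$metadata$sample_id)
    if (anyNA(i)) stop("unknown sample_id in subset", call. = FALSE)
  }
  spectrum_set(x$wavelengths, x$absorbance[i, , drop = FALSE],
               x$metadata[i, , drop = FALSE])
}

# channel subset by logical/integer index over wavelengths
subset_channels <- function(x, keep) {
  spectrum_set(x$wavelengths[keep], x$absorbance[, keep, drop = FALSE],
               x$metadata)
}

#' Default wavelength grid of the handheld instrument
#'
#' 228 evenly spaced channels across the 900-1700 nm near-infrared window
#' covered by low-cost handheld dispersive spectrometers. The grid is finer
#' than the instrument's 10 nm nominal resolution so that cropping and
#' derivative filtering retain enough channels.
#'
#' @param n_channels Number of channels.
#' @param low,high Wavelength range in nm.
#' @return Numeric vector of wavelengths.
#' @export
default_wavelength_grid <- function(n_channels = 228, low = 900, high = 1700) {
  validate_wavelength_grid(seq(low, high, length.out = n_channels))
}

# grid invariants: uniform spacing, >= 32 channels
validate_wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 32) {
    stop("wavelength grid must have at least 32 channels", call. = FALSE)
  }
  d <- diff(values)
  if (any(d <= 0)) stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 0.02 * stats::median(d)) {
    stop("wavelength grid must be uniformly spaced", call. = FALSE)
  }
  values
}
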