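#' Preprocessing configuration
#'
#' The chain applied before any modeling: crop to the informative wavelength
#' window, Savitzky-Golay smoothing/differentiation, then multiplicative
#' scatter correction against the training-set mean. Defaults follow the
#' usual handheld-NIR practice: analysis restricted to 1085-1601 nm (the
#' spectral edges are noisy and less repeatable), second-degree polynomial,
#' second derivative, 11-channel window.
#'
#' @param crop_low,crop_high Crop window in nm (inclusive).
#' @param sg_window Savitzky-Golay window length in channels (odd,
#'   > `sg_polyorder`).
#' @param sg_polyorder Polynomial degree of the SG fit.
#' @param sg_deriv Derivative order (<= `sg_polyorder`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(crop_low = 1085, crop_high = 1601,
                              sg_window = 11, sg_polyorder = 2, sg_deriv = 2) {
  if (crop_low >= crop_high) stop("crop_low must be < crop_high", call. = FALSE)
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder", call. = FALSE)
  }
  if (sg_deriv > sg_polyorder) {
    stop("sg_deriv must be <= sg_polyorder", call. = FALSE)
  }
  structure(list(crop_low = crop_low, crop_high = crop_high,
                 sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv)),
            class = "preprocess_config")
}

#' Crop a spectrum set to a wavelength window
#'
#' Keeps channels with `low <= lambda <= high` (both ends inclusive);
#' metadata is unchanged.
#'
#' @param spectra A [spectrum_set()].
#' @param low,high Window in nm.
#' @return The cropped `spectrum_set`.
#' @export
crop_spectra <- function(spectra, low = 1085, high = 1601) {
  keep <- spectra$wavelengths >= low & spectra$wavelengths <= high
  if (!any(keep)) {
    stop(sprintf("cropping to [%g, %g] nm leaves no channels", low, high),
         call. = FALSE)
  }
  if (sum(keep) < 8) {
    stop(sprintf("cropping to [%g, %g] nm leaves only %d channels (need >= 8)",
                 low, high, sum(keep)), call. = FALSE)
  }
  subset_channels(spectra, keep)
}

# SG convolution weights for the derivative at the window center, scaled to
# a derivative with respect to wavelength (spacing in nm)
savgol_coefficients <- function(window, polyorder, deriv, spacing) {
  half <- (window - 1L) %/% 2L
  z <- seq.int(-half, half)
  V <- outer(z, 0:polyorder, "^")
  C <- solve(crossprod(V), t(V))        # rows = fitted polynomial coefficients
  C[deriv + 1L, ] * factorial(deriv) / spacing^deriv
}

#' Savitzky-Golay derivative filter
#'
#' Replaces each spectrum by its smoothed `deriv`-th derivative with respect
#' to wavelength in nm: a moving-window least-squares polynomial fit whose
#' analytic derivative is evaluated at the window center. The half-window
#' channels at each end are dropped (no edge padding), so the output grid is
#' shorter by `window - 1` channels.
#'
#' @param spectra A [spectrum_set()] on a uniformly spaced grid.
#' @param window Odd window length in channels.
#' @param polyorder Polynomial degree (< `window`).
#' @param deriv Derivative order (<= `polyorder`).
#' @return A `spectrum_set` on the trimmed grid.
#' @export
savgol_derivative <- function(spectra, window = 11, polyorder = 2, deriv = 2) {
  p <- n_channels(spectra)
  if (window %% 2 != 1 || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  if (deriv > polyorder) stop("deriv must be <= polyorder", call. = FALSE)
  if (window > p) {
    stop(sprintf("window (%d) exceeds channel count (%d)", window, p),
         call. = FALSE)
  }
  wl <- validate_wavelength_grid(spectra$wavelengths)
  spacing <- stats::median(diff(wl))
  coef <- savgol_coefficients(window, polyorder, deriv, spacing)
  half <- (window - 1L) %/% 2L
  centers <- seq.int(half + 1L, p - half)
  # out[, j] = sum_k coef[k] * X[, centers[j] - half - 1 + k]
  out <- matrix(0, n_samples(spectra), length(centers))
  for (k in seq_len(window)) {
    out <- out + coef[k] * spectra$absorbance[, centers - half - 1L + k, drop = FALSE]
  }
  spectrum_set(wl[centers], out, spectra$metadata)
}

#' Fit a multiplicative scatter correction reference
#'
#' The reference is the channelwise mean of the training spectra.
#'
#' @param training A [spectrum_set()] with >= 2 spectra.
#' @return An object of class `msc_reference` holding the reference spectrum,
#'   its grid and a provenance tag.
#' @export
msc_fit <- function(training) {
  if (n_samples(training) < 2) {
    stop("MSC reference requires at least 2 training spectra", call. = FALSE)
  }
  ref <- colMeans(training$absorbance)
  if (stats::var(ref) <= 0) {
    stop("MSC reference is constant (zero variance)", call. = FALSE)
  }
  structure(list(wavelengths = training$wavelengths, reference = ref,
                 provenance = "training-set mean"),
            class = "msc_reference")
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference by ordinary least squares,
#' `x = a + b * ref`, and replaced by `(x - a) / b`, removing additive and
#' multiplicative scatter.
#'
#' @param spectra A [spectrum_set()] on the reference's grid.
#' @param ref An [msc_fit()] reference.
#' @return The corrected `spectrum_set`.
#' @export
msc_apply <- function(spectra, ref) {
  if (length(ref$reference) != n_channels(spectra) ||
      max(abs(ref$wavelengths - spectra$wavelengths)) > 1e-6) {
    stop("spectra and MSC reference are on different wavelength grids",
         call. = FALSE)
  }
  r <- ref$reference
  rc <- r - mean(r)
  denom <- sum(rc^2)
  X <- spectra$absorbance
  b <- as.numeric(X %*% rc) / denom   # OLS slope; rc sums to 0 so no centering of x needed
  a <- rowMeans(X) - b * mean(r)
  bad <- abs(b) < 1e-10
  if (any(bad)) {
    stop("MSC slope below tolerance for sample(s): ",
         paste(spectra$metadata$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  corrected <- (X - a) / b
  spectrum_set(spectra$wavelengths, corrected, spectra$metadata)
}

#' Full preprocessing pipeline
#'
#' Applies crop, then Savitzky-Golay derivative, then MSC, in that fixed
#' order (cropping first keeps the noisy spectral edges out of both the
#' derivative windows and the MSC reference). With `ref = NULL` (training
#' mode) the MSC reference is fitted on the input and returned; otherwise
#' (test mode) the supplied training reference is applied, so no test
#' information leaks into the correction.
#'
#' @param spectra A [spectrum_set()].
#' @param cfg A [preprocess_config()].
#' @param ref An [msc_fit()] reference, or `NULL` to fit one.
#' @return List with `spectra` (the preprocessed set) and `reference`
#'   (the MSC reference used).
#' @export
preprocess <- function(spectra, cfg = preprocess_config(), ref = NULL) {
  out <- crop_spectra(spectra, cfg$crop_low, cfg$crop_high)
  out <- savgol_derivative(out, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv)
  if (is.null(ref)) ref <- msc_fit(out)
  out <- msc_apply(out, ref)
  list(spectra = out, reference = ref)
}
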