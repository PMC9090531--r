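#' Simulate a library of NIR tablet spectra
#'
#' Generates absorbance spectra for every tablet in a sampling design. For a
#' tablet of a batch with bands \eqn{(c_k, w_k, A_k)} and batch amplitude
#' factor \eqn{f_b}:
#' \deqn{x(\lambda) = m\,[\sum_k A_k f_b e^{-(\lambda-c_k)^2/2w_k^2}
#'   + s(\lambda-\lambda_{min})] + a + \varepsilon(\lambda)}
#' with multiplicative factor \eqn{m} log-normal (median 1), additive offset
#' \eqn{a} and baseline slope \eqn{s} normal, and channel noise
#' \eqn{\varepsilon} whose sd is larger outside the noise model's edge
#' boundaries.
#'
#' Randomness is hierarchical: every batch and every tablet gets its own
#' substream seeded from a hash of (seed, brand, channel, batch, tablet), so
#' the same seed reproduces the library bit-for-bit and adding or removing a
#' brand does not perturb the draws of the others.
#'
#' @param design A `sampling_design`, e.g. [default_study_design()].
#' @param noise A [noise_model()].
#' @param grid Wavelength grid in nm, e.g. [default_wavelength_grid()].
#' @param seed Integer seed driving all randomness.
#' @return A [spectrum_set()] with metadata populated from the design.
#' @export
simulate_spectra <- function(design, noise = noise_model(),
                             grid = default_wavelength_grid(), seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!length(design)) stop("design must be non-empty", call. = FALSE)
  grid <- validate_wavelength_grid(grid)
  centers <- unlist(lapply(design, function(e) {
    c(recipe_bands(e$recipe)$center,
      if (!is.null(e$falsified_recipe)) recipe_bands(e$falsified_recipe)$center)
  }))
  if (any(centers < min(grid)) || any(centers > max(grid))) {
    stop("grid too short for band placement: band centers fall outside the grid",
         call. = FALSE)
  }
  sd_channel <- ifelse(grid < noise$edge_boundaries[1] |
                         grid > noise$edge_boundaries[2],
                       noise$channel_noise_sd_edges, noise$channel_noise_sd_core)
  rows <- list()
  meta <- list()
  for (entry in design) {
    brand <- entry$recipe$brand
    for (b in seq_len(entry$n_batches)) {
      fake <- b > entry$n_batches - entry$falsified_batches
      recipe <- if (fake) entry$falsified_recipe else entry$recipe
      batch_id <- sprintf("%s-%s-b%02d", brand, substr(entry$channel, 1, 3), b)
      clean <- band_profile(recipe_bands(recipe), grid)
      set.seed(substream_seed(seed, brand, entry$channel, b, "batch"))
      f_b <- 1 + stats::rnorm(1, 0, noise$batch_amplitude_sd)
      for (t in seq_len(entry$tablets_per_batch)) {
        set.seed(substream_seed(seed, brand, entry$channel, b, t))
        m <- exp(stats::rnorm(1, 0, noise$multiplicative_scatter_sd))
        a <- stats::rnorm(1, 0, noise$additive_offset_sd)
        s <- stats::rnorm(1, 0, noise$baseline_slope_sd)
        eps <- stats::rnorm(length(grid), 0, 1) * sd_channel
        rows[[length(rows) + 1L]] <-
          m * (f_b * clean + s * (grid - grid[1])) + a + eps
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("%s-t%02d", batch_id, t),
          brand = brand, batch_id = batch_id, channel = entry$channel,
          falsified = recipe$falsified, stringsAsFactors = FALSE)
      }
    }
  }
  spectrum_set(grid, do.call(rbind, rows), do.call(rbind, meta))
}

# sum of Gaussian bands evaluated on the grid
band_profile <- function(bands, grid) {
  if (!nrow(bands)) return(numeric(length(grid)))
  colSums(bands$amplitude *
            exp(-outer(bands$center, grid, "-")^2 / (2 * bands$width^2)))
}

# deterministic 31-bit substream seed from (seed, tokens...); characters are
# folded in codepoint by codepoint so brand names key their own streams
substream_seed <- function(seed, ...) {
  tokens <- unlist(lapply(list(...), function(t) {
    if (is.character(t)) utf8ToInt(t) else as.numeric(t)
  }))
  h <- as.double(seed) %% 2147483629
  for (t in tokens) h <- (h * 69069 + t + 1) %% 2147483629
  as.integer(h)
}
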