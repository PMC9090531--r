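#' Gaussian absorption band
#'
#' NIR tablet spectra are dominated by broad overtone/combination bands;
#' the generator models each as a Gaussian in wavelength.
#'
#' @param center Band center in nm.
#' @param width Gaussian sigma in nm (> 0).
#' @param amplitude Peak absorbance (>= 0, dimensionless).
#' @return One-row data frame with columns `center`, `width`, `amplitude`.
#' @export
band <- function(center, width, amplitude) {
  if (width <= 0) stop("band width must be > 0", call. = FALSE)
  if (amplitude < 0) stop("band amplitude must be >= 0", call. = FALSE)
  data.frame(center = center, width = width, amplitude = amplitude)
}

band_table <- function(...) do.call(rbind, list(...))

#' Product recipe: the spectral fingerprint of one brand
#'
#' A recipe holds the active-ingredient (API) bands shared by all products of
#' a formulation group and the excipient bands that distinguish brands.
#' A falsified recipe carries no API bands: its `api_bands` slot holds filler
#' bands at centers disjoint from the genuine API band centers, mimicking
#' tablets that contain excipients but none of the declared actives.
#'
#' @param brand Brand name (unique within a recipe library).
#' @param api_bands Data frame of [band()] rows (API bands, or filler bands
#'   when `falsified`).
#' @param excipient_bands Data frame of [band()] rows.
#' @param falsified Logical flag.
#' @return An object of class `product_recipe`.
#' @export
product_recipe <- function(brand, api_bands, excipient_bands, falsified = FALSE) {
  stopifnot(is.character(brand), length(brand) == 1L)
  structure(list(brand = brand, api_bands = api_bands,
                 excipient_bands = excipient_bands,
                 falsified = isTRUE(falsified)),
            class = "product_recipe")
}

recipe_bands <- function(recipe) rbind(recipe$api_bands, recipe$excipient_bands)

#' Noise model for the spectrum generator
#'
#' Encodes the nuisance structure that the preprocessing chain is designed to
#' remove: per-tablet multiplicative scatter (log-normal, median 1), additive
#' offset, linear baseline drift, a per-batch relative perturbation shared by
#' all band amplitudes, and channel noise that is larger outside the
#' informative 1085-1601 nm window (spectral edges of handheld instruments
#' are noisy and less repeatable).
#'
#' @param multiplicative_scatter_sd Log-sd of the multiplicative factor.
#' @param additive_offset_sd Sd of the additive offset (absorbance).
#' @param baseline_slope_sd Sd of the baseline slope (absorbance per nm).
#' @param batch_amplitude_sd Sd of the per-batch relative amplitude factor.
#' @param channel_noise_sd_core Channel noise sd inside `edge_boundaries`.
#' @param channel_noise_sd_edges Channel noise sd outside `edge_boundaries`;
#'   must be >= the core sd.
#' @param edge_boundaries Length-2 vector (low, high) in nm.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_scatter_sd = 0.08,
                        additive_offset_sd = 0.01,
                        baseline_slope_sd = 1.5e-5,
                        batch_amplitude_sd = 0.02,
                        channel_noise_sd_core = 8e-4,
                        channel_noise_sd_edges = 4e-3,
                        edge_boundaries = c(1085, 1601)) {
  sds <- c(multiplicative_scatter_sd, additive_offset_sd, baseline_slope_sd,
           batch_amplitude_sd, channel_noise_sd_core, channel_noise_sd_edges)
  if (any(sds < 0)) stop("all noise sd parameters must be >= 0", call. = FALSE)
  if (channel_noise_sd_edges < channel_noise_sd_core) {
    stop("channel_noise_sd_edges must be >= channel_noise_sd_core", call. = FALSE)
  }
  if (length(edge_boundaries) != 2 || edge_boundaries[1] >= edge_boundaries[2]) {
    stop("edge_boundaries must be (low, high) with low < high", call. = FALSE)
  }
  structure(list(multiplicative_scatter_sd = multiplicative_scatter_sd,
                 additive_offset_sd = additive_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 batch_amplitude_sd = batch_amplitude_sd,
                 channel_noise_sd_core = channel_noise_sd_core,
                 channel_noise_sd_edges = channel_noise_sd_edges,
                 edge_boundaries = as.numeric(edge_boundaries)),
            class = "noise_model")
}

#' Zero-noise model (every nuisance sd set to 0)
#' @return A `noise_model` with all standard deviations zero.
#' @export
zero_noise_model <- function() {
  noise_model(0, 0, 0, 0, 0, 0, c(1085, 1601))
}

#' One sampling-design entry
#'
#' @param recipe [product_recipe()] generating the licit batches.
#' @param n_batches Number of batches (>= 1).
#' @param tablets_per_batch Tablets scanned per batch (>= 1).
#' @param channel Sales channel, `"licit"` or `"illicit"`.
#' @param falsified_batches How many of the entry's batches (taken from the
#'   end of the batch sequence) are generated from `falsified_recipe`.
#' @param falsified_recipe Falsified counterpart recipe (same packaging brand
#'   name, no API bands); required when `falsified_batches > 0`.
#' @return An object of class `design_entry`.
#' @export
design_entry <- function(recipe, n_batches, tablets_per_batch = 10,
                         channel = c("licit", "illicit"),
                         falsified_batches = 0, falsified_recipe = NULL) {
  channel <- match.arg(channel)
  if (n_batches < 1 || tablets_per_batch < 1) {
    stop("n_batches and tablets_per_batch must be >= 1", call. = FALSE)
  }
  if (falsified_batches > 0 && is.null(falsified_recipe)) {
    stop("falsified_batches > 0 requires a falsified_recipe", call. = FALSE)
  }
  if (falsified_batches > n_batches) {
    stop("falsified_batches cannot exceed n_batches", call. = FALSE)
  }
  structure(list(recipe = recipe, n_batches = as.integer(n_batches),
                 tablets_per_batch = as.integer(tablets_per_batch),
                 channel = channel,
                 falsified_batches = as.integer(falsified_batches),
                 falsified_recipe = falsified_recipe),
            class = "design_entry")
}

#' Default recipe library: six DP/SP antimalarial brands plus falsified analogues
#'
#' Two formulation groups share API bands: dihydroartemisinin/piperaquine
#' (DP: Duo-Cotecxin, Ridmal, Malacur) and sulfadoxine/pyrimethamine
#' (SP: Maloxine, Combimal, Laridox, Fansidar). Brands differ in their
#' excipient bands, which is what makes brand-level authentication possible
#' even when the APIs are identical. Falsified analogues replace the API
#' bands with filler bands at centers at least 100 nm away from the smallest
#' API band of their group.
#'
#' @return Named list of [product_recipe()] objects; falsified analogues are
#'   stored under `"<brand>.falsified"`.
#' @export
default_recipe_library <- function() {
  dp_api <- band_table(
    band(1140, 18, 0.32), band(1210, 20, 0.28),
    band(1448, 24, 0.38), band(1528, 20, 0.22)
  )
  sp_api <- band_table(
    band(1170, 19, 0.34), band(1316, 22, 0.30),
    band(1472, 23, 0.34), band(1560, 16, 0.18)
  )
  common_exc <- band(1392, 26, 0.20)
  exc <- function(...) rbind(common_exc, band_table(...))
  lib <- list(
    "Duo-Cotecxin" = product_recipe("Duo-Cotecxin", dp_api,
                                    exc(band(1110, 15, 0.16), band(1254, 18, 0.12))),
    "Ridmal"   = product_recipe("Ridmal", dp_api,
                                exc(band(1122, 16, 0.10), band(1290, 20, 0.15))),
    "Malacur"  = product_recipe("Malacur", dp_api,
                                exc(band(1098, 14, 0.13), band(1342, 19, 0.11))),
    "Maloxine" = product_recipe("Maloxine", sp_api,
                                exc(band(1134, 15, 0.14), band(1246, 17, 0.10))),
    "Combimal" = product_recipe("Combimal", sp_api,
                                exc(band(1104, 16, 0.09), band(1362, 21, 0.13))),
    "Laridox"  = product_recipe("Laridox", sp_api,
                                exc(band(1146, 15, 0.12), band(1274, 18, 0.14))),
    "Fansidar" = product_recipe("Fansidar", sp_api,
                                exc(band(1092, 15, 0.11), band(1330, 20, 0.16)))
  )
  # falsified analogues: filler bands only, far from the group's smallest API
  # band center (DP: 1528 nm, SP: 1560 nm) so the missing API is detectable
  lib[["Duo-Cotecxin.falsified"]] <- product_recipe(
    "Duo-Cotecxin",
    band_table(band(1250, 24, 0.25), band(1386, 28, 0.30)),
    lib[["Duo-Cotecxin"]]$excipient_bands, falsified = TRUE)
  lib[["Maloxine.falsified"]] <- product_recipe(
    "Maloxine",
    band_table(band(1230, 25, 0.28), band(1402, 26, 0.24)),
    lib[["Maloxine"]]$excipient_bands, falsified = TRUE)
  lib
}

#' Default study design: eight brand/channel entries, 23 batches, 230 spectra
#'
#' Mirrors a field-collection campaign of antimalarial tablets: Duo-Cotecxin
#' (6 licit batches, one of which turns out to be falsified), Ridmal and
#' Malacur (2 licit batches each), Maloxine (5 licit batches plus 2 batches
#' bought from illicit street vendors, both falsified), Combimal, Laridox and
#' Fansidar (2 licit batches each); ten tablets scanned per batch.
#'
#' @param recipes Recipe library, see [default_recipe_library()].
#' @return A list of [design_entry()] objects (class `sampling_design`).
#' @export
default_study_design <- function(recipes = default_recipe_library()) {
  entries <- list(
    design_entry(recipes[["Duo-Cotecxin"]], n_batches = 6,
                 falsified_batches = 1,
                 falsified_recipe = recipes[["Duo-Cotecxin.falsified"]]),
    design_entry(recipes[["Ridmal"]],   n_batches = 2),
    design_entry(recipes[["Malacur"]],  n_batches = 2),
    design_entry(recipes[["Maloxine"]], n_batches = 5),
    design_entry(recipes[["Maloxine.falsified"]], n_batches = 2,
                 channel = "illicit", falsified_batches = 2,
                 falsified_recipe = recipes[["Maloxine.falsified"]]),
    design_entry(recipes[["Combimal"]], n_batches = 2),
    design_entry(recipes[["Laridox"]],  n_batches = 2),
    design_entry(recipes[["Fansidar"]], n_batches = 2)
  )
  structure(entries, class = "sampling_design")
}

#' Totals implied by a sampling design
#' @param design A `sampling_design` (list of [design_entry()]).
#' @return List with `n_entries`, `n_batches`, `n_spectra`,
#'   `n_illicit_batches`, `n_falsified_batches`.
#' @export
design_totals <- function(design) {
  nb <- vapply(design, function(e) e$n_batches, integer(1))
  tp <- vapply(design, function(e) e$tablets_per_batch, integer(1))
  ill <- vapply(design, function(e) e$channel == "illicit", logical(1))
  fb <- vapply(design, function(e) e$falsified_batches, integer(1))
  list(n_entries = length(design), n_batches = sum(nb),
       n_spectra = sum(nb * tp), n_illicit_batches = sum(nb[ill]),
       n_falsified_batches = sum(fb))
}
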