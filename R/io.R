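#' Write a spectrum set to the spectra CSV dialect
#'
#' Header `sample_id,brand,batch_id,channel,falsified,<wl1>,<wl2>,...` with
#' wavelengths printed in nm to 2 decimals; one row per tablet; absorbance
#' written to full double precision. This dialect is the interchange format
#' between all pipeline stages.
#'
#' @param spectra A [spectrum_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  df <- cbind(spectra$metadata,
              as.data.frame(spectra$absorbance, optional = TRUE))
  names(df) <- c(names(spectra$metadata), sprintf("%.2f", spectra$wavelengths))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum set from the spectra CSV dialect
#'
#' Validates the metadata header, a monotone increasing wavelength grid and a
#' fully numeric absorbance block; errors name the offending row or column.
#'
#' @param path File in the dialect written by [write_spectra()].
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "brand", "batch_id", "channel", "falsified")
  if (!identical(names(df)[seq_along(required)], required)) {
    stop("spectra CSV must start with columns ",
         paste(required, collapse = ","), call. = FALSE)
  }
  wl_names <- names(df)[-seq_along(required)]
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) {
    stop("non-numeric wavelength column header: ",
         wl_names[which(is.na(wl))[1]], call. = FALSE)
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    stop("wavelength columns are not strictly increasing", call. = FALSE)
  }
  mat <- as.matrix(df[, wl_names, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric absorbance value at row %d, column %s",
                 bad[1], wl_names[bad[2]]), call. = FALSE)
  }
  meta <- df[, required, drop = FALSE]
  meta$falsified <- as.logical(meta$falsified)
  if (anyNA(meta$falsified)) {
    stop("falsified column must be TRUE/FALSE", call. = FALSE)
  }
  spectrum_set(wl, mat, meta)
}

model_format_tag <- "nirsimca-model"
model_format_version <- 1L

#' Save a SIMCA or DD-SIMCA model as JSON
#'
#' The JSON structure mirrors the model object (grid, center, loadings,
#' component variances, confidence limits or chi-squared scalings, MSC
#' reference and preprocessing configuration) at full double precision, with
#' a format/version tag, so a reloaded model makes identical decisions.
#'
#' @param model A `simca_model` or `ddsimca_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  type <- if (inherits(model, "simca_model")) "simca"
          else if (inherits(model, "ddsimca_model")) "ddsimca"
          else stop("model must be a simca_model or ddsimca_model", call. = FALSE)
  payload <- unclass(model)
  payload$pca <- unclass(payload$pca)
  payload$cfg <- unclass(payload$cfg)
  payload$msc_reference <- unclass(payload$msc_reference)
  obj <- list(format = model_format_tag, version = model_format_version,
              type = type, model = payload)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return The restored `simca_model` or `ddsimca_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!identical(obj$format, model_format_tag) ||
      !identical(as.integer(obj$version), model_format_version)) {
    stop("model file version tag mismatch (expected ", model_format_tag,
         " v", model_format_version, ")", call. = FALSE)
  }
  m <- obj$model
  m$pca$loadings <- as.matrix(m$pca$loadings)
  m$pca$ncomp <- as.integer(m$pca$ncomp)
  m$pca$n <- as.integer(m$pca$n)
  class(m$pca) <- "pca_model"
  class(m$cfg) <- "preprocess_config"
  m$cfg$sg_window <- as.integer(m$cfg$sg_window)
  m$cfg$sg_polyorder <- as.integer(m$cfg$sg_polyorder)
  m$cfg$sg_deriv <- as.integer(m$cfg$sg_deriv)
  class(m$msc_reference) <- "msc_reference"
  if (obj$type == "ddsimca") {
    m$n_h <- as.integer(m$n_h)
    m$n_v <- as.integer(m$n_v)
    class(m) <- "ddsimca_model"
  } else {
    class(m) <- "simca_model"
  }
  m
}

#' Serialize a sampling design and noise model to a YAML config
#'
#' Flat key paths: `noise.<parameter>`, `grid.{low,high,n_channels}` and
#' `design[i].{brand,channel,n_batches,tablets_per_batch,falsified_batches}`
#' plus the band tables of each entry's recipes.
#'
#' @param design A `sampling_design`.
#' @param noise A [noise_model()].
#' @param grid Wavelength grid.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(design, noise, grid, path) {
  bands_list <- function(b) lapply(seq_len(nrow(b)), function(i) as.list(b[i, ]))
  recipe_list <- function(r) {
    if (is.null(r)) return(NULL)
    list(brand = r$brand, falsified = r$falsified,
         api_bands = bands_list(r$api_bands),
         excipient_bands = bands_list(r$excipient_bands))
  }
  obj <- list(
    noise = unclass(noise),
    grid = list(low = min(grid), high = max(grid), n_channels = length(grid)),
    design = lapply(design, function(e) {
      list(brand = e$recipe$brand, channel = e$channel,
           n_batches = e$n_batches, tablets_per_batch = e$tablets_per_batch,
           falsified_batches = e$falsified_batches,
           recipe = recipe_list(e$recipe),
           falsified_recipe = recipe_list(e$falsified_recipe))
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a study config written by [write_study_config()]
#'
#' @param path YAML file path.
#' @return List with `design` (a `sampling_design`), `noise`
#'   ([noise_model()]) and `grid` (wavelength vector).
#' @export
read_study_config <- function(path) {
  obj <- yaml::read_yaml(path)
  bands_df <- function(l) do.call(rbind, lapply(l, function(b) {
    band(b$center, b$width, b$amplitude)
  }))
  recipe_from <- function(r) {
    if (is.null(r)) return(NULL)
    product_recipe(r$brand, bands_df(r$api_bands), bands_df(r$excipient_bands),
                   falsified = isTRUE(r$falsified))
  }
  design <- lapply(obj$design, function(e) {
    design_entry(recipe_from(e$recipe), e$n_batches, e$tablets_per_batch,
                 e$channel, e$falsified_batches, recipe_from(e$falsified_recipe))
  })
  class(design) <- "sampling_design"
  list(design = design,
       noise = do.call(noise_model, obj$noise),
       grid = seq(obj$grid$low, obj$grid$high, length.out = obj$grid$n_channels))
}
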