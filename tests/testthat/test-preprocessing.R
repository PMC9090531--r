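test_that("crop keeps exactly the channels inside the window, inclusive", {
  grid <- default_wavelength_grid()
  ss <- matrix_set(matrix(rnorm(3 * length(grid)), 3), wl = grid)
  cropped <- crop_spectra(ss, 1085, 1601)
  expect_true(all(cropped$wavelengths >= 1085 & cropped$wavelengths <= 1601))
  # independent brute-force count of grid points in the interval
  expect_equal(n_channels(cropped), sum(grid >= 1085 & grid <= 1601))
  # full-range crop is the identity
  ident <- crop_spectra(ss, min(grid), max(grid))
  expect_identical(ident$absorbance, ss$absorbance)
  expect_error(crop_spectra(ss, 1e5, 2e5), "no channels")
  expect_identical(cropped$metadata, ss$metadata)
})

test_that("Savitzky-Golay derivative is exact on polynomials and drops edges", {
  wl <- tiny_grid(50)
  const <- matrix_set(matrix(2.5, 2, 50), wl = wl)
  d2 <- savgol_derivative(const, 11, 2, 2)
  expect_equal(n_channels(d2), 40L)
  expect_equal(max(abs(d2$absorbance)), 0)
  expect_equal(d2$wavelengths, wl[6:45])
  # quadratic in nm: second derivative is the constant 2a everywhere retained
  a <- 3e-6
  quad <- matrix_set(rbind(a * wl^2, 1 + 0.5 * a * wl^2), wl = wl)
  dq <- savgol_derivative(quad, 11, 2, 2)
  expect_equal(dq$absorbance[1, ], rep(2 * a, 40), tolerance = 1e-10)
  expect_equal(dq$absorbance[2, ], rep(a, 40), tolerance = 1e-10)
  # any polynomial of degree <= polyorder is differentiated exactly
  cubic <- matrix_set(matrix(1 + 2 * wl - 3e-3 * wl^2 + 4e-6 * wl^3, 1), wl = wl)
  dc <- savgol_derivative(cubic, 11, 3, 2)
  expect_equal(dc$absorbance[1, ], -6e-3 + 24e-6 * wl[6:45], tolerance = 1e-9)
})

test_that("Savitzky-Golay derivative matches the per-window polynomial-fit oracle", {
  set.seed(101)
  wl <- tiny_grid(64)
  x <- as.numeric(cumsum(rnorm(64, sd = 0.05)))
  ss <- matrix_set(matrix(x, 1), wl = wl)
  for (deriv in 0:2) {
    got <- savgol_derivative(ss, 11, 2, deriv)$absorbance[1, ]
    expect_equal(got, sg_oracle(x, wl, 11, 2, deriv), tolerance = 1e-9)
  }
  # independent library cross-check on the interior channels
  skip_if_not_installed("signal")
  spacing <- median(diff(wl))
  lib <- signal::sgolayfilt(x, p = 2, n = 11, m = 2, ts = spacing)
  got2 <- savgol_derivative(ss, 11, 2, 2)$absorbance[1, ]
  expect_equal(got2, lib[6:59], tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(savgol_derivative(ss, 65, 2, 2), "exceeds channel count")
  expect_error(savgol_derivative(ss, 10, 2, 2), "odd")
  expect_error(savgol_derivative(ss, 11, 2, 3), "deriv")
})

test_that("MSC reference is the training mean and the fit handles degenerate input", {
  set.seed(5)
  r <- rnorm(30)
  same <- matrix_set(rbind(r, r))
  expect_equal(msc_fit(same)$reference, r, ignore_attr = TRUE)
  two <- matrix_set(rbind(r, 2 * r))
  expect_equal(msc_fit(two)$reference, 1.5 * r, ignore_attr = TRUE)
  X <- matrix(rnorm(8 * 30), 8)
  expect_equal(msc_fit(matrix_set(X))$reference, colMeans(X), ignore_attr = TRUE)
  expect_error(msc_fit(matrix_set(matrix(rnorm(30), 1))), "at least 2")
  expect_error(msc_fit(matrix_set(matrix(1, 3, 30))), "constant")
})

test_that("MSC inverts additive/multiplicative distortion and matches the OLS oracle", {
  set.seed(6)
  r <- as.numeric(scale(cumsum(rnorm(40))))
  ref <- msc_fit(matrix_set(rbind(r, r + rnorm(40, sd = 1e-9))))
  ss <- matrix_set(rbind(r, 3 + 2 * r, rnorm(40)))
  out <- msc_apply(ss, ref)
  expect_equal(out$absorbance[1, ], r, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(out$absorbance[2, ], r, tolerance = 1e-6, ignore_attr = TRUE)
  # arbitrary spectrum: (a, b) match the normal-equation oracle
  x <- ss$absorbance[3, ]
  ab <- msc_oracle(x, ref$reference)
  expect_equal(out$absorbance[3, ], (x - ab["a"]) / ab["b"], ignore_attr = TRUE)
  # near-zero slope errors and names the sample
  flat <- matrix_set(matrix(5, 1, 40), brand = "Flat")
  expect_error(msc_apply(flat, ref), "Flat-s001")
})

test_that("MSC removes simulated scatter and is idempotent at the set mean", {
  # multiplicative/additive scatter only, no channel noise
  nm <- noise_model(multiplicative_scatter_sd = 0.15, additive_offset_sd = 0.05,
                    baseline_slope_sd = 0, batch_amplitude_sd = 0,
                    channel_noise_sd_core = 0, channel_noise_sd_edges = 0)
  ss <- simulate_spectra(one_brand_design(n_batches = 1, tablets_per_batch = 20),
                         nm, tiny_grid(60), seed = 9)
  corrected <- msc_apply(ss, msc_fit(ss))
  expect_lt(max(apply(corrected$absorbance, 2, var)), 1e-10)
  # idempotence: re-correcting against a refit reference changes nothing
  again <- msc_apply(corrected, msc_fit(corrected))
  expect_lt(max(abs(again$absorbance - corrected$absorbance)), 1e-8)
})

test_that("pipeline composes crop, SG and MSC in that order with a shared reference", {
  ss <- simulate_spectra(one_brand_design(), noise_model(),
                         default_wavelength_grid(), seed = 21)
  cfg <- preprocess_config()
  trained <- preprocess(ss, cfg)
  # training then test mode on the same data gives identical output
  tested <- preprocess(ss, cfg, ref = trained$reference)
  expect_equal(trained$spectra$absorbance, tested$spectra$absorbance)
  # stagewise manual application reproduces the pipeline
  manual <- crop_spectra(ss, cfg$crop_low, cfg$crop_high)
  manual <- savgol_derivative(manual, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv)
  manual <- msc_apply(manual, msc_fit(manual))
  expect_equal(trained$spectra$absorbance, manual$absorbance)
  # pinned order: crop->SG->MSC differs from SG->MSC->crop on the same data
  alt <- savgol_derivative(ss, cfg$sg_window, cfg$sg_polyorder, cfg$sg_deriv)
  alt <- msc_apply(alt, msc_fit(alt))
  alt <- crop_spectra(alt, cfg$crop_low, cfg$crop_high)
  shared <- intersect(round(alt$wavelengths, 9),
                      round(trained$spectra$wavelengths, 9))
  a <- alt$absorbance[, round(alt$wavelengths, 9) %in% shared]
  b <- trained$spectra$absorbance[, round(trained$spectra$wavelengths, 9) %in% shared]
  expect_gt(max(abs(a - b)), 1e-8)
})

test_that("zero-noise duplicate tablets stay identical through the pipeline", {
  ss <- simulate_spectra(one_brand_design(n_batches = 1, tablets_per_batch = 6),
                         zero_noise_model(), default_wavelength_grid(), seed = 2)
  out <- preprocess(ss)$spectra$absorbance
  expect_equal(max(abs(sweep(out, 2, out[1, ]))), 0)
})
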