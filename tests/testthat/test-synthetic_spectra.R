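test_that("default study design reproduces the collection campaign arithmetic", {
  design <- default_study_design()
  tot <- design_totals(design)
  expect_equal(tot$n_entries, 8L)
  expect_equal(tot$n_batches, 23L)
  expect_equal(tot$n_spectra, 230L)
  expect_equal(tot$n_illicit_batches, 2L)
  # the illicit entry is wholly falsified, plus one falsified licit batch
  expect_equal(tot$n_falsified_batches, 3L)
  batch_counts <- vapply(design, function(e) e$n_batches, integer(1))
  expect_equal(batch_counts, c(6L, 2L, 2L, 5L, 2L, 2L, 2L, 2L))
  expect_true(all(vapply(design, function(e) e$tablets_per_batch, integer(1)) == 10L))
})

test_that("simulated library matches the design and flags falsified batches", {
  ss <- simulate_spectra(default_study_design(), noise_model(),
                         default_wavelength_grid(), seed = 42)
  expect_equal(n_samples(ss), 230L)
  md <- ss$metadata
  expect_equal(length(unique(md$batch_id)), 23L)
  # exactly one falsified licit Duo-Cotecxin batch, two falsified illicit batches
  dc_fals <- unique(md$batch_id[md$brand == "Duo-Cotecxin" & md$falsified])
  expect_length(dc_fals, 1L)
  expect_true(all(md$channel[md$batch_id == dc_fals] == "licit"))
  ill <- unique(md$batch_id[md$channel == "illicit"])
  expect_length(ill, 2L)
  expect_true(all(md$falsified[md$channel == "illicit"]))
})

test_that("simulation is deterministic and hierarchical in the seed", {
  design <- default_study_design()
  a <- simulate_spectra(design, noise_model(), default_wavelength_grid(), seed = 7)
  b <- simulate_spectra(design, noise_model(), default_wavelength_grid(), seed = 7)
  expect_identical(a$absorbance, b$absorbance)
  c <- simulate_spectra(design, noise_model(), default_wavelength_grid(), seed = 8)
  expect_false(identical(a$absorbance, c$absorbance))
  # dropping a brand leaves the other brands' draws untouched
  sub <- design[-2]
  class(sub) <- "sampling_design"
  d <- simulate_spectra(sub, noise_model(), default_wavelength_grid(), seed = 7)
  keep <- a$metadata$brand != "Ridmal"
  expect_identical(a$absorbance[keep, ], d$absorbance)
})

test_that("zero noise makes every tablet of a batch identical", {
  ss <- simulate_spectra(one_brand_design(), zero_noise_model(),
                         tiny_grid(60), seed = 1)
  for (b in unique(ss$metadata$batch_id)) {
    X <- ss$absorbance[ss$metadata$batch_id == b, ]
    expect_equal(max(abs(sweep(X, 2, X[1, ]))), 0)
  }
})

test_that("a single-band recipe difference shows up as exactly that Gaussian band", {
  grid <- tiny_grid(80)
  extra <- band(1350, 18, 0.25)
  base_bands <- rbind(band(1150, 20, 0.3), band(1500, 25, 0.35))
  d1 <- one_brand_design("A", 1, 1, bands = base_bands)
  d2 <- one_brand_design("A", 1, 1, bands = rbind(base_bands, extra))
  s1 <- simulate_spectra(d1, zero_noise_model(), grid, seed = 3)
  s2 <- simulate_spectra(d2, zero_noise_model(), grid, seed = 3)
  analytic <- extra$amplitude * exp(-(grid - extra$center)^2 / (2 * extra$width^2))
  expect_equal(as.numeric(s2$absorbance - s1$absorbance), analytic,
               tolerance = 1e-12)
  far <- abs(grid - extra$center) > 4 * extra$width
  expect_true(all(abs((s2$absorbance - s1$absorbance)[, far]) <
                    extra$amplitude * exp(-8) + 1e-12))
})

test_that("channel noise is larger outside the informative window", {
  nm <- noise_model(multiplicative_scatter_sd = 0, additive_offset_sd = 0,
                    baseline_slope_sd = 0, batch_amplitude_sd = 0,
                    channel_noise_sd_core = 0.01, channel_noise_sd_edges = 0.05)
  design <- one_brand_design(n_batches = 1, tablets_per_batch = 1200)
  ss <- simulate_spectra(design, nm, default_wavelength_grid(), seed = 11)
  v <- apply(ss$absorbance, 2, var)
  edge <- ss$wavelengths < 1085 | ss$wavelengths > 1601
  expect_gt(min(v[edge]), max(v[!edge]))
})

test_that("falsified analogues lack the API signal at the smallest API band", {
  recipes <- default_recipe_library()
  grid <- default_wavelength_grid()
  for (brand in c("Duo-Cotecxin", "Maloxine")) {
    licit <- recipes[[brand]]
    fake <- recipes[[paste0(brand, ".falsified")]]
    expect_true(fake$falsified)
    # filler centers disjoint from genuine API centers
    expect_length(intersect(fake$api_bands$center, licit$api_bands$center), 0L)
    smallest <- licit$api_bands[which.min(licit$api_bands$amplitude), ]
    d_lic <- one_brand_design(brand, 1, 1, bands = rbind(licit$api_bands,
                                                         licit$excipient_bands))
    d_fak <- one_brand_design(brand, 1, 1, bands = rbind(fake$api_bands,
                                                         fake$excipient_bands))
    s_lic <- simulate_spectra(d_lic, zero_noise_model(), grid, seed = 1)
    s_fak <- simulate_spectra(d_fak, zero_noise_model(), grid, seed = 1)
    ch <- which.min(abs(grid - smallest$center))
    expect_gte(s_lic$absorbance[1, ch] - s_fak$absorbance[1, ch],
               smallest$amplitude * 0.999)
  }
})

test_that("band centers outside the grid are an explicit error", {
  d <- one_brand_design(bands = band(2000, 20, 0.3))
  expect_error(simulate_spectra(d, zero_noise_model(), tiny_grid(60), seed = 1),
               "grid too short")
  expect_error(simulate_spectra(one_brand_design(), zero_noise_model(),
                                tiny_grid(60)),
               "seed")
})
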