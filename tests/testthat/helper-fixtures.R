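# Shared builders for small in-memory fixtures. Everything is generated in
# code; nothing is read from disk.

tiny_grid <- function(n = 40, low = 1000, high = 1600) {
  seq(low, high, length.out = n)
}

# spectrum_set wrapper around a bare matrix with minimal metadata
matrix_set <- function(X, wl = seq(1000, by = 4, length.out = ncol(X)),
                       brand = "BrandA", falsified = FALSE) {
  X <- as.matrix(X)
  spectrum_set(wl, X, data.frame(
    sample_id = sprintf("%s-s%03d", brand, seq_len(nrow(X))),
    brand = brand, batch_id = paste0(brand, "-b01"), channel = "licit",
    falsified = falsified, stringsAsFactors = FALSE))
}

# one-entry design: a single brand with Gaussian bands inside the grid
one_brand_design <- function(brand = "BrandA", n_batches = 2,
                             tablets_per_batch = 5,
                             bands = rbind(band(1200, 20, 0.3),
                                           band(1450, 25, 0.4))) {
  recipe <- product_recipe(brand, bands, band(1320, 22, 0.15))
  structure(list(design_entry(recipe, n_batches, tablets_per_batch)),
            class = "sampling_design")
}

# brute-force Savitzky-Golay oracle: per-window least-squares polynomial fit,
# analytic derivative at the window center
sg_oracle <- function(x, wl, window, polyorder, deriv) {
  half <- (window - 1) %/% 2
  centers <- seq(half + 1, length(x) - half)
  vapply(centers, function(j) {
    idx <- (j - half):(j + half)
    z <- wl[idx] - wl[j]
    fit <- stats::lm(x[idx] ~ stats::poly(z, polyorder, raw = TRUE))
    unname(stats::coef(fit)[deriv + 1]) * factorial(deriv)
  }, numeric(1))
}

# normal-equation oracle for the per-spectrum MSC regression x = a + b * ref
msc_oracle <- function(x, ref) {
  beta <- solve(crossprod(cbind(1, ref)), crossprod(cbind(1, ref), x))
  c(a = beta[1], b = beta[2])
}

# independently coded exhaustive maximin selection (Kennard-Stone oracle)
ks_oracle <- function(X, n_train) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1, 2); bestd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > bestd) { bestd <- d(i, j); best <- c(i, j) }
  }
  sel <- sort(best)
  while (length(sel) < n_train) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(i) min(vapply(sel, d, numeric(1), i = i)),
                    numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sort(sel)
}
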