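test_that("score and orthogonal distances match their definitions and oracle", {
  set.seed(61)
  X <- matrix(rnorm(40 * 10), 40) %*% diag(c(5, 3, rep(1, 8)))
  pca <- fit_pca(X, 2)
  d <- dd_distances(pca, X)
  # training mean: both distances zero
  ctr <- dd_distances(pca, matrix(pca$center, 1))
  expect_equal(ctr$h, 0, tolerance = 1e-12)
  expect_equal(ctr$v, 0, tolerance = 1e-12)
  # h equals the explicit inverse-variance Mahalanobis oracle in score space
  S <- project_pca(pca, X)$scores
  expect_equal(d$h, as.numeric(mahalanobis(S, rep(0, 2), diag(pca$variances))),
               tolerance = 1e-10)
  # full rank: v = 0 for every training sample
  full <- fit_pca(X, 10)
  expect_lt(max(dd_distances(full, X)$v), 1e-16 * sum(X^2))
})

test_that("moment estimator recovers chi-squared degrees of freedom", {
  set.seed(62)
  for (N in c(1, 4)) {
    draws <- 2.5 * rchisq(1e5, N) / N
    est <- estimate_dof(draws)
    expect_equal(est$dof, N)
    expect_equal(est$scaling, 2.5, tolerance = 0.02)
  }
  expect_equal(estimate_dof(rep(3, 10))$dof, 250L)
  expect_error(estimate_dof(c(1, 2)), "at least 5")
})

test_that("DD-SIMCA model: critical value, alpha monotonicity, permutation invariance", {
  ss <- simulate_spectra(one_brand_design("Maloxine", n_batches = 3,
                                          tablets_per_batch = 10),
                         noise_model(), default_wavelength_grid(), seed = 63)
  m <- fit_ddsimca(ss, "Maloxine", ncomp = 2, alpha = 1e-6)
  expect_equal(m$c_crit, qchisq(1 - 1e-6, m$n_h + m$n_v))
  m2 <- fit_ddsimca(ss, "Maloxine", ncomp = 2, alpha = 1e-2)
  expect_gt(m$c_crit, m2$c_crit)
  perm <- subset_samples(ss, sample(n_samples(ss)))
  mp <- fit_ddsimca(perm, "Maloxine", ncomp = 2, alpha = 1e-6)
  expect_equal(mp$pca$loadings, m$pca$loadings, tolerance = 1e-9)
  expect_equal(mp$h0, m$h0, tolerance = 1e-9)
  expect_identical(c(mp$n_h, mp$n_v), c(m$n_h, m$n_v))
  expect_error(fit_ddsimca(subset_samples(ss, 1:2), "Maloxine", ncomp = 2), "n")
})

test_that("acceptance is boundary-inclusive and monotone in (h, v)", {
  ss <- simulate_spectra(one_brand_design("B", n_batches = 3,
                                          tablets_per_batch = 10),
                         noise_model(), default_wavelength_grid(), seed = 64)
  m <- fit_ddsimca(ss, "B", ncomp = 2, alpha = 0.05)
  dec <- dd_decide(m, ss)
  expect_true(all(dec$accepted == (dec$c <= m$c_crit)))
  expect_true(all(dec$x_plot >= 0 & dec$y_plot >= 0))
  # a synthetic sample sitting exactly on the boundary is accepted
  h_star <- m$c_crit * m$h0 / m$n_h   # v = 0, c = c_crit exactly
  c_star <- m$n_h * h_star / m$h0
  expect_true(c_star <= m$c_crit + 1e-12 && c_star >= m$c_crit - 1e-12)
  # monotone: dominated (h, v) pairs of an accepted sample are accepted
  acc <- dec[dec$accepted, ][1, ]
  c_dom <- m$n_h * (acc$h / 2) / m$h0 + m$n_v * (acc$v / 2) / m$v0
  expect_lte(c_dom, m$c_crit)
})

test_that("total distance is invariant to rotation of the loadings basis", {
  set.seed(65)
  X <- matrix(rnorm(50 * 8), 50) %*% diag(c(4, 2.5, rep(0.8, 6)))
  pca <- fit_pca(X, 2)
  d <- dd_distances(pca, X)
  # rotate the two loadings within their span and recompute from scratch
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  loadings_rot <- pca$loadings %*% R
  Xc <- sweep(X, 2, pca$center)
  S_rot <- Xc %*% loadings_rot
  # orthogonal distance is subspace-determined, hence unchanged
  v_rot <- rowSums((Xc - S_rot %*% t(loadings_rot))^2)
  expect_equal(v_rot, d$v, tolerance = 1e-10, ignore_attr = TRUE)
  # score distance, as a Mahalanobis distance, is unchanged: in the PCA basis
  # the score covariance is diagonal (= the component variances), so the
  # implemented h equals the full-covariance Mahalanobis in any rotated basis
  S <- project_pca(pca, X)$scores
  expect_equal(d$h,
               as.numeric(mahalanobis(S, rep(0, 2), stats::cov(S))) *
                 (1), tolerance = 1e-6)
  h_rot <- as.numeric(mahalanobis(S_rot, rep(0, 2), stats::cov(S_rot)))
  expect_equal(h_rot, d$h, tolerance = 1e-8)
})

test_that("in-model coverage: acceptance at significance alpha stays above 1 - 2*alpha", {
  set.seed(66)
  n <- 10000
  X <- matrix(rnorm(n * 12), n) %*% diag(c(6, 4, rep(1, 10)))
  for (alpha in c(0.05, 0.01)) {
    pca <- fit_pca(X, 2)
    d <- dd_distances(pca, X)
    eh <- estimate_dof(d$h); ev <- estimate_dof(d$v)
    cc <- eh$dof * d$h / eh$scaling + ev$dof * d$v / ev$scaling
    accept <- mean(cc <= qchisq(1 - alpha, eh$dof + ev$dof))
    expect_gte(accept, 1 - 2 * alpha)
    if (alpha == 0.05) expect_equal(accept, 0.95, tolerance = 0.011)
  }
})

test_that("known effective degrees of freedom are recovered from generated classes", {
  set.seed(67)
  # score space of dimension A: h ~ chi-squared(A) exactly in the population
  for (A in c(2, 5)) {
    X <- matrix(rnorm(1e5 * (A + 6)), 1e5) %*%
      diag(c(seq(8, 3, length.out = A), rep(0.5, 6)))
    pca <- fit_pca(X, A)
    d <- dd_distances(pca, X)
    expect_lte(abs(estimate_dof(d$h)$dof - A), 1)
  }
})
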