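#' Mean-centered principal component analysis by SVD
#'
#' Columns are centered (never autoscaled: the spectra are already on a
#' common derivative/MSC scale), decomposed by singular value decomposition,
#' and the first `ncomp` right singular vectors retained as loadings. Each
#' loading column's largest-magnitude element is forced positive so results
#' are stable run to run. Component variances are
#' \eqn{\lambda_a = s_a^2/(n-1)}.
#'
#' @param X Numeric matrix (n samples x p channels), n >= 2.
#' @param ncomp Number of components to retain (>= 1, <= rank of the
#'   centered matrix).
#' @return An object of class `pca_model` with fields `center`, `loadings`
#'   (p x ncomp, orthonormal columns), `variances` (length `ncomp`),
#'   `all_variances` (all min(n-1, p) eigenvalues, used for residual
#'   statistics), `ncomp`, `n`, `total_variance`.
#' @export
fit_pca <- function(X, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("PCA requires at least 2 samples", call. = FALSE)
  if (ncomp < 1) stop("ncomp must be >= 1", call. = FALSE)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  tol <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tol)
  if (ncomp > rank) {
    stop(sprintf("ncomp (%d) exceeds the rank of the centered data (%d)",
                 ncomp, rank), call. = FALSE)
  }
  k <- min(n - 1L, p)
  all_var <- sv$d[seq_len(k)]^2 / (n - 1)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-|.| element of each loading positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  structure(list(center = center, loadings = loadings,
                 variances = all_var[seq_len(ncomp)],
                 all_variances = all_var, ncomp = as.integer(ncomp),
                 n = as.integer(n), total_variance = sum(all_var)),
            class = "pca_model")
}

#' Project samples onto a PCA model
#'
#' Returns scores, Hotelling T-squared and Q residuals. T-squared uses the
#' training score variances (never re-estimated on test data):
#' \eqn{T^2_i = \sum_a t_{ia}^2/\lambda_a}; the Q residual is the squared
#' distance to the model plane,
#' \eqn{q_i = \|(x_i - \bar x) - P t_i\|^2}.
#'
#' @param model A [fit_pca()] model.
#' @param X Matrix with the model's channel count.
#' @return List with `scores` (n x ncomp), `t2`, `q` (length-n vectors).
#' @export
project_pca <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop(sprintf("X has %d channels but the model expects %d",
                 ncol(X), length(model$center)), call. = FALSE)
  }
  Xc <- sweep(X, 2, model$center)
  scores <- Xc %*% model$loadings
  resid <- Xc - scores %*% t(model$loadings)
  q <- rowSums(resid^2)
  t2 <- rowSums(sweep(scores^2, 2, model$variances, "/"))
  list(scores = scores, t2 = as.numeric(t2), q = as.numeric(q))
}

#' Explained variance fractions
#'
#' @param model A [fit_pca()] model.
#' @param all If `TRUE`, fractions for all min(n-1, p) components; otherwise
#'   only the retained ones.
#' @return Numeric vector of fractions \eqn{\lambda_a / \sum \lambda}.
#' @export
explained_variance <- function(model, all = FALSE) {
  v <- if (all) model$all_variances else model$variances
  v / model$total_variance
}

#' Hotelling confidence ellipse for a score plot
#'
#' Ellipse semi-axes for the component pair `(i, j)` at the given confidence
#' level, from the two-component Hotelling limit
#' \eqn{T^2_{lim} = 2(n-1)/(n-2)\,F_{level}(2, n-2)}; the semi-axis along
#' component a is \eqn{\sqrt{\lambda_a T^2_{lim}}}.
#'
#' @param model A [fit_pca()] model with `n > 2` training samples.
#' @param pair Integer pair of component indices (distinct).
#' @param level Confidence level in (0, 1).
#' @return Object of class `confidence_ellipse` with `pair`, `semi_axes`,
#'   `level`.
#' @export
score_ellipse <- function(model, pair = c(1, 2), level = 0.95) {
  if (model$n <= 2) stop("confidence ellipse requires n > 2", call. = FALSE)
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop("pair must be two distinct component indices", call. = FALSE)
  }
  if (any(pair > model$ncomp)) stop("component index exceeds ncomp", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  n <- model$n
  t2_lim <- 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  structure(list(pair = as.integer(pair),
                 semi_axes = sqrt(model$variances[pair] * t2_lim),
                 level = level),
            class = "confidence_ellipse")
}
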