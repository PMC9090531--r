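#' Score and orthogonal distances for DD-SIMCA
#'
#' The score distance \eqn{h_i = \sum_a t_{ia}^2/\lambda_a} is the
#' Mahalanobis distance within the PCA subspace; the orthogonal distance
#' \eqn{v_i} is the squared residual norm after reconstruction with the
#' retained components. These are the same quantities as Hotelling
#' T-squared and the Q residual, under data-driven SIMCA's names.
#'
#' @param pca A [fit_pca()] model.
#' @param X Matrix with the model's channel count.
#' @return List with numeric vectors `h` and `v`.
#' @export
dd_distances <- function(pca, X) {
  st <- project_pca(pca, X)
  list(h = st$t2, v = st$q)
}

#' Moment estimator of a scaled chi-squared law
#'
#' Models a distance sample as \eqn{d_0 \chi^2(N)/N}: the scaling is the
#' sample mean and the degrees of freedom follow from the moment identity
#' \eqn{Var = 2 d_0^2/N}, i.e. `N = round(2 * mean^2 / var)`, clipped to
#' `[1, 250]`. A zero-variance (degenerate) sample returns the ceiling 250.
#'
#' @param distances Numeric vector (>= 5 values).
#' @return List with `scaling` (mean) and `dof` (integer).
#' @export
estimate_dof <- function(distances) {
  if (length(distances) < 5) {
    stop("dof estimation requires at least 5 distance values", call. = FALSE)
  }
  d0 <- mean(distances)
  s2 <- stats::var(distances)
  if (!is.finite(s2) || s2 <= 0 || d0 <= 0) {
    return(list(scaling = d0, dof = 250L))
  }
  dof <- round(2 * d0^2 / s2)
  list(scaling = d0, dof = as.integer(min(max(dof, 1), 250)))
}

#' Fit a data-driven SIMCA model for one target brand
#'
#' Preprocesses the single-brand training set (storing the configuration and
#' MSC reference for self-contained prediction), fits a PCA with `ncomp`
#' components, computes training score and orthogonal distances, fits each as
#' a scaled chi-squared by [estimate_dof()], and sets the critical total
#' distance \eqn{c_{crit} = \chi^2_{1-\alpha}(N_h + N_v)}.
#'
#' @param training A [spectrum_set()] of the target brand only, n > `ncomp`.
#' @param brand Target brand name.
#' @param ncomp Number of principal components.
#' @param alpha Significance level (tolerated false-rejection rate of
#'   genuine members), e.g. `1e-6`.
#' @param cfg A [preprocess_config()].
#' @return An object of class `ddsimca_model`.
#' @export
fit_ddsimca <- function(training, brand, ncomp = 2, alpha = 1e-6,
                        cfg = preprocess_config()) {
  if (!all(training$metadata$brand == brand)) {
    stop("training set contains spectra not labeled '", brand, "'", call. = FALSE)
  }
  n <- n_samples(training)
  if (n <= ncomp) {
    stop(sprintf("DD-SIMCA requires n (%d) > ncomp (%d)", n, ncomp),
         call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  prep <- preprocess(training, cfg)
  P <- prep$spectra$absorbance
  pca <- fit_pca(P, ncomp)
  dist <- dd_distances(pca, P)
  eh <- estimate_dof(dist$h)
  ev <- estimate_dof(dist$v)
  structure(list(brand = brand, pca = pca,
                 h0 = eh$scaling, n_h = eh$dof,
                 v0 = ev$scaling, n_v = ev$dof,
                 alpha = alpha,
                 c_crit = stats::qchisq(1 - alpha, eh$dof + ev$dof),
                 cfg = cfg, msc_reference = prep$reference,
                 training_h = dist$h, training_v = dist$v),
            class = "ddsimca_model")
}

#' Accept or reject spectra against a DD-SIMCA model
#'
#' Computes the total distance \eqn{c = N_h h/h_0 + N_v v/v_0} and accepts a
#' sample iff \eqn{c \le c_{crit}} (boundary inclusive). Also emits the
#' acceptance-plot coordinates \eqn{\ln(1 + h/h_0)}, \eqn{\ln(1 + v/v_0)}.
#'
#' @param model A [fit_ddsimca()] model.
#' @param spectra A raw [spectrum_set()]; the model's stored preprocessing is
#'   applied.
#' @return Object of class `dd_decision`: data frame with `sample_id`,
#'   `brand`, `falsified`, `h`, `v`, `c`, `accepted`, `x_plot`, `y_plot`.
#' @export
dd_decide <- function(model, spectra) {
  pp <- preprocess(spectra, model$cfg, ref = model$msc_reference)$spectra
  dist <- dd_distances(model$pca, pp$absorbance)
  cc <- model$n_h * dist$h / model$h0 + model$n_v * dist$v / model$v0
  out <- data.frame(sample_id = spectra$metadata$sample_id,
                    brand = spectra$metadata$brand,
                    falsified = spectra$metadata$falsified,
                    class = model$brand,
                    h = dist$h, v = dist$v, c = cc,
                    accepted = cc <= model$c_crit,
                    x_plot = log1p(dist$h / model$h0),
                    y_plot = log1p(dist$v / model$v0),
                    stringsAsFactors = FALSE)
  class(out) <- c("dd_decision", "data.frame")
  out
}
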