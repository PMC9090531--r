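#' Jackson-Mudholkar confidence limit for the Q residual
#'
#' Given the residual component variances (the eigenvalues beyond the
#' retained components), computes the classic Jackson-Mudholkar limit from
#' \eqn{\theta_k = \sum \lambda^k} (k = 1, 2, 3). Returns 0 when all
#' residual variances are zero (a degenerate, perfectly fitted class). If
#' the cube-root normal approximation degenerates (its base becomes
#' non-positive, possible for extreme eigenvalue spread) the Box scaled
#' chi-squared approximation \eqn{g\,\chi^2_{level}(h)} with
#' \eqn{g=\theta_2/\theta_1}, \eqn{h=\theta_1^2/\theta_2} is used instead.
#'
#' @param residual_variances Numeric vector of residual eigenvalues (>= 0).
#' @param level Confidence level in (0, 1).
#' @return The Q limit (scalar >= 0).
#' @export
q_confidence_limit <- function(residual_variances, level = 0.95) {
  lam <- residual_variances[residual_variances > 0]
  if (!length(lam)) return(0)
  th1 <- sum(lam); th2 <- sum(lam^2); th3 <- sum(lam^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  ca <- stats::qnorm(level)
  base <- ca * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2
  if (h0 != 0 && base > 0) {
    th1 * base^(1 / h0)
  } else {
    (th2 / th1) * stats::qchisq(level, th1^2 / th2)
  }
}

#' Hotelling T-squared confidence limit
#'
#' \eqn{T^2_{lim} = A(n-1)/(n-A)\,F_{level}(A, n-A)} for `A` components
#' estimated from `n` training samples.
#'
#' @param ncomp Number of components A (>= 1).
#' @param n Training sample count (> `ncomp`).
#' @param level Confidence level in (0, 1).
#' @return The T-squared limit (scalar).
#' @export
t2_confidence_limit <- function(ncomp, n, level = 0.95) {
  if (n <= ncomp) {
    stop(sprintf("T2 limit requires n (%d) > ncomp (%d)", n, ncomp),
         call. = FALSE)
  }
  ncomp * (n - 1) / (n - ncomp) * stats::qf(level, ncomp, n - ncomp)
}

#' Fit a classical SIMCA one-class model for one brand
#'
#' Preprocesses the training spectra in training mode (the model stores its
#' own crop/derivative configuration and MSC reference so prediction is
#' self-contained), fits a per-class PCA (component count by venetian-blinds
#' cross-validation when `ncomp = "auto"`), and computes the Q and
#' T-squared confidence limits on the training statistics.
#'
#' @param training A [spectrum_set()] containing only spectra of `brand`
#'   (n >= 3).
#' @param brand Brand name modeled.
#' @param ncomp Integer component count, or `"auto"`.
#' @param confidence Confidence level of the Q/T2 limits.
#' @param prob_threshold Membership-probability threshold for assignment.
#' @param cfg A [preprocess_config()].
#' @return An object of class `simca_model`.
#' @export
fit_simca_class <- function(training, brand, ncomp = "auto",
                            confidence = 0.95, prob_threshold = 0.8,
                            cfg = preprocess_config()) {
  if (!all(training$metadata$brand == brand)) {
    stop("training set contains spectra not labeled '", brand, "'", call. = FALSE)
  }
  n <- n_samples(training)
  if (n < 3) {
    stop(sprintf("SIMCA class model requires >= 3 training spectra (got %d)", n),
         call. = FALSE)
  }
  prep <- preprocess(training, cfg)
  P <- prep$spectra$absorbance
  if (identical(ncomp, "auto")) {
    n_splits <- min(10L, nrow(P))
    cap <- nrow(P) - ceiling(nrow(P) / n_splits) - 1L   # blind-complement limit
    # also cap at n/3: with so few training samples per class, residual
    # eigenvalues (and hence the Q limit) degenerate beyond that
    cap <- min(cap, max(1L, nrow(P) %/% 3L))
    ncomp <- venetian_blinds_select(P, max_ncomp = min(10L, cap), n_splits)
  }
  pca <- fit_pca(P, ncomp)
  resid_var <- pca$all_variances[seq_along(pca$all_variances) > ncomp]
  # guard numerically-zero eigenvalues so a perfectly fitted class yields 0
  resid_var <- resid_var[resid_var > max(pca$all_variances) * 1e-12]
  stats_train <- project_pca(pca, P)
  structure(list(brand = brand, pca = pca,
                 q_limit = q_confidence_limit(resid_var, confidence),
                 t2_limit = t2_confidence_limit(ncomp, n, confidence),
                 theta = c(sum(resid_var), sum(resid_var^2), sum(resid_var^3)),
                 confidence = confidence, prob_threshold = prob_threshold,
                 cfg = cfg, msc_reference = prep$reference,
                 training_q = stats_train$q, training_t2 = stats_train$t2),
            class = "simca_model")
}

#' Class-membership probability from Q and T-squared
#'
#' Reduced distance \eqn{d = \sqrt{(q/Q_{lim})^2 + (T^2/T^2_{lim})^2}} mapped
#' to \eqn{p = \exp(-d^2 \ln 2 / 2)}: p = 1 at the class center, p = 0.5 for
#' a sample sitting exactly on both confidence limits (d = sqrt(2)), strictly
#' decreasing in both statistics. This explicit map is this package's
#' documented membership rule (commercial SIMCA toolboxes do not publish
#' theirs). A zero Q limit (perfect-fit class) treats `q/q_limit` as 0 when
#' q is numerically zero and as infinite otherwise.
#'
#' @param model A [fit_simca_class()] model.
#' @param q,t2 Numeric vectors of Q residuals and Hotelling T-squared.
#' @return Membership probabilities in `[0, 1]`.
#' @export
simca_probability <- function(model, q, t2) {
  if (model$q_limit > 0) {
    rq <- q / model$q_limit
  } else {
    rq <- ifelse(q <= 1e-12, 0, Inf)
  }
  d2 <- rq^2 + (t2 / model$t2_limit)^2
  exp(-d2 * log(2) / 2)
}

#' Assign test spectra against a set of SIMCA class models
#'
#' Raw spectra are preprocessed per model with that model's stored
#' configuration and training MSC reference, projected, and scored with
#' [simca_probability()]. A sample is assigned to every class whose
#' probability reaches the model's threshold (class-modeling semantics:
#' none, one, or several classes are possible; falsified samples are
#' expected to be assigned to no class).
#'
#' @param models List of [fit_simca_class()] models.
#' @param spectra A raw [spectrum_set()].
#' @return Object of class `simca_prediction`: data frame `table` with one
#'   row per (sample, class) holding `q`, `t2`, `d`, `p`, `assigned`, plus
#'   `assignments`, a per-sample list of assigned classes.
#' @export
simca_assign <- function(models, spectra) {
  if (inherits(models, "simca_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    pp <- preprocess(spectra, m$cfg, ref = m$msc_reference)$spectra
    st <- project_pca(m$pca, pp$absorbance)
    p <- simca_probability(m, st$q, st$t2)
    rq <- if (m$q_limit > 0) st$q / m$q_limit else ifelse(st$q <= 1e-12, 0, Inf)
    data.frame(sample_id = spectra$metadata$sample_id,
               brand = spectra$metadata$brand,
               falsified = spectra$metadata$falsified,
               class = m$brand, q = st$q, t2 = st$t2,
               d = sqrt(rq^2 + (st$t2 / m$t2_limit)^2),
               p = p, assigned = p >= m$prob_threshold,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  assignments <- lapply(split(table$class[table$assigned],
                              factor(table$sample_id[table$assigned],
                                     levels = spectra$metadata$sample_id)),
                        identity)
  structure(list(table = table, assignments = assignments),
            class = "simca_prediction")
}
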