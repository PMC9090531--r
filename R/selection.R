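#' Kennard-Stone train/test split
#'
#' Classic deterministic maximin selection on Euclidean distances: the two
#' mutually farthest samples seed the training set, then the sample whose
#' minimum distance to the selected set is largest is added, until
#' `ceiling(train_fraction * n)` samples are selected. Ties are broken by
#' lowest index, so the split is fully deterministic.
#'
#' @param X Numeric matrix (rows = samples), typically preprocessed spectra.
#' @param train_fraction Fraction in (0, 1) selected for training.
#' @param ids Sample identifiers (defaults to row indices).
#' @return List of class `split_result` with `train`, `test` (ids) and
#'   `method = "kennard_stone"`.
#' @export
kennard_stone <- function(X, train_fraction, ids = seq_len(nrow(X))) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) stop("Kennard-Stone requires at least 2 samples", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- ceiling(train_fraction * n)
  D <- as.matrix(stats::dist(X))
  # farthest pair, lowest indices on ties
  flat <- which(D == max(D), arr.ind = TRUE)
  flat <- flat[order(pmin(flat[, 1], flat[, 2]), pmax(flat[, 1], flat[, 2])), ,
               drop = FALSE]
  sel <- sort(unname(flat[1, ]))
  if (n_train < 2) sel <- sel[1]
  while (length(sel) < n_train) {
    mind <- apply(D[, sel, drop = FALSE], 1, min)
    mind[sel] <- -Inf
    sel <- c(sel, which.max(mind))     # which.max takes the lowest index on ties
  }
  sel <- sort(sel)
  structure(list(train = ids[sel], test = ids[-sel], method = "kennard_stone"),
            class = "split_result")
}

#' Batch-wise train/test split for one brand
#'
#' Sorted licit batch ids go to training first (`n_train_batches` of them);
#' all remaining batches form the test set. Batches flagged falsified are
#' never placed in training — falsified samples enter the test set only.
#'
#' @param spectra A [spectrum_set()].
#' @param brand Brand to split.
#' @param n_train_batches Number of training batches.
#' @return `split_result` with `train`, `test` sample ids and
#'   `method = "by_batch"`.
#' @export
split_by_batches <- function(spectra, brand, n_train_batches) {
  md <- spectra$metadata[spectra$metadata$brand == brand, , drop = FALSE]
  if (!nrow(md)) stop("no spectra for brand '", brand, "'", call. = FALSE)
  batches <- sort(unique(md$batch_id))
  if (length(batches) <= n_train_batches) {
    stop(sprintf("brand '%s' has %d batches; need more than n_train_batches (%d)",
                 brand, length(batches), n_train_batches), call. = FALSE)
  }
  fals_batches <- unique(md$batch_id[md$falsified])
  licit_batches <- setdiff(batches, fals_batches)
  if (length(licit_batches) < n_train_batches) {
    stop(sprintf("brand '%s' has only %d non-falsified batches (< %d requested)",
                 brand, length(licit_batches), n_train_batches), call. = FALSE)
  }
  train_b <- licit_batches[seq_len(n_train_batches)]
  structure(list(train = md$sample_id[md$batch_id %in% train_b],
                 test = md$sample_id[!(md$batch_id %in% train_b)],
                 method = "by_batch"),
            class = "split_result")
}

#' Venetian-blinds cross-validation for PCA component count
#'
#' For each candidate component count A, every k-th sample (k = 1..n_splits)
#' is held out, a PCA is fit on the rest, and the held-out residual sum of
#' squares after projection onto the A loadings is accumulated (PRESS).
#' Because projecting isotropic noise onto any A directions removes energy
#' proportionally to A, raw PRESS decreases mechanically with A; candidates
#' are therefore compared on PRESS per residual degree of freedom,
#' `PRESS(A) / (n * (p - A))`, which is flat for structureless noise and
#' floors at the true rank for low-rank data. The selected A is the smallest
#' whose adjusted PRESS is within 5% of the minimum (parsimony rule).
#'
#' Callers should order rows by batch then acquisition index before striping
#' so each blind spans batches (spectra from [simulate_spectra()] already
#' are).
#'
#' @param X Numeric matrix (n x p).
#' @param max_ncomp Largest candidate A; capped (with a warning) when it
#'   reaches the smallest blind-complement size.
#' @param n_splits Number of blinds (default 10, reduced to n when n < 10).
#' @return Selected component count (integer) with the adjusted PRESS curve
#'   attached as attribute `"press"`.
#' @export
venetian_blinds_select <- function(X, max_ncomp, n_splits = 10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  n_splits <- min(n_splits, n)
  if (n_splits < 2) stop("venetian blinds require n >= 2 splits", call. = FALSE)
  folds <- lapply(seq_len(n_splits), function(k) seq.int(k, n, by = n_splits))
  min_train <- n - max(lengths(folds))
  cap <- min(min_train - 1L, p)
  if (max_ncomp > cap) {
    warning(sprintf("max_ncomp capped at %d (blind-complement size limit)", cap))
    max_ncomp <- cap
  }
  if (max_ncomp < 1) stop("no admissible component count", call. = FALSE)
  press <- numeric(max_ncomp)
  for (hold in folds) {
    Xtr <- X[-hold, , drop = FALSE]
    center <- colMeans(Xtr)
    sv <- svd(sweep(Xtr, 2, center), nu = 0, nv = max_ncomp)
    Hc <- sweep(X[hold, , drop = FALSE], 2, center)
    total <- sum(Hc^2)
    proj <- Hc %*% sv$v                      # scores on up to max_ncomp loadings
    press <- press + (total - cumsum(colSums(proj^2)))
  }
  adj <- press / (n * (p - seq_len(max_ncomp)))
  sel <- which(adj <= 1.05 * min(adj))[1]
  structure(as.integer(sel), press = adj)
}

#' Sensitivity/specificity report for one-class predictions
#'
#' Builds a per-class classification report from a long prediction table.
#' For each class, target test samples are the non-falsified spectra whose
#' true brand equals the class; every other sample (other brands, and all
#' falsified spectra) is a foreign challenge. Sensitivity is the percentage
#' of targets accepted, specificity the percentage of foreign samples
#' rejected; an empty group yields `NA` (never a division by zero). A pooled
#' row aggregates counts over all classes.
#'
#' @param predictions Data frame with columns `class`, `sample_id`, `brand`,
#'   `falsified` and a logical acceptance column (`accepted` or `assigned`),
#'   e.g. `simca_assign(...)$table` or the output of [dd_decide()].
#' @return Data frame of class `classification_report` with columns `class`,
#'   `n_target`, `n_foreign`, `true_accept`, `true_reject`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_report <- function(predictions) {
  predictions <- as.data.frame(predictions)
  acc_col <- intersect(c("accepted", "assigned"), names(predictions))[1]
  if (is.na(acc_col)) {
    stop("predictions need an 'accepted' or 'assigned' logical column",
         call. = FALSE)
  }
  per_class <- lapply(split(predictions, predictions$class), function(df) {
    target <- !df$falsified & df$brand == df$class[1]
    acc <- df[[acc_col]]
    data.frame(class = df$class[1],
               n_target = sum(target), n_foreign = sum(!target),
               true_accept = sum(acc[target]), true_reject = sum(!acc[!target]),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, per_class)
  rep <- rep[order(rep$class), , drop = FALSE]
  pooled <- data.frame(class = "(pooled)",
                       n_target = sum(rep$n_target),
                       n_foreign = sum(rep$n_foreign),
                       true_accept = sum(rep$true_accept),
                       true_reject = sum(rep$true_reject))
  rep <- rbind(rep, pooled)
  rep$sensitivity <- ifelse(rep$n_target > 0,
                            100 * rep$true_accept / rep$n_target, NA_real_)
  rep$specificity <- ifelse(rep$n_foreign > 0,
                            100 * rep$true_reject / rep$n_foreign, NA_real_)
  rownames(rep) <- NULL
  class(rep) <- c("classification_report", "data.frame")
  rep
}
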