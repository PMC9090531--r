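#' Replicate the brand-authentication study on synthetic spectra
#'
#' End-to-end driver: simulate the default multi-brand tablet library,
#' split each modeled brand into training and test sets (3 training / 2 test
#' batches for brands with at least 5 licit batches, otherwise a
#' Kennard-Stone 60/40 split; falsified batches go to the test set only),
#' fit one classical SIMCA model per modeled brand and DD-SIMCA models for
#' the two brands with falsified analogues, score the pooled test set with
#' both, and report per-class sensitivity and specificity.
#'
#' Six brands are modeled; the seventh (Fansidar) contributes test spectra
#' as a foreign challenge only.
#'
#' @param seed Integer seed for the spectrum generator.
#' @param design,noise,grid Study conditions (defaults:
#'   [default_study_design()], [noise_model()], [default_wavelength_grid()]).
#' @param cfg Preprocessing configuration.
#' @param model_brands Brands to model with classical SIMCA.
#' @param dd_brands Brands to model with DD-SIMCA.
#' @param dd_ncomp,dd_alpha DD-SIMCA component count and significance level.
#' @param confidence,prob_threshold Classical SIMCA limit level and
#'   membership threshold.
#' @param train_batches Training batches for brands split batch-wise.
#' @param train_fraction Kennard-Stone training fraction for 2-batch brands.
#' @return List of class `study_replication` with elements `spectra`,
#'   `splits`, `test_ids`, `simca` (models, predictions, report) and
#'   `ddsimca` (models, decisions, report).
#' @export
replicate_study <- function(seed = 42,
                            design = default_study_design(),
                            noise = noise_model(),
                            grid = default_wavelength_grid(),
                            cfg = preprocess_config(),
                            model_brands = c("Combimal", "Duo-Cotecxin",
                                             "Laridox", "Malacur", "Maloxine",
                                             "Ridmal"),
                            dd_brands = c("Duo-Cotecxin", "Maloxine"),
                            dd_ncomp = 2, dd_alpha = 1e-6,
                            confidence = 0.95, prob_threshold = 0.8,
                            train_batches = 3, train_fraction = 0.6) {
  ss <- simulate_spectra(design, noise, grid, seed = seed)
  md <- ss$metadata

  splits <- lapply(model_brands, function(brand) {
    licit <- md$brand == brand & !md$falsified
    n_licit_batches <- length(unique(md$batch_id[licit]))
    if (n_licit_batches >= train_batches + 2) {
      split_by_batches(ss, brand, train_batches)
    } else {
      # 2-batch brands: Kennard-Stone on spectra preprocessed with a
      # reference fitted on all of this brand's licit spectra
      brand_ss <- subset_samples(ss, which(licit))
      P <- preprocess(brand_ss, cfg)$spectra
      ks <- kennard_stone(P$absorbance, train_fraction,
                          ids = brand_ss$metadata$sample_id)
      fals_ids <- md$sample_id[md$brand == brand & md$falsified]
      ks$test <- c(ks$test, fals_ids)
      ks
    }
  })
  names(splits) <- model_brands

  # pooled test set: every modeled brand's test spectra plus the spectra of
  # unmodeled brands (foreign challenges)
  test_ids <- unique(c(unlist(lapply(splits, `[[`, "test")),
                       md$sample_id[!(md$brand %in% model_brands)]))
  test_ids <- md$sample_id[md$sample_id %in% test_ids]   # keep acquisition order
  test_ss <- subset_samples(ss, test_ids)

  simca_models <- lapply(model_brands, function(brand) {
    fit_simca_class(subset_samples(ss, splits[[brand]]$train), brand,
                    ncomp = "auto", confidence = confidence,
                    prob_threshold = prob_threshold, cfg = cfg)
  })
  names(simca_models) <- model_brands
  simca_pred <- simca_assign(simca_models, test_ss)
  simca_report <- evaluate_report(simca_pred$table)

  dd_models <- lapply(dd_brands, function(brand) {
    fit_ddsimca(subset_samples(ss, splits[[brand]]$train), brand,
                ncomp = dd_ncomp, alpha = dd_alpha, cfg = cfg)
  })
  names(dd_models) <- dd_brands
  dd_decisions <- do.call(rbind, lapply(dd_models, dd_decide, spectra = test_ss))
  rownames(dd_decisions) <- NULL
  dd_report <- evaluate_report(dd_decisions)

  structure(list(seed = seed, spectra = ss, splits = splits,
                 test_ids = test_ids,
                 simca = list(models = simca_models,
                              predictions = simca_pred$table,
                              report = simca_report),
                 ddsimca = list(models = dd_models,
                                decisions = dd_decisions,
                                report = dd_report)),
            class = "study_replication")
}

#' @export
print.study_replication <- function(x, ...) {
  cat(sprintf("<study_replication> seed %d, %d spectra, %d test spectra\n",
              x$seed, n_samples(x$spectra), length(x$test_ids)))
  cat("\nClassical SIMCA report:\n")
  print(as.data.frame(x$simca$report), digits = 4)
  cat("\nDD-SIMCA report:\n")
  print(as.data.frame(x$ddsimca$report), digits = 4)
  invisible(x)
}

#' Headline figures of a study replication
#'
#' @param run A [replicate_study()] result.
#' @return List with `simca_pooled_specificity` (percentage of foreign or
#'   falsified test spectra rejected, pooled over the classical SIMCA
#'   models), `simca_n_foreign`, `dd_worst` (the smaller of sensitivity and
#'   specificity across the DD-SIMCA models) and `dd_n_test`.
#' @export
study_headline <- function(run) {
  srep <- run$simca$report
  pooled <- srep[srep$class == "(pooled)", ]
  drep <- run$ddsimca$report
  dclasses <- drep[drep$class != "(pooled)", ]
  list(simca_pooled_specificity = pooled$specificity,
       simca_n_foreign = pooled$n_foreign,
       dd_worst = min(c(dclasses$sensitivity, dclasses$specificity)),
       dd_n_test = sum(dclasses$n_target + dclasses$n_foreign))
}
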