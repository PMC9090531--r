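#!/usr/bin/env Rscript
# Preprocess the library (crop to 1085-1601 nm, Savitzky-Golay second
# derivative, MSC) and explore it with PCA: the falsified batches should
# separate from the licit clusters in the PC1-PC2 score plot, which is how
# suspicious samples are flagged before any class modeling. Writes the score
# table with the 95% confidence ellipse.

library(nirsimca)

ss <- read_spectra("results/spectra.csv")
prep <- preprocess(ss, preprocess_config())
cat(sprintf("preprocessed: %d channels retained of %d\n",
            n_channels(prep$spectra), n_channels(ss)))

pca <- fit_pca(prep$spectra$absorbance, 3)
st <- project_pca(pca, prep$spectra$absorbance)
ev <- explained_variance(pca)
cat(sprintf("PC1+PC2 explain %.1f%% of preprocessed variance\n",
            100 * sum(ev[1:2])))

ell <- score_ellipse(pca, c(1, 2), 0.95)
scores <- data.frame(prep$spectra$metadata,
                     pc1 = st$scores[, 1], pc2 = st$scores[, 2],
                     pc3 = st$scores[, 3], t2 = st$t2, q = st$q,
                     outside_95_ellipse = (st$scores[, 1] / ell$semi_axes[1])^2 +
                       (st$scores[, 2] / ell$semi_axes[2])^2 > 1)
write.csv(scores, "results/pca_scores.csv", row.names = FALSE)

flagged <- table(falsified = scores$falsified, outside = scores$outside_95_ellipse)
print(flagged)
cat(sprintf("%d of %d falsified spectra fall outside the 95%% ellipse\n",
            sum(scores$falsified & scores$outside_95_ellipse),
            sum(scores$falsified)))
cat("wrote results/pca_scores.csv\n")
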