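#!/usr/bin/env Rscript
# Generate the synthetic multi-brand tablet library that stands in for the
# field-collected spectra: 8 brand/channel entries, 23 batches, 10 tablets
# per batch = 230 handheld-NIR absorbance spectra on 900-1700 nm, including
# two falsified illicit-channel Maloxine batches and one falsified licit
# Duo-Cotecxin batch. Writes the spectra CSV and the study config.

library(nirsimca)

seed <- 42
dir.create("results", showWarnings = FALSE)

design <- default_study_design()
noise <- noise_model()
grid <- default_wavelength_grid()

tot <- design_totals(design)
cat(sprintf("design: %d entries, %d batches, %d spectra (%d illicit batches)\n",
            tot$n_entries, tot$n_batches, tot$n_spectra, tot$n_illicit_batches))

ss <- simulate_spectra(design, noise, grid, seed = seed)
print(ss)

write_spectra(ss, "results/spectra.csv")
write_study_config(design, noise, grid, "results/study_config.yaml")
cat("wrote results/spectra.csv and results/study_config.yaml (seed", seed, ")\n")
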