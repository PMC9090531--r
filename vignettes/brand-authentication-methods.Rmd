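---
title: "One-class brand authentication from handheld NIR spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-class brand authentication from handheld NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsimca)
```

## The screening problem

Falsified medicines — tablets that contain none of their declared active
pharmaceutical ingredients (APIs) — are a serious public-health problem,
especially where laboratory drug-quality control is scarce. Handheld
near-infrared (NIR) spectrometers covering 900–1700 nm offer a fast,
non-destructive first-line screen: NIR absorbance in this window arises from
broad O–H/C–H/N–H overtone and combination bands, so a tablet's spectrum is a
fingerprint of both its API and its excipient matrix. Because the question is
*"is this tablet what its packaging claims?"*, the right statistical tool is
one-class (class-modeling) classification: each genuine brand gets its own
model, and a test tablet is accepted or rejected by that brand's model alone.
`nirsimca` implements the full chain — synthetic spectrum generation,
preprocessing, PCA exploration, classical SIMCA and data-driven SIMCA
(DD-SIMCA) — as testable package code driven by the scripts in `analysis/`.

## What the synthetic generator emulates

No spectra are shipped with the package; the generator stands in for a
field-collection campaign and defines the study conditions everything else is
tested under. The default design (`default_study_design()`) has eight
brand/channel entries over two fixed-dose antimalarial formulation groups —
dihydroartemisinin/piperaquine (DP) and sulfadoxine/pyrimethamine (SP) — with
batch counts (6, 2, 2, 5, 2, 2, 2, 2), ten tablets per batch, hence 23
batches and 230 spectra. Two illicit-channel Maloxine batches and one licit
Duo-Cotecxin batch are falsified: their recipes carry the brand's excipient
bands plus filler bands but no API bands, mimicking confirmed no-API
falsifications that still contain a tablet matrix.

Each tablet spectrum is a sum of Gaussian bands distorted by exactly the
nuisances the preprocessing chain is designed to remove:

* a log-normal multiplicative scatter factor (median 1, log-sd 0.08) and a
  normal additive offset (sd 0.01 AU) — particle-size/path-length scatter;
* a linear baseline drift (slope sd 1.5e-5 AU/nm);
* one relative band-amplitude factor shared by all tablets of a batch
  (sd 2%) — batch-to-batch formulation variation;
* channel noise with sd 8e-4 AU inside 1085–1601 nm and 4e-3 AU outside —
  handheld-instrument edges are noisy and less repeatable.

These values are the package's fixed defaults, chosen once as typical of
low-cost handheld instruments scanning intact tablets. Randomness is
hierarchical: every (brand, channel, batch, tablet) tuple hashes to its own
substream of the single integer seed, so libraries are bit-reproducible and
adding a brand never perturbs another brand's draws.

What the generator does *not* emulate matters for interpreting results:
within a batch, tablets differ only by scatter, baseline and channel noise —
there is no tablet-to-tablet compositional variability, no instrument drift
between sessions, no temperature or moisture effects, and bands are exactly
Gaussian. Passing tests therefore demonstrate that the algorithms behave as
specified under their own assumptions, not that a particular instrument will
reach the same figures on real tablets.

## Preprocessing

`preprocess()` applies, in a pinned order:

1. **Crop** to 1085–1601 nm (inclusive). Cropping comes first so the noisy
   edges never enter a derivative window or the scatter-correction reference.
2. **Savitzky-Golay second derivative**: a moving 11-channel window,
   second-degree polynomial least-squares fit, analytic second derivative at
   the window center, scaled by the channel spacing so the result is a
   derivative with respect to nm and grid-independent. The half-window
   channels at each end are dropped rather than padded — padding invents
   data, and the range is already cropped. The window width is not dictated
   by the instrument; 11 channels (≈ 39 nm on the default grid) is typical
   for handheld NIR and is configurable. The derivative removes the additive
   offset and the linear baseline exactly.
3. **Multiplicative scatter correction (MSC)**: each spectrum is regressed on
   a reference by OLS, `x = a + b·ref`, and replaced by `(x − a)/b`. The
   reference is always the *training-set* mean; test spectra are corrected
   against the training reference, so no test information leaks into the
   model space. MSC removes the multiplicative factor — including the
   batch amplitude factor, which scales all bands equally — exactly in the
   noise-free case (a tested invariant).

A numerical guard: an MSC slope below 1e-10 in magnitude aborts with the
offending sample named, rather than silently amplifying noise.

## PCA, T², Q

`fit_pca()` is mean-centered SVD PCA without autoscaling (the spectra are
already on a common derivative scale). Component variances are
\(\lambda_a = s_a^2/(n-1)\); loadings signs are fixed by forcing each
column's largest-magnitude element positive, making results platform-stable.
`project_pca()` returns scores, the Hotelling statistic
\(T^2_i = \sum_a t_{ia}^2/\lambda_a\) (training variances, never re-estimated
on test data) and the residual \(q_i = \|x_i - \hat x_i\|^2\). Score-plot
screening uses the two-component Hotelling ellipse at 95%,
\(T^2_{lim} = 2(n-1)/(n-2) F_{0.95}(2, n-2)\).

## Classical SIMCA

One PCA per brand. Confidence limits at 95%: the Q limit by
Jackson–Mudholkar from \(\theta_k = \sum \lambda^k\) over the residual
eigenvalues (falling back to the Box scaled-\(\chi^2\) approximation if the
cube-root base degenerates), the T² limit by
\(A(n-1)/(n-A)\,F(A, n-A)\). Commercial toolboxes convert these statistics
into a class-membership probability but do not publish the formula; this
package's documented rule is the reduced distance
\(d = \sqrt{(q/Q_{lim})^2 + (T^2/T^2_{lim})^2}\) mapped through
\(p = e^{-d^2 \ln 2 / 2}\), which is 1 at the class center, exactly 0.5 for a
sample sitting on both limits simultaneously (\(d = \sqrt 2\)), and strictly
decreasing in both statistics. A sample is assigned to every class with
\(p \ge 0.8\) — class-modeling semantics, so none or several assignments are
possible and falsified tablets are expected to match no class.

The component count per class is selected by venetian-blinds
cross-validation (10 blinds; samples ordered by batch before striping so
each blind spans batches). Held-out residual energy after projection onto the
training loadings decreases mechanically with the component count A — for
structureless noise it is proportional to \(p - A\) — so candidates are
compared on PRESS per residual degree of freedom,
\(PRESS(A)/(n(p-A))\), which is flat under isotropic noise and floors at the
true rank for noiseless low-rank data; the smallest A within 5% of the
minimum wins. Automatic selection is additionally capped at \(n/3\)
components: with a dozen training spectra per class, larger models leave too
few residual eigenvalues to estimate a meaningful Q limit.

On the synthetic library the six brand models reject *every* foreign and
falsified test spectrum (pooled specificity 100%), because brands differ by
excipient bands that are enormous relative to within-class noise after
preprocessing. Sensitivity is a different story: within a synthetic class the
only variability is filter-correlated channel noise, so with 12–30 training
spectra against 136 channels the training residual eigenvalues underestimate
the residual energy of *new* samples, genuine test tablets land near or
beyond the 95% Q limit, and the 0.8 threshold turns them away — the
batch-split brands show 10–45% sensitivity. This is honest small-sample
SIMCA behavior under this generator's conditions, and it is why acceptance
is judged on specificity for the classical models.

## DD-SIMCA

Data-driven SIMCA replaces fixed-form limits with distributions fitted to the
training distances: the score distance \(h_i\) (identical to \(T^2_i\)) and
the orthogonal distance \(v_i\) (identical to \(q_i\)) are each modeled as
scaled chi-squared, \(d_0 \chi^2(N)/N\), with the scaling \(d_0\) the sample
mean and the degrees of freedom by the classical method of moments
\(N = \text{round}(2 d_0^2 / s^2)\), clipped to [1, 250] (the ceiling guards
quantile evaluation for near-degenerate classes; a zero-variance sample gets
the ceiling). The total distance
\(c = N_h h/h_0 + N_v v/v_0\) is accepted iff \(c \le \chi^2_{1-\alpha}(N_h + N_v)\),
boundary inclusive. The acceptance plot uses \(\ln(1+h/h_0)\) vs
\(\ln(1+v/v_0)\). The moment estimator (rather than robust quantile
variants) is the canonical default; training-set outlier pruning is
deliberately not implemented.

The study replication fits DD-SIMCA for the two brands with falsified
analogues and enough batches (Duo-Cotecxin, Maloxine), two PCs each, at
\(\alpha = 10^{-6}\) for both models. \(\alpha\) is the tolerated
false-rejection rate of genuine tablets; a screening tool wants it tiny, and
\(10^{-6}\)/\(10^{-7}\) are the values used in this kind of application. No
rule for choosing \(\alpha\) is implemented — it is an argument. With the
generous \(\alpha\) boundary both models reach 100% sensitivity *and* 100%
specificity on the synthetic test pool: foreign and falsified tablets differ
in band structure, which inflates \(v\) by orders of magnitude.

## Splitting and evaluation

Brands with at least five licit batches are split batch-wise — first three
sorted licit batches train, the rest test — so train and test never share a
batch; falsified batches can never enter training. Two-batch brands are split
60/40 by the deterministic Kennard-Stone maximin algorithm (seeded with the
farthest pair, ties broken by lowest index). Kennard-Stone runs on
preprocessed spectra; since the split precedes model training, the
split-stage MSC reference is fitted on all of the brand's licit spectra, and
each class model then refits its own reference on its training subset only.
Sensitivity is the percentage of genuine target-brand test tablets accepted;
specificity the percentage of non-members (other brands and falsified
analogues) rejected; empty groups report `NA`, never a division by zero.

Six brands are modeled; Fansidar's spectra serve only as foreign challenges
in the test pool, mirroring the modeled-brand table of the motivating
application.

## Numerical choices and degenerate inputs

* Grid: 228 channels over 900–1700 nm; uniform spacing is validated with a
  2% tolerance so a grid whose wavelengths were printed to 2 decimals still
  passes.
* A perfectly fitted class (zero residual variance) gets \(Q_{lim} = 0\); its
  probability rule treats \(q/Q_{lim}\) as 0 for numerically zero \(q\) and
  as infinite otherwise.
* Jackson–Mudholkar at a *single* residual eigenvalue is the Wilson–Hilferty
  approximation of \(\chi^2(1)\), which is about 2.5% low at the 95% level —
  an approximation property, tested as such.
* All tie-breaks (Kennard-Stone, loading signs, blind assignment) are
  deterministic; two runs with the same seed are byte-identical, which is
  itself a test.

## Problem sizes used in the tests

The test-suite calibration experiments use 10^4 samples for limit coverage
(false-rejection rates 5% ± 1 percentage point at the 95% level, DD-SIMCA
acceptance ≥ 1 − 2α) and 10^5 draws for exact moment recovery of
\(N \in \{1..10\}\); the end-to-end replication uses the full 230-spectrum
design. These sizes make the stochastic assertions stable at the stated
tolerances while keeping the whole suite around ten seconds.

## Known limitations

* The membership-probability map is a documented stand-in; numbers produced
  with commercial SIMCA software will differ in the borderline region even
  on identical statistics.
* Real-data quantities reported for field-collected spectra (per-class PC
  counts, pooled-PCA explained variance) depend on the actual tablets and
  instrument and are not reproduced by the synthetic conditions.
* The generator's within-class variability is deliberately minimal; see the
  classical-SIMCA sensitivity discussion above before extrapolating any
  sensitivity figure to real screening.
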