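---
title: "Auditing frozen image-model embeddings for subgroup bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing frozen image-model embeddings for subgroup bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedaudit)
```

## The problem

A frozen feature extractor assigns every scan an embedding vector; task
heads trained on these embeddings cannot change how the features are
computed. If the embedding geometry separates patients by biologic sex or
racial identity in the same directions that separate disease from
non-disease, downstream classifiers will perform unevenly across those
subgroups, and no amount of head training can fix it. `embedaudit`
quantifies both halves of this failure mode: *are* protected
characteristics encoded in the features, and *do* they translate into
performance disparities?

## The shift audit

Given an embedding matrix and per-scan metadata, the inspection pipeline
is:

1. **Balanced subsample.** Equal numbers of patients per racial group
   (default 1000), one scan per drawn patient, chosen uniformly. Balancing
   at the patient level removes both group-size confounding and
   within-patient clustering from the tests. Groups smaller than the quota
   are drawn with replacement and flagged.
2. **PCA.** The subsample's embeddings are centered (never scaled — the
   feature scale is part of what the backbone learned) and decomposed by
   SVD. Component signs are fixed by making the largest-magnitude loading
   positive, so results are reproducible; sign is otherwise arbitrary.
   The leading modes capture the largest variation, which for a
   disease-trained backbone is expected to include disease separation; the
   audit asks whether those same modes also separate sex or race.
3. **KS tests.** For each subgroup pair and each of the first `n_modes`
   modes (default 4), a two-sample Kolmogorov–Smirnov statistic
   $D = \sup_x |\hat F_a(x) - \hat F_b(x)|$ is evaluated over the pooled
   sample points with the right-continuous ECDF convention. Projections of
   continuous embeddings are continuous, so ties have measure zero, but the
   convention is fixed for testability. P-values use the asymptotic
   Kolmogorov distribution at effective size $n_a n_b/(n_a+n_b)$; at the
   subsample sizes involved (hundreds to thousands per side) the
   asymptotic form is accurate and fast, and exact enumeration would buy
   nothing.
4. **Multiplicity.** All comparisons × all modes form a *single*
   Benjamini–Yekutieli family:
   $\tilde p_{(i)} = \min(1, \min_{j\ge i} p_{(j)}\, m\, c(m)/j)$,
   $c(m)=\sum_{k=1}^m 1/k$. BY is valid under arbitrary dependence — the
   mode projections of one comparison are anything but independent.
   Whether one should pool disease, sex and race tests into one family or
   adjust per characteristic is a genuine judgment call; the pooled family
   is the more conservative choice and is recorded in the report's
   `adjustment` field. Significance is declared at adjusted $p < \alpha$
   (default 0.05).

Disease contrasts (e.g. "no finding" vs "pleural effusion") compare scans
positive for *exactly one* of the two labels; co-positive scans belong to
neither side. This is a declared convention — plotting "presence of
disease" does not by itself say how overlap is handled.

t-SNE (via Rtsne, Barnes–Hut, perplexity 30, seeded) is provided as a
qualitative view only, run on the PCA coordinates retaining 99% of the
variance. **No statistics are computed on t-SNE coordinates**: its
distances are not calibrated, so the KS machinery applies to PCA modes
only. Marginal-density panels normalize each subgroup's kernel density
independently to integrate to 1 on a common grid, removing base-rate
differences from the picture.

## The performance audit

1. **Heads.** Three capacities on frozen features: `linear` (single fully
   connected layer), `mlp3`, `mlp5` (3/5 hidden layers, rectifier units,
   width 256 by default). Multilabel sigmoid outputs with independent
   per-label binary cross-entropy — condition labels co-occur, so
   softmax would be wrong. Training is full-batch Adam (default step size
   0.05 — appropriate for full-batch gradients, and about five times
   faster to converge than the minibatch-habit 0.01); the returned
   parameters are those with the best mean validation AUC, evaluated every
   5 epochs. Labels constant in the training split are excluded from the
   selection metric with a warning. None of these hyperparameters is
   prescribed by the methodology being implemented; all are exposed with
   the defaults stated here. The frozen-backbone contract is absolute: no
   operation modifies the embedding inputs (the head standardizes
   internally by training-set mean/SD, which is a property of the head,
   not the features).
2. **Balanced test set.** Rows are drawn with replacement, `n_per_cell`
   from every (group × label-status × age-bin) stratum. Age bins default
   to decades (18, 30, …, 90, 100); "correcting for differences in age"
   admits many recipes, and exact stratified equalization is the simplest
   one that makes the balance literal rather than asymptotic. The default
   `n_per_cell` makes the balanced set roughly the size of the input
   cohort, keeping bootstrap CI widths comparable to an unresampled
   analysis. Empty strata are a hard, named error — silently dropping a
   stratum would silently unbalance the design.
3. **Operating point.** τ is the smallest threshold whose pooled FPR does
   not exceed the target (0.20). An exact FPR of 0.20 is unattainable on
   finite samples; staying on the conservative side and reporting
   `achieved_fpr` makes the convention auditable. Subgroup TPR/FPR are
   computed at this single pooled τ — recalibrating per subgroup would
   erase exactly the disparity being measured.
4. **Uncertainty.** Percentile bootstrap (default 2000 replicates, 95%)
   over evaluation rows with τ held fixed; the uncertainty of τ itself is
   not propagated, matching the fixed-threshold reading of the metrics.
   Resampling is at the patient level (all of a patient's drawn rows move
   together) because repeated scans of one patient are strongly
   correlated. Replicates on which a metric is undefined (a resample
   missing a class) are redrawn and counted. Percentile rather than BCa:
   with balanced strata of hundreds of rows the refinement is negligible
   and the simple method is transparent.
5. **Disparity.** For one characteristic's panel (sex groups, or race
   groups — never pooled across characteristics), the relative change is
   $(m_g - \bar m)/\bar m$ with $\bar m$ the unweighted subgroup mean;
   the changes sum to zero by construction. Whether a headline summary
   should average over sex and race jointly is ambiguous; panels are kept
   separate and any pooling is left to the caller.
6. **Sensitivity.** `one_scan_per_patient()` reduces the cohort to one
   random scan per patient so any analysis can be repeated without
   within-patient clustering.

## The synthetic cohort: what it emulates and what it does not

`synthetic_config()` states a world: a CheXpert-like cohort of three
racial groups with strong imbalance (defaults 0.14/0.07/0.79), a 0.55/0.45
male/female split, age 63 ± 17 years truncated to [18, 100], one to three
scans per patient, a patient-level 60/10/30 train/validation/test split,
and four condition labels with per-group prevalences (defaults 0.10, 0.40,
0.12, 0.09). The sex split and age structure follow the published summary
of that cohort; the group proportions and prevalences are realistic
declared values, since the source tabulation is not machine-readable.

Embeddings follow an additive linear-Gaussian model: isotropic noise
($\sigma$, default 1) plus a shared per-patient random effect (default
0.25σ), displaced along mutually orthogonalized unit directions by disease
status (per-group effect sizes $\beta_{gl}$, default 1.5σ), sex (default
0.5σ on the male side) and group (defaults 0.4σ/0.4σ/0 with the majority
group as reference). Orthogonalization (Gram–Schmidt, in the order
disease, sex, group) makes the injected shifts statistically separable, so
ground truth is unambiguous in recovery tests. Default shift sizes are
chosen to represent a moderately biased backbone: detectable at the
audit's default subsample sizes, not overwhelming.

Two analytic consequences anchor the tests. With all effect sizes zero the
rows are i.i.d. isotropic Gaussian, so the audit must reject at most its
nominal rate. A pure mean shift $\delta$ between two Gaussian populations
has population KS distance $2\Phi(\delta/2) - 1$, giving a closed-form
target for the empirical statistic.

What the generator does **not** model: how real backbones encode protected
characteristics (nothing says the mechanism is additive or linear — this
is an explicit simplification, not a claim), label co-occurrence structure,
site/acquisition effects, or any image content. A green recovery test
therefore establishes that the audit machinery is correct, not that it
would detect every real-world bias mechanism.

## Numerical and reproducibility choices

* Every generation or sampling operation draws from its own RNG stream,
  seeded as `config seed + fixed per-operation offset` — reproducible
  without cross-operation coupling; all outputs are bit-identical under a
  fixed seed.
* KS survival function: $2\sum_{k\ge1} (-1)^{k-1} e^{-2k^2\lambda^2}$,
  truncated at 200 terms, clamped to (0, 1]; $\lambda \le 0.05$ returns 1
  (the series converges too slowly there and the true value is 1 to double
  precision).
* PCA on a constant matrix, requests for more modes than rows permit,
  empty samples, empty strata, p-values outside (0, 1], subgroups missing
  a class: all are errors or flagged `NA`s, never silent.
* Degenerate relative change (subgroup-mean zero) is an error: a relative
  scale does not exist there.

## Limitations

* The MLP trainer is plain full-batch Adam in R; it is adequate for the
  head sizes the audit uses (embedding dims in the tens to hundreds) but
  is not a deep-learning framework.
* The shift audit tests the first `n_modes` PCA modes only, mirroring the
  methodology it implements; a shift orthogonal to the leading modes (for
  instance, the default 0.5σ sex shift in a high-dimensional embedding
  where disease effects dominate the variance) can be missed. That is a
  property of the method, faithfully reproduced, not of the
  implementation.
* BY over the pooled family is conservative; per-characteristic families
  would reject more often and can be had by passing restricted comparison
  lists.
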