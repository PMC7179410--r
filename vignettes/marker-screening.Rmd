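---
title: "Screening chemical markers from untargeted LC-MS feature tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening chemical markers from untargeted LC-MS feature tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chemomarker` implements a complete screening workflow for finding chemical
markers that discriminate two groups of biological samples — in the motivating
application, the dried roots and rhizomes of two officinal *Gentiana* species
— from an aligned, normalized LC-MS feature table. This vignette explains the
statistical models behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical conventions the implementation commits to.

## The workflow

Starting from a samples × features abundance matrix with group labels
(`group_a`, `group_b`, `qc`), the stages run in a fixed order:

1. **QC-RSD filter.** Pooled quality-control samples are repeated injections
   of one physical mixture, so their variation is purely analytical. A
   feature whose relative standard deviation across QC injections exceeds
   15% is considered unstable and removed.
2. **80% rule.** A feature must be detected (non-missing and positive) in at
   least 80% of the samples of at least one biological group. This keeps
   group-specific compounds (present in only one species) while removing
   features that are sporadic everywhere.
3. **Univariate screen.** A two-sided pooled-variance Student's *t*-test per
   feature, flagged at raw p < 0.05.
4. **PCA.** An unsupervised overview with cumulative R²X and a 7-fold
   cross-validated Q².
5. **OPLS-DA.** A supervised model separating class-predictive from
   class-orthogonal variation, validated by permutation testing; features
   with VIP > 1 advance.
6. **Iterative random forests.** 100 forests with distinct seeds on the
   VIP-selected features; features that are the single most important
   variable in at least 4 of the 100 rankings become the selected markers.
7. **Final evaluation.** One forest on the selected markers, reporting the
   out-of-bag error rate and the ROC AUC from out-of-bag votes.

`run_pipeline()` executes all stages; each is also exported on its own.

## Filtering and scaling conventions

**RSD definition.** RSD = 100·s/m over the QC injections, with the n−1
standard deviation — QC counts are small (8 by default), so the unbiased
denominator matters. A feature whose QC mean is zero has an undefined RSD
and is removed as unstable.

**Presence.** "Detected" means non-missing *and* strictly positive, because
vendor exports use blank cells and zeros interchangeably for undetected
peaks. The 80% boundary is inclusive: 4 detections out of 5 qualifies.

**Missing values.** For the presence rule, missing is simply absent. For
every computation that needs a complete matrix (RSD, *t*-tests, all
multivariate models), missing cells are imputed with half of the feature's
minimum observed positive value — the standard below-detection surrogate in
metabolomics. This choice interacts with the marker-selection stage; see
*Known limitations*.

**Pareto scaling.** Before PCA and OPLS-DA each feature is mean-centered and
divided by the square root of its standard deviation. Full unit-variance
scaling inflates noise features; no scaling lets the most abundant compounds
dominate; Pareto is the metabolomics compromise. Scaling is *not* applied
before the *t*-test (the test is scale-equivariant) or the forests (trees
are invariant to monotone per-feature transforms). Constant features are
dropped with a warning since they carry no information and no valid scale.

## PCA and OPLS-DA

PCA components come from the singular value decomposition of the scaled
matrix; R²X per component is the component's share of the total sum of
squares. Q² is estimated by row-wise 7-fold cross-validation: loadings are
refit without each fold, held-out rows are projected onto them, and the
squared reconstruction error accumulates into PRESS with
Q² = 1 − PRESS/SS. Commercial chemometrics software sometimes uses
element-wise (EM-style) cross-validation instead; the row-wise scheme is
simpler, fully reproducible, and documented here as the package's
definition of Q².

The OPLS-DA follows the canonical orthogonal-projections formulation: the
predictive weight is w ∝ Xᵀy (y coded ±1 and centered; the first sorted
class label is +1); each orthogonal component is extracted from the part of
the X-loading orthogonal to w and deflated from X; the final predictive
component is a 1-component PLS fit on the deflated matrix. With zero
orthogonal components the model *is* 1-component PLS-DA, and the test suite
verifies that identity against an independently coded NIPALS implementation
and against `mixOmics::pls`. R²Y is the explained sum of squares of the
centered class vector; Q² cross-validates the whole filter-then-predict
composite with the same interleaved 7-fold scheme. Fold assignment is
deterministic over the *sorted* sample identifiers, so Q² does not depend on
the order samples happen to arrive in.

`k_orth = "auto"` keeps adding orthogonal components while Q² improves by
more than 0.01 — the usual significance-of-the-next-component heuristic.
A fixed `k_orth` is always available and is what the permutation test uses,
so every permuted refit has the original model's complexity.

**VIP.** VIP aggregates the squared normalized weights over all components,
weighted by each component's explained sum of squares of y. Orthogonal
components explain essentially none of y, so their weight collapses and the
mean of VIP² across features is exactly 1 — the customary VIP > 1 rule then
selects features that carry more than an average share of the
discrimination. The S-plot coordinates are the covariance and the Pearson
correlation of each feature with the predictive score.

**Permutation validation.** The class vector is shuffled (200 times by
default), the model refit each time, and R²Y/Q² recorded against the
absolute correlation between the shuffled and original labels. The
regression lines through those points — including the unpermuted model at
correlation 1 — give intercepts at correlation 0; an original Q² that
exceeds every permuted Q² and a low (typically negative) Q² intercept
indicate the discrimination is not an overfitting artefact.

## Iterative random-forest selection

Forests use 500 trees and mtry = ⌊√p⌋ (the classification default), with
permutation importance (mean decrease in accuracy). Each of the 100
iterations runs with seed = base seed + iteration, making the whole log
reproducible from one integer. Importance ranks break ties by feature
order, so rankings are valid permutations even in degenerate cases.

Two summaries are computed from the 100 rankings:

- the **cumulative top-N matrix** C[v, N] — in how many iterations feature v
  ranked within the top N — whose all-iterations plateau defines a *stable
  set* of consistently important features. The threshold N\* can be fixed or
  chosen automatically as the smallest N whose (non-empty) stable-set size
  is unchanged for 3 consecutive N; the non-emptiness condition avoids the
  degenerate plateau of size 0 at very small N.
- the **rank-1 frequency** — in how many iterations feature v was the single
  most important variable. Markers are the features reaching at least
  `min_frequency = 4`. The inclusive "≥" reading is deliberate: with the
  frequency tabulation {9, 6, 5, 5, 5, 5, 4, 4, 4, 4, 4} it returns 11
  variables, which is the only reading under which that published-style
  tabulation sums to 11 selected markers.

The final forest on the selected markers reports its OOB error and the AUC
of the ROC built from OOB class-vote fractions — OOB votes are genuine
held-out predictions, so no separate test split is introduced.

## The synthetic-data generator

Real raw data for the motivating study are not publicly deposited, so every
stage is exercised against `synthesize_table()`, which emulates the study
design: 52 + 34 biological samples, 8 pooled-QC injections, 400 features,
10 planted markers.

- **Intensity model.** Log-normal: log2 intensity = per-feature baseline
  (uniform on [10, 20] log2 units, i.e. abundances spanning roughly
  10³–10⁶, a typical dynamic range for normalized LC-MS peak tables)
  ± half the planted log2 fold change (2.0 by default, antisymmetric so
  half the markers are up in each group) + Gaussian noise with
  σ_log = √ln(1 + CV²) so that the natural-scale coefficient of variation
  equals the configured 30% biological / 8% technical values.
- **QC samples** are noisy replicates of the pooled grand profile, exactly
  how pooled QC samples are prepared in practice. Planted unstable features
  get a 40% technical CV, far enough above the 15% threshold that their
  empirical RSD over 8 injections exceeds it with high probability.
- **Sparse features** are forced missing in 30% of the samples of *each*
  group (70% presence < 80% in both), so the 80% rule must remove them.
- **Missingness** is otherwise completely at random at 5% in biological
  samples. Marker, unstable and sparse sets are disjoint by construction.
- Generation is a pure function of the config including its seed.

What the generator does **not** emulate: retention-time drift, correlated
co-eluting features, isotope/adduct redundancy, batch effects, and
intensity-dependent (left-censored) missingness. Passing tests therefore
demonstrate the correctness and determinism of the computations and the
recoverability of planted structure — not performance on the full
messiness of real data.

## Problem sizes used by the test suite

The suite runs the full default design (94 × 400) for the end-to-end
properties, 200 label permutations for the validation test, and smaller
matrices (20–60 samples, 20–50 features, 10–50 forest iterations) for
model-level properties where the property itself does not depend on scale.
These sizes are the package's own choices to keep the examples sharp and
quick while leaving every assertion at full strength.

## Known limitations

- **Rank-1 concentration.** The 100 forest iterations refit the *same*
  dataset with different RNG streams. With 500 trees the forest-to-forest
  importance noise is small, so the rank-1 frequency concentrates on the
  few features that happen to separate the groups most cleanly in that one
  sampling draw — on default synthetic data the rule therefore selects a
  small, pure subset of the planted markers (false-discovery proportion 0,
  but sensitivity well below 1). A broad rank-1 rotation like the published
  {9, 6, 5×4, 4×5} tabulation requires many near-tied features, a regime
  real data can occupy but a design with a handful of strong planted
  markers does not. The cumulative top-N stable set is the robust
  alternative when the goal is recovering *all* consistently important
  features; both summaries are exported.
- Half-minimum imputation of completely-at-random missing cells places
  imputed values at the bottom of a feature's range regardless of the
  sample's group, which blurs otherwise clean markers; this mirrors what
  the same convention does on real data.
- The PCA Q² scheme is row-wise, as documented above; numbers from software
  using element-wise CV are not directly comparable.
- The m/z arithmetic covers C/H/N/O/S/P/Na/Cl monoisotopic masses and the
  two negative-mode adducts used by the compound tables; it is annotation
  arithmetic, not structure elucidation.

## Compound tables and m/z auditing

The package ships verbatim transcriptions of the study's compound tables
(87 characterized constituents with class and species flags; 11 screened
markers of which 7 are identified; the sample-collection layout).
`audit_fixture_mz()` recomputes every record's adduct m/z from its formula
— `[M−H]⁻` = M − 1.00727646, `[M−H+HCOOH]⁻` = M + 46.00548 − 1.00727646,
with the electron mass folded into the proton constant since the tables
print 2 decimals — and flags records whose printed value deviates by more
than 0.02 Th. Several printed rows are internally inconsistent; the audit
reports them and the fixtures keep them untouched, because a transcription
that silently "corrects" its source is worth less than one that documents
the discrepancies. `explain_losses()` matches precursor-fragment mass
differences against a library of common neutral losses (water, ketene,
anhydroglucose, the C₃H₆O₃ cross-ring loss, …) to reproduce the glycoside
fragmentation ladders used in compound characterization.
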