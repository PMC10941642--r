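---
title: "Scoring metabolomics processing schemes against a quantitative reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolomics processing schemes against a quantitative reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaeval)
```

## The model behind the benchmark

Semiquantitative metabolomics measures peak areas
$a_{ij} \approx c_{ij} \, e_i$, where $c_{ij}$ is the true concentration
of metabolite $j$ in sample $i$ and $e_i$ is a sample-specific
multiplicative technical error accumulated through extraction,
derivatisation and injection.  A spiked internal standard (IS) is a
compound of *known, constant* amount, so its measured response tracks
$e_i$.  The quality of a data-processing recipe can then be judged by
how closely the multivariate analysis of the processed areas matches the
same analysis of a paired absolutely quantified dataset of the same
samples.

The analysis whose output is compared is PLS-DA against the biological
group factor, summarised by the VIP vector (one importance score per
metabolite, with $\mathrm{mean}(VIP^2) = 1$ by construction).  Two
processing routes $x$ and $y$ are compared by
$\mathrm{sim}(x,y) = 1 - \lVert x - y \rVert_2$.  This statistic is
exactly 1 for identical VIP profiles and *unbounded below*: a scheme
that inflates the importance of many metabolites can score far below
zero.  Because of that, the package always emits a second column in
which both VIP vectors are first scaled to unit Euclidean norm, bounding
the distance by 2; every table names the column it ranks by.

## The processing stages

**ccmn.**  The IS responses contain the systematic error, but they can
also pick up biological variation (carry-over, matrix effects that
co-vary with the groups).  ccmn therefore (1) centres the log IS matrix,
(2) projects it onto the orthogonal complement of the one-hot group
design — removing everything a group mean could explain — (3) extracts
the first `np` principal-component scores of the residual as error
estimates, (4) regresses each centred log analyte on those scores and
subtracts the fit, and (5) restores means and exponentiates.  The
retained scores are orthogonal to the design by construction, so group
separation cannot be removed.  `np` defaults to `min(2, q)` for `q`
internal standards; with the single IS of both simulated presets,
`np = 1`.  Computation is on the natural-log scale with
back-transformation (`log_internal = TRUE`), matching the reference
implementation of the method; the raw-scale variant exists for data that
are already log-like.

**nomis** regresses centred log analytes on the centred log IS matrix
directly, with no design orthogonalisation.  When biology leaks into the
ISs, nomis removes it together with the error — the package's
ccmn-vs-nomis contrast test simulates exactly this leakage and checks
that the post-normalization group F statistic is higher under ccmn.

**Transformations and scalings** use the conventional definitions;
the sample ($n-1$) standard deviation is used everywhere, and scaling
statistics are computed over *all* samples of the dataset being
processed, QCs included, because whole datasets are processed before any
group-wise evaluation.  The generalized log is
$\mathrm{glog}_B(x;\lambda) = \log_B\!\big((x + \sqrt{x^2+\lambda})/2\big)$
with $\lambda$ in squared-intensity units; the automatic rule sets
$\lambda$ to the square of the smallest strictly positive value of the
dataset, which makes the transform behave like a plain log across the
observed dynamic range while staying defined at zero.  The chosen
$\lambda$ is recorded per scheme in the evaluation report.  Negative
feature means under level scaling are allowed but flagged, since
`(x-m)/m` then flips signs.

**Order is fixed**: normalization, then transformation, then scaling.
`"ccmn+sqrt+none"` is the canonical string form; the all-`none` recipe
prints as `"raw"`.

## Missing values

Below-LOD absence is not missing-at-random: a metabolite genuinely
absent from one sample group produces a whole missing block.  The
two-stage policy treats a (feature, group) block with a missing fraction
strictly above 30 % as structural and fills it with the feature's
*global* observed minimum (the group minimum may not exist when the
whole block is missing).  Remaining sporadic cells are imputed with an
iterative random-forest scheme: initialise with feature means, regress
each incomplete feature on all others with a regression forest
(100 trees, `mtry = p/3`, terminal nodes of at most 5 observations),
sweep in order of increasing missingness, and stop at the first increase
of the normalised squared change between successive imputations
(returning the previous iterate) or after 10 sweeps.  No published
hyperparameters exist for this step in the workflow the package
follows, so the defaults are the standard ones of the iterative-forest
literature and are recorded in the imputation report.  The forest is a
small pure-R CART implementation: the imputer only ever sees
metabolomics-sized matrices (tens of samples, tens of features), and a
compiled dependency would be the only reason to ship one.

## PLS-DA conventions

NIPALS PLS2 on column-mean-centred X and one-hot, column-centred Y.  No
internal scaling is applied to X — the processing scheme under test owns
any scaling, and silently autoscaling inside the model would collapse
all location-scale scalings of the grid into one.  Pooled QC samples are
excluded from the class model by default (they are not a biological
class) but participate in PCA and the property profiles.  The component
count is fixed at $A = 2$ for every benchmark fit: the case studies the
benchmark emulates use two-component score plots, and the report records
$A$ so sensitivity can be re-run.  Components are sign-fixed (largest
weight element positive) so stored loadings are reproducible; requests
beyond the data rank truncate with a warning.

## The synthetic world

`sim_preset("milk")` emulates a well-controlled food study: 4 groups of
13/6/7/3 biological samples, triplicate injections, 10 pooled QC
injections, 16 metabolites of which 2 are dominant (50-fold above the
largest ordinary baseline, strong group effects), one IS, shared
multiplicative error with $\sigma_e = 0.3$ on the log scale,
per-cell biological noise $\sigma = 0.2$, and three (feature, group)
blocks forced below the limit of detection so the structural imputation
rule has realistic targets.  `sim_preset("urine")` emulates a clinical
cohort: 2 groups of 53/63 subjects, 8 metabolites, one IS, large
inter-individual variance ($\sigma = 0.8$), weak group effects.
Dominant-feature folds, group-effect sizes and noise levels were chosen
once to reproduce the qualitative features reported for the real
studies (a few highly abundant right-skew-driving metabolites; weak,
noisy class separation in urine) and are not tuned per test.

Concentrations are log-normal:
$c_{ij} = \exp(\mu_{g(i)j} + \varepsilon_{ij})$; areas are
$a_{ij} = c_{ij} \, e_i \, \exp(\tau_{ij})$ with
$e_i \sim \mathrm{LogNormal}(0, \sigma_e)$ shared across all analytes
and ISs of sample $i$, and small per-cell technical noise $\tau$
defaulting to half the biological noise so that a noise-free design
yields `area == conc` bit-exactly.  An optional leak coefficient couples
a per-group contrast into the IS responses for the ccmn-vs-nomis
contrast.  The generator always returns the truth (per-sample $\log e_i$
and the group-mean matrix), so tests never re-derive hidden parameters.

What the simulator does **not** emulate: chromatographic drift or batch
order (no drift correction is in scope), correlated metabolite blocks
(pathway structure), heavy-tailed outliers, or non-linear IS-analyte
relationships.  A green benchmark test therefore establishes that the
pipeline recovers a *linear, log-normal* shared error — it says nothing
about drift-dominated or strongly non-linear data.

## Numerical choices

* Pseudo-inverses (rank-deficient designs, constant ISs) go through an
  SVD with relative tolerance $10^{-10}$; a constant IS yields a zero
  correction rather than an error.
* Shapiro–Wilk is undefined for constant group values; such features are
  counted as non-normal with a warning.
* Skewness uses the moment estimator with the $((n-1)/n)^{3/2}$
  small-sample factor, the default of the tooling commonly cited for
  this diagnostic.
* CV is undefined for zero group means and recorded as `NA`; the
  fold-difference trend records zero-mean cells as missing rather than
  dividing by zero.
* Hierarchical clustering of VIP profiles uses Euclidean distances with
  complete linkage by default (average and Ward are available).
* Schemes whose domain preconditions fail on a given dataset (log of
  zero, power scaling of negative values) are recorded as *skipped* with
  the error message; the benchmark never silently drops or fails a grid
  cell.

## Design decisions that were genuinely open

* **Similarity normalization.**  The literal similarity statistic is
  unbounded below, yet published percentages for real case studies fall
  in 4–83 %, which suggests bounded distances.  Both variants are
  computed side by side; the default ranking column is the literal
  statistic, and tables name the column used.
* **Benchmark geometry caveat.**  On simulated pairs the plain `ccmn`
  scheme robustly beats `raw`, but the *grid-wide mean* similarity of
  ccmn-containing schemes does not beat the matching non-ccmn schemes:
  after strong scalings (auto, range, vast) the reference VIP profile —
  dominated by the two abundant markers — is far away regardless, and
  removing the shared error shifts weak features' importance in a
  direction that this unbounded statistic punishes.  This mirrors the
  behaviour of the real case studies, where a ccmn + cube + vast recipe
  was the single *worst* performer.  The package reports the per-scheme
  table and leaves the aggregation to the analyst.
* **Exchange format.**  A single wide CSV with reserved metadata columns
  and `#` comment headers (unit tag, IS list) keeps round trips lossless
  without sidecar files; a sidecar feature-metadata CSV and an IS name
  prefix are also accepted on read.  Repository-specific table formats
  are deliberately not parsed; users reshape to the wide CSV.
* **Structural-minimum source.**  The feature's global minimum (not the
  group minimum) is used for structural substitution, because the rule
  fires precisely when a group has no observed values.

## Known limitations

* The random-forest imputer is exact enough for sporadic missingness but
  slow for thousands of features; it is pure R by design.
* PLS-DA assumes complete data; imputation must run first.
* The benchmark requires identical sample ordering between the area and
  concentration tables and will not align keys itself.
* Property-profile PCA needs at least three successfully profiled
  schemes and silently omits schemes whose groups are too small for
  Shapiro–Wilk.
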