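---
title: "Stability-selected elastic-net VAR networks: model, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected elastic-net VAR networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabvar)
```

## The inference problem

Given expression for $p$ genes measured at $T$ time points in $R$
replicates, we want a *directed*, *signed*, *lagged* network: an edge
$g' \to g$ asserts that the past expression of $g'$ improves prediction of
$g$'s present expression beyond what $g$'s own past and every other gene's
past already provide — conditional Granger causality.  Transcriptional
time series make this hard in a characteristic way: $p$ is large, $T$ is
small (often 10–25 points), replicates are few, and effects must be
estimated for every ordered gene pair at once.

## The model

Each gene $g$ is modelled as a lag-$L$ vector autoregression
$$
X_t^g \;=\; \sum_{\ell=1}^{L} \alpha_\ell^g X_{t-\ell}^g
 \;+\; \sum_{g' \neq g}\sum_{\ell=1}^{L} \beta_\ell^{g',g} X_{t-\ell}^{g'}
 \;+\; \epsilon_t ,
$$
with Gaussian innovations.  Stacking times $t = L+1,\dots,T$ over
replicates gives $N = R\,(T-L)$ rows per effect gene; replicates enter as
independent stacked rows (no replicate random effect).  The predictor
matrix is ordered lag-major — all genes at lag 1, then all genes at lag 2
— a convention fixed once and asserted in tests; the row order
(time-major, replicates in declared order) is equally a convention and
affects no estimator.

Because $Lp \gg N$, the coefficients are estimated under an elastic-net
penalty,
$$
\hat\beta \;=\; \arg\min_b \;\|y - Xb\|_2^2
 + \lambda\left(a\|b\|_1 + (1-a)\|b\|_2^2\right),
$$
written here exactly as the package minimizes it: no $1/2$ on the
quadratic term, no $1/N$ on the loss, and no intercept (profiles are
centered first).  The solver is a small compiled cyclic coordinate
descent on the Gram matrix.  Keeping the objective in this exact form
matters for calibration: ridge ($a=0$) must agree with its closed form
$(X'X+\lambda I)^{-1}X'y$ and lasso ($a=1$) on an orthonormal design must
soft-threshold ordinary least squares at $\lambda/2$; both identities are
enforced to $10^{-6}$ in the test suite, and a proximal-gradient
implementation — a different algorithm family — serves as the oracle for
intermediate $a$.

### Preprocessing

Each (gene, replicate) temporal profile is centered to mean zero across
time and deliberately *not* scaled to unit variance: rescaling would
inflate the apparent influence of nearly-flat profiles.  Missing time
points are filled by linear interpolation in actual time coordinates
(never index positions), and never extrapolated at series ends.  Values
are modelled in whatever (typically log-scale, batch-corrected) space
they arrive in; the package applies no expression-level normalisation of
its own.  Zero-variance genes are dropped with a warning — they carry no
temporal signal and destabilise cross-validation.  Unevenly spaced series
are accepted, but a max/min gap ratio above 4 triggers a warning because
the model assumes comparable causal effects across gaps.

### Hyperparameters

One penalty pair $(\lambda^*, a^*)$ is selected for *all* genes by
leave-one-out cross-validation over the grid
$\lambda \in \{10^{-4},\dots,1\}$, $a \in \{0.1, 0.3, \dots, 0.9\}$: for
every grid point, gene, and design row, the model is refit without that
row and the squared error on the held-out row is accumulated with a
$1/N$ scale per gene.  Exact ties are broken toward the sparser model
(larger $\lambda$, then larger $a$) so the selection is deterministic.
The pair is tuned once on the original data and reused for every
permutation and bootstrap refit — this constant-time hyperparameter
search is what keeps the bootstrap ensemble affordable, and it reflects
the view that the permuted and resampled data sets are stand-ins for the
original, not new estimation problems.

## Calibration by permutation

### Edge FDR

A single permuted data set is created by shuffling each (gene, replicate)
profile independently across time, destroying lagged cross-gene
dependence while preserving marginals.  For each effect gene the model is
refit with the effect gene's own lagged values *unpermuted* (self-dynamics
are preserved; self-loops are never candidate edges) and all other genes
permuted.  For each (effect gene, lag), the coefficient magnitude
threshold is the smallest observed value $T$ at which
$$
\frac{\#\{|\tilde\beta| > T\}}{\#\{|\tilde\beta| > T\} + \#\{|\beta| > T\}}
\;\le\; 0.05 ,
$$
with strict inequalities as written and $0/0$ read as $0$.  An edge
survives if it clears the threshold at any lag.  The scan always
terminates because the ratio is $0$ at the largest observed magnitude.

### Stability selection and stability FDR

The thresholded inference is repeated on $B$ bootstrap resamples of the
design rows (default $B = 1000$; $B = 100$ is a documented fast mode —
the acceptance suite asserts that on the reference fixture the two agree
to an edge Jaccard of at least 0.6 and a mean absolute
selection-frequency deviation of at most 0.05).  A bootstrap
fit is the weighted fit with the resample's integer row multiplicities,
and the *same* row multisets are applied to the real design and to its
permutation-null counterpart, so each bootstrap network has an honest
per-bootstrap edge-FDR calibration.  An edge's selection frequency $\pi$
is the fraction of bootstrap networks containing it.

Selection frequencies need their own null: a *second*, independent
permutation of the data is run through the identical machinery (same row
multisets, first permutation still providing the coefficient null),
yielding null frequencies $\hat\pi$.  With two lags each pair carries two
frequencies; the lag whose mean bootstrap coefficient is larger in
magnitude is chosen — independently on the real and null sides, ties to
the smaller lag — and one global frequency cutoff $T_b$ is then the
smallest observed value at which the same ratio rule holds at level 0.2.
Pooling globally (rather than per effect gene) follows from reporting a
single network-wide frequency cutoff; this is flagged in the
documentation since per-gene pooling is a defensible alternative.

Mean bootstrap coefficients average the fitted value over *all* $B$ fits,
zeros included, whether or not the edge survived that bootstrap's
edge-FDR — the simplest reading of an "average across the bootstrap
networks" — and the edge's sign and effect size are taken from that mean
at the chosen lag.

Worked at desk scale:

```{r example}
sim <- simulate_var(p = 8, density = 0.12, n_times = 14, n_reps = 4, seed = 5)
fit <- stabvar(sim$ts, boots = 50, seed = 9, lambda = 0.01, a = 0.5)
fit
head(as.data.frame(fit), 4)
aupr(edge_ranking(fit, "frequency"), sim$gold)
```

## What the simulator emulates — and what it does not

`simulate_var()` plants a sparse random coefficient structure (default
edge density 0.05, magnitudes in $[0.5, 1]$, 30% negative, lag drawn
uniformly per edge, lag-1 self-decay in $[0.2, 0.5]$), rescales it to a
companion-form spectral radius of at most 0.95, and iterates the process
with Gaussian innovations (sd 0.2) from a 200-step burn-in.  The default
shape — 15 genes, 21 time points, 10 replicates — is a desk-scale version
of the community-benchmark geometry (100 genes, 21 points, 10 series),
chosen so that a full pipeline run takes seconds rather than hours.
`add_perturbation_phase()` optionally adds the benchmark's square-wave
"drug" shift to a third of genes for the first half of the series.

The simulator is a deliberate idealisation: its processes are stationary,
linear, Gaussian, and complete, whereas real post-exposure expression is
none of these.  Passing the recovery suite therefore demonstrates
correctness of the machinery — solver exactness, honest FDR calibration,
frequency ranking that finds planted structure — not that the method will
achieve any particular accuracy on RNA-seq data.  Conversely the
simulator does reproduce the features the method actually leans on: short
replicated series, sparsity, signed lagged effects, and a gene count
exceeding what a per-time-point analysis could resolve.

## Numerical choices and degenerate inputs

- Coordinate descent runs to a $10^{-12}$ coefficient-change tolerance;
  grids are solved warm-started (lambdas descending within each `a`).
- LOOCV refits reuse rank-one Gram downdates; at the default grids and
  the reference fixture (15 genes, $N = 190$) tuning takes a few seconds.
- FDR threshold scans use strict `>` on both counts, candidates are the
  observed magnitudes, and both estimated-FDR inequalities are asserted
  at run time on every fit.
- An all-zero response returns the zero coefficient vector; all-zero
  null magnitudes keep every positive coefficient; identical real and
  null distributions force an empty survivor set.
- Missing values at terminal time points are an error (no extrapolation);
  duplicated (gene, time, replicate) records and non-numeric fields are
  hard errors with locations.
- Bootstrap index sets are drawn sequentially, so runs with smaller $B$
  are prefixes of runs with larger $B$ under the same seed; per-gene
  accumulators are checkpointed to disk and resumed exactly.
- Gene-level bootstrap loops are independent and may be forked
  (`cores`); reductions are order-insensitive, so the worker count never
  changes the result.

## Open design points, resolved

- *Re-centering under resampling*: bootstrap resampling breaks exact
  zero means; we still fit without an intercept to stay in the stated
  model class, accepting the small misfit rather than re-centering each
  resample (which would change the null-comparability of coefficients).
- *Row and column order*: the stacking order of replicates within time
  points and the lag-major column order are equivalent conventions; both
  are fixed and asserted rather than configurable.
- *Ranking comparisons*: both the frequency ranking and the single-fit
  coefficient-magnitude ranking are always available
  (`edge_ranking()`), so the value added by the bootstrap is measurable
  on any data set.
- *Validation regressions*: the pairwise lag-1 validation fit is plain
  OLS (no penalty) because validation series are short and the question
  is directional concordance, not selection; slopes carry ordinary
  t-test p-values with Benjamini–Hochberg adjustment across cause genes.

## Known limitations

Linearity and stationarity are assumed, not checked; edges are
conditional Granger claims, not interventional ones; the inferred graph
is not constrained acyclic; and with strongly uneven time grids the
meaning of a "lag" drifts.  The stability-FDR cutoff is a network-wide
quantity — per-effect-gene calibration would give different (possibly
better localised) control.  Finally, every empirical number quoted above
is one the package's own tests or acceptance script recompute; none are
imported from elsewhere.
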