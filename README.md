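# stabvar

Directed gene-network inference from short, replicated expression time
series, for systems biologists who have a few dozen time points and want
signed, lagged, statistically calibrated cause→effect hypotheses rather
than co-expression clusters.

## The method

An edge g′ → g is claimed when the past expression of g′ improves
prediction of g beyond g's own past and every other gene's past —
conditional Granger causality.  Each gene g is fit as a lag-L vector
autoregression over all p genes,

    X_t^g = Σ_ℓ α_ℓ^g X_{t−ℓ}^g + Σ_{g′≠g} Σ_ℓ β_ℓ^{g′,g} X_{t−ℓ}^{g′} + ε_t,

estimated under an elastic-net penalty λ(a‖β‖₁ + (1−a)‖β‖₂²) because the
L·p predictors far exceed the N = R(T−L) stacked samples.  Significance is
calibrated empirically, twice:

1. **Edge FDR (≤ 0.05).**  Each gene's temporal profile is shuffled across
   time (per replicate) to build a null coefficient distribution; per
   effect gene and lag, coefficients are kept only above the smallest
   magnitude threshold at which the null/real exceedance ratio is ≤ 0.05.
2. **Stability FDR (≤ 0.2).**  The thresholded inference is repeated on
   B bootstrap resamples of the design rows (B = 1000 by default, 100 as a
   fast mode); an edge's *selection frequency* π is the fraction of
   bootstrap networks containing it.  A second, independent permutation is
   pushed through the identical machinery to get null frequencies, and one
   network-wide cutoff on π is chosen by the same ratio rule at 0.2.

Surviving edges carry a lag (the one with the larger mean bootstrap
coefficient), a sign, and an effect size.  The package also bundles a
sparse-VAR simulator with planted ground truth, AUPR/AUROC benchmarking
against gold-standard edge lists, Fisher-exact gene-class enrichment, and
an unpenalized pairwise lag-1 VAR for validating edges on perturbation
(e.g. overexpression) series.

## Worked example

```r
library(stabvar)
sim <- simulate_var(p = 10, density = 0.08, n_times = 15, n_reps = 4, seed = 3)
fit <- stabvar(sim$ts, boots = 100, seed = 8)
fit
#> Stability-selected elastic-net VAR network
#>   data: 10 genes, 15 time points, 4 replicates (52 rows, lag 2)
#>   penalty: lambda = 1, a = 0.9 (elastic_net, LOOCV)
#>   bootstrap: B = 100, edge FDR <= 0.05
#>   stability threshold: pi > 0.5 (stability FDR <= 0.2)
#>   network: 12 directed edges
head(as.data.frame(fit), 5)
#>  cause effect lag sign effect_size selection_frequency
#>     g1    g10   1   -1      -0.566                1.00
#>     g2     g3   2    1       0.525                0.99
#>     g7     g6   1    1       0.238                0.96
#>     g7     g5   1    1       0.481                0.95
#>     g4     g9   2    1       0.277                0.87
aupr(edge_ranking(fit, "frequency"), sim$gold)
#> [1] 0.81
```

The fit says: leave-one-out cross-validation settled on a strong, mostly
ℓ₁ penalty (λ = 1, a = 0.9); after 100 bootstrap networks, edges appearing
in more than half of them clear the frequency null at stability FDR ≤ 0.2,
giving 12 directed edges (the simulator planted 5; ranking all 90 ordered
pairs by selection frequency scores AUPR 0.81 against that ground truth).
Signs distinguish activating from inhibitory effects — e.g. g1 ⊣ g10 is
inhibitory with effect size −0.57 at lag 1.

Classed-object niceties: `summary()`, `coef()` (cause × effect × lag
tensor), `predict()`/`residuals()` (one-step-ahead), `plot()` (real vs
null frequency histograms), `simulate()` (new series from the fitted
process), `write_network()`/`read_network()` (ranked TSV).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/stabvar simulate --spec inst/extdata/specs/dense-small.yaml --out sim/
Rscript inst/cli/stabvar infer --input sim/timeseries.tsv --bootstrap 100 --seed 42 --out run/
Rscript inst/cli/stabvar evaluate --network run/network.tsv --gold sim/gold.tsv
```

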