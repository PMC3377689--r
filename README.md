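# hdmrnet

Variance-based inference of biological network structure from multivariate
single-cell-style measurements, using the Random Sampling High Dimensional
Model Representation (RS-HDMR).

## The problem and who this is for

Given tables of simultaneous per-cell measurements of many network nodes
(phosphoproteins, lipids, cytokines — one table per experimental
condition), a systems biologist wants three things at once:

1. **structure** — which nodes act on which, including nonlinear and
   cooperative (multi-input) effects, while suppressing indirect
   connections that pass through measured intermediates;
2. **forward prediction** — the value of an unmeasured node from the rest
   of the observed network state;
3. **inverse classification** — which experimental perturbation a cell was
   subjected to, from its observed state alone.

hdmrnet addresses all three with a single fitted object. For each output
node $y$ it estimates the hierarchical expansion

$$g(\mathbf{x}) \approx f_0 + \sum_i f_i(x_i) + \sum_{i<j} f_{ij}(x_i,x_j)
+ \sum_{i<j<k} f_{ijk}(x_i,x_j,x_k),$$

where each component function is a weighted sum of orthonormal polynomials
built from the empirical sample measure (so no distributional assumptions
and no discretization). Candidate components are screened by an F-test on
the reduction in residual sum of squares (*model reduction*), survivors are
refit jointly by least squares, and each component receives a sensitivity
index $S_k = \mathrm{cov}(\hat f_k, y)/\mathrm{var}(y)$ — its share of the
output variance, with covariance contributions under correlated inputs;
$\sum_k S_k + S_\mathrm{res} = 1$ exactly. Per-input totals $T_i$ (summed
over all components containing input $i$), aggregated across conditions by
their maximum and thresholded at $\tau$, give the network edges. The fitted
expansion doubles as a Fully Equivalent Operational Model (FEOM): evaluated
forward it predicts nodes; fitted on a control-vs-perturbed
pairwise-comparison table with Boolean labels it classifies conditions at a
0.5 threshold.

Everything is tidyverse-native: functions take a data frame first and
return tibbles, fitted objects have `tidy()`/`glance()` methods and
`autoplot()` diagnostics.

## A worked example

Fit a known cooperative benchmark (two interacting inputs plus a product
term, 10% output noise) and compare estimated sensitivity indices with the
generator's closed-form truth:

```r
library(hdmrnet)

spec  <- make_benchmark_spec("cooperative", seed = 3)
d     <- sample_synthetic(spec, 3000)          # tibble: 3000 cells x 5 nodes
model <- fit_hdmr(d, "y", max_order = 2)
model
#> <hdmr_model> output 'y' (n = 3000)
#>   f0 = 0.3215 (normalized scale), residual variance = 0.0004288
#>   components: 2 first-, 1 second-, 0 third-order
#>    x1, x2, x1:x2

report <- compute_sensitivities(model, d)
tidy(report)
#> # A tibble: 3 x 4
#>   component order variables     S
#>   <chr>     <int> <chr>     <dbl>
#> 1 x1            1 x1        0.555
#> 2 x2            1 x2        0.300
#> 3 x1:x2         2 x1,x2     0.135

analytic_sensitivities(spec)$components
#> # A tibble: 3 x 4
#>   output id    order     S
#>   <chr>  <chr> <int> <dbl>
#> 1 y      x1        1 0.569
#> 2 y      x2        1 0.279
#> 3 y      x1:x2     2 0.142
```

The F-test kept exactly the three true components (the two noise-only
inputs were rejected), and each estimated index sits within Monte-Carlo
error of its analytic value: x1 alone explains ~56% of the output variance,
x2 ~30%, and the cooperative x1·x2 interaction ~14%, with ~1% residual.
`autoplot(report)` draws the decomposition; `aggregate_network()` +
`export_network()` turn per-condition reports into a thresholded SIF/
adjacency network, and `evaluate_prediction()` / `classify_inverse()`
exercise the forward and inverse FEOMs. `run_pipeline()` (or the
`inst/scripts/hdmrnet` command-line wrapper) chains every stage from a YAML
config and writes a manifest with seeds and checksums.

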