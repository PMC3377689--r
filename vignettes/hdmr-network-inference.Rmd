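---
title: "Variance-based network inference with RS-HDMR: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-based network inference with RS-HDMR: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmrnet)
```

## The model

hdmrnet treats each node of a biological network (a phosphoprotein, a lipid,
a cytokine) as a function of the remaining measured nodes. For an output
$y = g(x_1, \dots, x_N)$ observed over $n$ randomly sampled cells, the
Random Sampling High Dimensional Model Representation (RS-HDMR) expands $g$
hierarchically:

$$
g(\mathbf{x}) \approx f_0 \;+\; \sum_i f_i(x_i) \;+\; \sum_{i<j}
f_{ij}(x_i, x_j) \;+\; \sum_{i<j<k} f_{ijk}(x_i, x_j, x_k),
$$

where $f_0$ is the output mean, first-order components $f_i$ capture
independent effects, and second/third-order components capture cooperative
effects. Each component is a weighted sum of orthonormal polynomial basis
functions of its inputs; higher-order components use tensor products of the
per-variable polynomials.

The practical appeal for single-cell data is that each of the $n$ scattered
sample points informs *every* component simultaneously, so nonlinear and
cooperative structure can be estimated from realistic sample sizes without
discretizing the measurements.

### Data-adaptive orthonormal bases

For each input, the monomials $x, x^2, \dots$ are orthonormalized against
the constant under the *empirical* inner product
$\langle f, g\rangle = \tfrac1n \sum_t f(x_t)\,g(x_t)$ — Monte-Carlo
integration over the sample measure, so no parametric assumption about the
input distribution is made. We use modified Gram–Schmidt with one
re-orthogonalization pass, which keeps the empirical means, unit mean
squares and cross-products of the polynomials within about $10^{-14}$ of
their targets for degrees up to 3 on unit-interval data; a relative
tolerance of $10^{-10}$ flags rank deficiency (too few distinct values for
the requested degree). The leading coefficient of each polynomial is made
positive so the basis is unique. On a uniform sample the construction
converges to the shifted Legendre polynomials $\sqrt3(2x-1)$,
$\sqrt5(6x^2-6x+1)$, $\sqrt7(20x^3-30x^2+12x-1)$, which is the oracle used
in the tests.

Second- and third-order component functions use pure tensor products of the
first-order polynomials, without re-orthogonalizing the products against
lower orders: the products of zero-mean factors are used as they are, and
any residual non-orthogonality (present only under correlated inputs) is
handled downstream by the covariance-aware sensitivity indices.

### Model reduction by F-test

All inputs are candidates at first order. Candidates are visited in
deterministic lexicographic order; each candidate's basis terms are added
to the running model and kept only when the F statistic on the reduction in
residual sum of squares is significant at level $\alpha$ (default 0.01,
configurable). Selection proceeds order by order; under the default
*hierarchical* policy, second- and third-order candidates are drawn only
from inputs that already carry a significant first-order component, which
is what is observed in practice for signaling data and keeps the candidate
count linear-ish rather than combinatorial. An exhaustive policy is
available. After selection, every surviving component is refit **jointly**
by least squares around the output mean — coefficients are not frozen from
the screening stage. Each component's term columns are centered on their
training means, so $f_0$ equals the training mean of the output exactly and
the training residuals have exactly zero mean.

Multiple-testing correction across candidates is deliberately not applied
by default (the per-candidate type-I rate, not the family-wise rate, is
calibrated to $\alpha$); this matches the method's standard practice, and
the null-data tests verify the per-candidate rate directly. The selection
log records every tested candidate with its F statistic and p value, so a
Benjamini–Hochberg pass can be applied post hoc by the user if desired.

The joint refit is what suppresses *indirect* connections: a source node
acting on the output only through a measured intermediate is often
marginally significant (it is correlated with the output), but once the
intermediate's component is in the model the source's coefficients shrink
toward zero and its sensitivity share becomes negligible.

### Sensitivity indices

With components $\hat f_k$ evaluated over a table and
$\varepsilon = y - \hat g(\mathbf{x})$, the package attributes to each
component

$$
S_k = \frac{\operatorname{cov}(\hat f_k,\, y)}{\operatorname{var}(y)},
\qquad
S_{\mathrm{res}} = \frac{\operatorname{cov}(\varepsilon,\, y)}
{\operatorname{var}(y)},
$$

with the population ($1/n$) convention throughout, matching the
Monte-Carlo reading of all integrals. Because
$\sum_k \hat f_k + \varepsilon = y - f_0$, the identity
$\sum_k S_k + S_{\mathrm{res}} = 1$ holds *exactly* (to machine precision),
which the tests assert at $10^{-10}$. Under independently sampled inputs
the cross-covariances vanish and $S_k \to \operatorname{var}(\hat f_k) /
\operatorname{var}(y)$, the classical variance-based index. Under
correlated inputs the variance decomposition contains pairwise covariance
terms; how to apportion them to individual components is genuinely open,
and we adopt $\operatorname{cov}(\hat f_k, y)/\operatorname{var}(y)$
because it is the unique linear allocation that (a) sums exactly to one and
(b) reduces to the classical index under independence. Each component then
absorbs its full row of covariances, including with the residual. Negative
indices are possible under correlation and are reported, not clipped; the
attribution rule is logged in every report.

Per-input totals $T_i$ sum the indices of every component whose variable
tuple contains input $i$ — a cooperative index counts fully toward both
(or all three) participants, so $\sum_i T_i$ can exceed $\sum_k S_k$.
Order totals partition $\sum_k S_k$ by interaction order.

### Network assembly

One model is fitted per node per experimental condition (each node in turn
as output). The network weight for input $\to$ output is the **maximum of
$T_{\text{input}}$ over conditions**, and edges are called where the weight
reaches a threshold $\tau$. Pairwise-comparison (inverse-FEOM) models
contribute only edges incident to their perturbed node. The default
$\tau = 0.1$ is an analysis parameter, not a constant of nature: it is
logged with every graph, and `edge_tau_profile()` exports the edge count
over a threshold grid so $\tau$ can be chosen empirically; edge sets are
nested in $\tau$ by construction. Directionality follows the regression
convention (rows of the weight matrix are outputs); `symmetrize_network()`
provides the undirected view for comparison with mutual-information
methods.

### FEOMs: forward prediction and inverse classification

The fitted expansion is a Fully Equivalent Operational Model: evaluated
forward it predicts a node from the rest of the network state
(`predict()`, `evaluate_prediction()`); fitted on a pairwise-comparison
table with the perturbed node's column replaced by 0/1 condition labels,
it is an *inverse* FEOM whose continuous output is thresholded at 0.5 to
classify the experimental condition of a sample (`classify_inverse()`).
Relative prediction errors are computed on the original measurement scale
with the observed value as denominator; observations equal to zero are
excluded from the tolerance fractions and counted separately. The 0.5
threshold is fixed by convention; an ROC export over thresholds is
provided as an extra.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `degrees` k / l / m | 3 / 2 / 1 | polynomial degree of first-order components and of each factor of second-/third-order products (dimensionless) |
| `alpha` | 0.01 | per-candidate F-test level for component inclusion |
| `max_order` | 2 | highest component order fitted |
| `policy` | hierarchical | candidate pool for orders ≥ 2 |
| `tau` | 0.1 | sensitivity-total threshold for edge calling |
| noise `scale` c | — | additive noise sd as a fraction of each node's sample sd; multiplicative noise sd as a fraction of the value |

The degree defaults follow the usual practice for this family of methods
(cubic independent effects, bilinear-to-biquadratic cooperative effects);
they are cheap to raise when the data supports it, and the rank-deficiency
check fails loudly when it does not.

## Normalization policy

Every node is linearly rescaled to $[0,1]$ by its training minimum and
maximum. The transform is **frozen from the training data**: test and
prediction inputs are mapped with the stored (min, max) and clamped to
$[0,1]$ with a warning, since the expansion is only defined on the sampled
range. Constant columns are rejected by name (a zero-variance input cannot
support a basis). Forward predictions are mapped back to the original
measurement scale through the stored output range.

## The synthetic benchmark

Real acceptance data for this method (multi-condition single-cell
cytometry panels) cannot be bundled, so the package ships a generator
whose presets define the study conditions used by the test suite:

* **additive** — five independent U(0,1) inputs; output
  $y = 0.5 + 1.0\,L_1(x_1) + 0.8\,L_1(x_2) + 0.6\,L_2(x_3) + \eta$ in the
  orthonormal Legendre basis; two inputs carry no signal. Output noise is
  10% of the signal sd here and below.
* **cooperative** — adds a dominant product term
  $0.5\,L_1(x_1)L_1(x_2)$ to first-order weights 1.0 / 0.7.
* **indirect-chain** — $x_2 = 0.15 + 0.7\,x_1 + N(0, 0.15^2)$ and
  $y = L_1(x_2) + \eta$: the source $x_1$ reaches the output only through
  the measured intermediate (correlation $\approx 0.8$). A `direct_link`
  switch adds a strong direct term $0.6\,L_1(x_1)$. The intermediate noise
  was chosen to keep the benchmark out of the near-collinear regime: at
  much higher source–intermediate correlation the variance inflation of
  the jointly fitted coefficients, not indirect leakage, dominates the
  source's total, and the benchmark would no longer measure what it
  claims.
* **perturbation-pair / perturbation-null** — a perturbed node $P$
  shifted by +2 between conditions, with a downstream reporter
  $D = 0.1 + 0.8\,P + N(0, 0.05^2)$ (pair) or $D$ driven by an unrelated
  node (null). The shift separates the reporter's class-conditional means
  by roughly 7 within-class standard deviations in the pair preset and by
  nothing in the null preset.

Because truths are expressed in the orthonormal Legendre basis under
independent uniform sampling, every term has unit variance and zero
cross-covariance, so `analytic_sensitivities()` returns exact indices
$w^2 / (\sum w^2 + \sigma_\eta^2)$ that serve as recovery oracles.

What the generator does **not** emulate: heavy-tailed and zero-inflated
fluorescence distributions, instrument compensation artifacts, biological
feedback (all presets are acyclic by construction), and time dependence.
Passing tests therefore demonstrate correctness of the estimator under its
own assumptions, not performance on any particular cytometry dataset.

## Numerical choices and degenerate inputs

* Population ($1/n$) variance convention everywhere; sums of indices are
  exact identities, not asymptotic ones.
* F tests guard the perfect-fit corner: once the model interpolates the
  data (relative residual below $10^{-12}$), further candidates are
  excluded rather than admitted with $p = 0/0$.
* Candidates whose terms are collinear with the current model are logged
  as untestable and excluded; a rank-deficient final design aborts with
  the collinear terms named.
* Ties in testing order are broken lexicographically by node name, making
  every fit bit-reproducible; `fit_all_nodes()` is invariant to column
  order.
* Degenerate tables fail early with the offending node named: empty
  files, non-numeric cells, duplicate node names, constant columns,
  splits leaving fewer than two rows.

## Problem sizes used by the tests

The test suite runs the benchmarks at $n$ between 400 and 5000 samples per
condition (20 seeds for index recovery, 10 seeds for the classification
and robustness protocols, 200 replicates at $n = 150$ for the type-I
calibration), sizes at which the Monte-Carlo error of the indices
(~$n^{-1/2}$) sits comfortably inside the asserted tolerances while the
whole suite stays fast enough to run habitually.

## Known limitations

* Covariance attribution is one defensible convention among several;
  strongly correlated inputs can make individual $S_k$ negative or
  larger than their independent-sampling values, and only their sum is
  invariant.
* The F-test controls per-candidate, not family-wise, error; with many
  nodes a small number of false edges at weights just above 0 is
  expected, which is why edge calling applies the τ threshold rather
  than significance alone.
* Single-time-point data cannot reveal feedback direction; edge
  directionality reflects the regression convention, not causality.
* Extrapolation outside the training range is clamped, so the FEOM is a
  surrogate only on the sampled domain.

## A worked example

```{r example, eval = FALSE}
spec <- make_benchmark_spec("cooperative", seed = 3)
d <- sample_synthetic(spec, 3000)
model <- fit_hdmr(d, "y", max_order = 2)
report <- compute_sensitivities(model, d)
tidy(report)
analytic_sensitivities(spec)$components
autoplot(report)
```

The README shows the numbers this prints and what they mean.
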