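# edgenull

Edge-centric functional-connectivity measures and their analytic
predictions under a static Gaussian null model.

## The problem

Edge-centric analyses of parcellated BOLD recordings unwrap the node
functional-connectivity (nFC) matrix into per-frame contributions: for
z-scored signals `z_i(t)` of `N` parcels, the edge time series of a pair
is `c_ij(t) = z_i(t) z_j(t)`, and from it one builds the edge FC (eFC,
the `E × E` similarity matrix over all `E = N(N−1)/2` edges), the RSS
(the per-frame cofluctuation amplitude, whose spikes are read as
"events"), binarised edge series, edge communities, and seed-based
coactivation (CAP) summaries. The question for anyone using these
measures is what they add beyond the static nFC. Under the *static
Gaussian null* — i.i.d. frames `Z(t) ~ N(0, R)` with `R` the observed
nFC, preserving all spatial and destroying all temporal correlation —
every one of them has a closed form in terms of `R`:

- **eFC**: `eFC_{jk,lm} = (r_jk r_lm + r_jl r_km + r_jm r_kl) /
  (sqrt(1 + 2 r_jk²) sqrt(1 + 2 r_lm²))`
- **RSS**: `RSS_all(t) = ‖z(t)‖²`, and `RSS/√2` is a generalised χ² — a
  sum of `N` independent `Gamma(1/2, √2 λ_i)` components, one per
  eigenvalue of `R`; mean `N/√2`, variance `Σ λ_i²`, with a
  subexponential (heavy) tail, so large "events" are expected under the
  null
- **binary edges**: Bernoulli with `p_jk = 1/2 + arcsin(r_jk)/π`
- **CAP frames**: `E[Z | Z_k = z*] = z* · R[, k]`, the scaled seed column
- **edge communities / node similarity**: predicted from the eFC closed
  form, with node distances `∝ (1 − r_ij)^{1/2}`

The package computes both sides — empirical measures from data, analytic
predictions from a correlation model — plus a Kolmogorov–Smirnov test of
empirical RSS series against the Gamma-mixture null and a fully seeded
surrogate generator (i.i.d. null and AR(1) contrast) so every prediction
is verifiable end to end on synthetic data. It is aimed at researchers
evaluating whether an edge-centric finding is genuinely dynamic or a
property of the static nFC.

## Worked example

```r
library(edgenull)

# a modular 50-node correlation model: blocks of 20/15/10/5 at rho = 0.5
model <- build_correlation(
  correlation_spec(50, "modular", module_sizes = c(20, 15, 10, 5),
                   rho_within = 0.5))
model
#> correlation_model: 50 nodes, kind: modular
#>   eigenvalues: [ 10.5 ... 0.5 ], sum = 50

# a null surrogate session: 1200 i.i.d. frames with covariance R
bold <- zscore_bold(sample_bold(surrogate_spec(model, 1200, seed = 7)))

# empirical vs predicted edge FC
pred <- predict_efc(model)
emp  <- edge_fc(edge_time_series(bold))
cor(emp$values[upper.tri(emp$values)], pred$values[upper.tri(pred$values)])
#> [1] 0.9637...

# the analytic RSS null and a significance test of the empirical series
d <- null_rss_distribution(model)
null_rss_moments(d)
#>      mean  variance
#>  35.35534 225.00000
ks_test_rss(rss(bold), d)
#> Kolmogorov-Smirnov test against the Gamma-mixture RSS null
#>   D = 0.038991, p = 0.05205, n = 1200 (upper_triangular RSS)
#>   reject at alpha = 0.05 : FALSE

# the hallmark event finding, reproduced by the null: the top-5% RSS
# frames reconstruct the nFC far better than the bottom-5%
frame_sorted_reconstruction(bold, model, fractions = 0.05)
#>   fraction  direction n_frames similarity
#> 1     0.05 descending       60  0.9404334
#> 2     0.05  ascending       60  0.3459650
```

The eFC agreement of 0.96 shows the fourth-order edge structure of this
session is almost entirely determined by its second-order nFC; the KS
test does not reject the static null for the RSS series (as it must
not, since the surrogate realises it); and the reconstruction table
shows that "high-amplitude events driving the nFC" arises in data with
no temporal structure at all. `kurtosis_ratio(bold)` (here 0.05) reports
the size of the norm approximation linking the published
upper-triangular RSS to the exact `‖z‖²` form.

A thin CLI over the same functions lives at `inst/cli/edgenull.R`
(subcommands `simulate`, `ets`, `efc`, `predict-efc`, `rss`, `rss-test`,
`communities`, `caps`, `report`), reading and writing tab-separated
matrices with YAML sidecar configs that make every run reproducible.

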