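# burstkit

Tools for inferring the kinetics of transcriptional bursting from single-cell
expression snapshots (single-cell qPCR, and count data more generally), for
researchers asking not just *whether* a gene's expression differs between cell
populations but *through which physical mechanism* — burst frequency or burst
magnitude.

## The model

Under the two-state (telegraph) promoter model a gene switches on at rate
K<sub>on</sub>, off at rate K<sub>off</sub>, and transcribes at rate
K<sub>t</sub> while on; all rates are normalised to the mRNA degradation rate.
The stationary mRNA count follows the beta-Poisson law

P(x) = [Γ(K<sub>on</sub>+x) Γ(K<sub>on</sub>+K<sub>off</sub>) K<sub>t</sub><sup>x</sup>] /
[Γ(x+1) Γ(K<sub>on</sub>+K<sub>off</sub>+x) Γ(K<sub>on</sub>)] ·
₁F₁(K<sub>on</sub>+x, K<sub>on</sub>+K<sub>off</sub>+x, −K<sub>t</sub>),

which burstkit evaluates in log space and precomputes over a parameter grid
(a lookup table), so the log-likelihood of a whole cell population is a single
matrix product with its count histogram. On top of this kernel the package
provides:

* **`ml_estimate()` / `estimate_kinetics()`** — grid maximum-likelihood
  estimation of (K<sub>on</sub>, K<sub>off</sub>, K<sub>t</sub>) per gene and
  population;
* **`ct_to_counts()`** — conversion of normalised qPCR Ct values to bounded
  count surrogates with a per-gene scale shared across populations;
* **`sabec()`** — Simulated Annealing for Bursty Expression Clustering:
  annealed iterative reassignment runs aggregated into a consensus matrix,
  with PAC / variation-of-information / corrected-Rand diagnostics, PAM
  consensus cuts and outlier pruning;
* **`epik()` / `epik_compare()`** — Estimation of Parameter changes in
  Kinetics: per gene and population pair, BIC scenario selection,
  marginal-probability scores and subsampling Kolmogorov–Smirnov statistics,
  combined into conservative intersection calls;
* **`generate_design_a/b/c()`, `gillespie_two_state()`** — the in-silico
  benchmark generators and an exact stochastic simulator used as an
  independent oracle for the analytic law;
* **`run_pipeline()`** — normalisation → estimation → clustering → pruning →
  differential-kinetics calls, driven by one config list (or YAML file), with
  a JSON manifest. A thin command-line front end ships in
  `inst/cli/burstkit.R`.

Everything user-facing takes and returns tidy data frames; fitted objects have
`tidy()` / `glance()` methods and `autoplot()` visualisations.

## A worked example

```r
library(burstkit)

tab <- build_lookup_table(
  grid_spec(seq(0.2, 5, 0.2), seq(0.4, 5, 0.4), seq(10, 200, 10), x_max = 250))

counts <- sample_stationary_counts(1.0, 2.0, 50, n = 5000, seed = 11)
glance(ml_estimate(counts, tab))
#> # A tibble: 1 × 7
#>    k_on k_off   k_t log_likelihood   row n_cells n_expressing
#>   <dbl> <dbl> <dbl>          <dbl> <int>   <int>        <int>
#> 1     1     2    50        -18842.  1045    5000         4801
```

The true parameters (1, 2, 50) are recovered exactly at this sample size. On a
simulated five-population dataset the consensus clustering recovers the
planted structure:

```r
ds <- generate_design_b(n_datasets = 1, seed = 42)[[1]]
sb <- sabec(ds$counts, k = 5, table = tab, runs = 15, seed = 1)
glance(sb)
#> # A tibble: 1 × 5
#>       k  runs   pac mean_iterations prop_converged
#>   <dbl> <int> <dbl>           <dbl>          <dbl>
#> 1     5    15 0.156             4.6              1
```

A PAC of 0.16 means under a sixth of cell pairs cluster ambiguously
across restarts; cutting the consensus into five clusters reproduces the true
population labels (corrected Rand = 1.0 on this dataset). See the vignette
(`vignettes/bursting-kinetics.Rmd`) for the model, the algorithms, parameter
meanings and the package's design decisions.

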