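# dpbmm

Model-based clustering of DNA methylation profiles with a **Dirichlet
process beta mixture model**.

Methylation arrays report a "beta value" per sample and CpG locus — the
fraction of methylated signal, bounded in (0, 1) and typically bimodal
(hypo- vs hypermethylated). Clustering tumour samples by these profiles is a
standard route to finding methylation subtypes, but Gaussian-mixture methods
(k-means, Euclidean hierarchical clustering) assume the wrong distribution,
and finite mixtures need the number of clusters fixed or selected by an
external criterion. `dpbmm` addresses both: each cluster models every locus
with its own beta distribution,

```
x_il | c_i = k  ~  Beta(alpha_kl, beta_kl),     alpha_kl, beta_kl >= 1,
```

and the per-cluster parameter vectors receive a Dirichlet process prior
DP(tau, G0), so the number of clusters K is inferred from the data. Because
G0 (zero-mean Gaussians on the unconstrained shapes, alpha = exp|L_alpha|)
is not conjugate to the beta likelihood, posterior sampling uses a "no-gaps"
Gibbs sampler: urn-weighted label updates with explicit fresh-component
draws, per-locus random-walk Metropolis updates of the shapes,
Dirichlet-sampled mixing proportions, and an auxiliary-variable gamma update
of the concentration tau. See `vignette("dpbmm-methods")` for the full
model, the sampler, and every default.

The package is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` / `autoplot()` on fits, and pipes end to end. It also ships

- preprocessing: detection p-value probe filtering, variance-based locus
  selection, boundary clipping;
- evaluation: BCubed precision / recall / F against reference labels;
- synthetic-data generators reproducing the benchmark designs;
- plain-text I/O (TSV/CSV matrices, JSON run manifests) and a thin CLI at
  `inst/scripts/dpbmm.R` with `simulate` / `run` / `evaluate` subcommands.

## Worked example

Simulate the four-cluster benchmark (100 samples x 200 loci, mixing
proportions 0.2 / 0.3 / 0.2 / 0.3), fit, and evaluate against the truth:

```r
library(dpbmm)

sim <- simulate_beta_mixture(seed = 1)

fit <- sim$data |>
  clip_beta_values() |>
  dpbmm(n_iter = 2000, burn_in = 300, seed = 1001)

fit
#> Dirichlet process beta mixture fit
#>   100 samples x 200 loci, 1700 kept iterations
#>   estimated clusters: 4
#>   estimated proportions: 0.26, 0.17, 0.24, 0.33
#>   posterior mean tau: 0.773; MH acceptance: 0.37

evaluate_clustering(truth = sim$labels$cluster,
                    predicted = fit$assignments$cluster)
#> # A tibble: 1 x 6
#>   precision recall f_measure k_true k_pred     n
#>       <dbl>  <dbl>     <dbl>  <int>  <int> <int>
#> 1         1      1         1      4      4   100
```

The fit recovers the number of clusters (4), the partition itself (BCubed
precision, recall and F all 1: every pair of samples is grouped exactly as
in the truth), and the realized mixing proportions — this seed drew labels
at frequencies 0.17 / 0.24 / 0.26 / 0.33, and the estimated cluster
fractions match them (in the fit's own cluster order). `autoplot(fit)` shows
the trace of K settling at 4
after burn-in; `plot_coclustering(fit)` shows four crisp posterior blocks.

On real arrays, run the preprocessing first:

```r
data <- read_beta_matrix("beta_values.tsv", orientation = "loci")
pv   <- read_beta_matrix("detection_pvalues.tsv", orientation = "loci")

fit <- data |>
  filter_detection_pvalues(pv) |>      # drop probes failing QC
  clip_beta_values() |>
  select_variable_loci(20) |>          # J most variable loci
  dpbmm(seed = 1)

tidy(fit)                              # sample_id, cluster, confidence
write_dpbmm_results(fit, "results/")
```

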