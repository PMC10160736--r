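# pbvoom

Differential expression for pseudo-bulk single-cell RNA-seq when
experimental groups are **heteroscedastic** — when some groups (say, healthy
controls) are biologically much less variable than others (say, patients).

## The problem

Pseudo-bulk analysis sums UMI counts over all cells of one type in each
sample and then applies bulk RNA-seq machinery. The standard *voom* pipeline
fits a gene-wise linear model E(y_g) = Xβ_g to log-CPM values y, plots
√(residual SD) against average log2 count, fits a single LOWESS trend lo(·)
through those points, and weights every observation by the inverse fourth
power of the predicted trend at its fitted log count:

    w_gi = lo(λ̂_gi)⁻⁴

A *single* trend assumes every group is equally variable. In real
pseudo-bulk data common biological coefficients of variation (BCV = √φ,
with φ the negative-binomial dispersion) routinely differ by group, and a
pooled trend then underestimates the variance of noisy groups (inflating
false discoveries in their comparisons) and overestimates the variance of
quiet groups (costing power). `pbvoom` provides two group-aware remedies:

* **voomByGroup** (`voom_by_group()`): subset the expression and the design
  to each group, fit a *group-specific* mean-variance trend, take
  `w_gic = lo_c(λ̂_gic)⁻⁴`, and assemble the per-group weights into one
  matrix `w#` used in the weighted linear-model fit. Groups with ≤ 2
  samples fall back to the overall trend (the `dynamic` option).
* **voomQWB** (`voom_qwb()`): keep the single trend but estimate one
  quality weight per *group block* under the model
  var(ε_gi) = σ_g² exp(γ_i), giving combined weights
  `w*_gi = w_gi / exp(γ̂_i)`.

Downstream, both feed the usual empirical-Bayes moderated t pipeline
(`de_test()`): gene-wise weighted least squares, variance squeezing toward a
scaled-F prior, moderated t-statistics and Benjamini–Hochberg adjusted
p-values.

The package also ships the validation apparatus: a correlated
negative-binomial single-cell simulator (gamma–Poisson with a Gaussian
copula inducing intra-subject correlation; `simulate_dataset()`,
`scenario_preset()`), group-wise common-BCV estimation by Cox–Reid adjusted
profile likelihood (`estimate_common_dispersion()`), an FDR/power benchmark
harness (`run_benchmark()`), and mean-variance / MDS diagnostics
(`plot_mean_variance()`, `plot_mds()`).

## Worked example

Simulate the heteroscedastic four-group study design (12 samples, 10,000
genes, 250 cells per sample, group BCV targets 0.20/0.22/0.26/0.28, 50
genes upregulated per group at log2FC 2), aggregate, filter, normalize, and
test the High-vs-High comparison with voomByGroup:

```r
library(pbvoom)

cfg <- scenario_preset("scenario1", seed = 42)
sim <- simulate_pseudobulk(cfg)
pb  <- sim$pb |> filter_genes(min_total = 30) |> tmm_norm_factors()
pb
#> pseudobulk: 6739 genes x 12 samples (g1 n=3, g2 n=3, g3 n=3, g4 n=3)

X   <- design_matrix(pb, ~ 0 + group)
fit <- voom_by_group(pb, X)
fit
#> pbvoom_fit (voomByGroup): 6739 genes x 12 samples
#> group BCV:
#>    g1    g2    g3    g4
#> 0.203 0.219 0.260 0.275

tab <- de_test(fit, "g4-g3")
tidy(tab)
#> # A tibble: 6,739 x 6
#>   gene     logFC AveExpr     t  P.Value     adj.P.Val
#> 1 gene3689  2.48   11.0   7.84 5.30e-13 0.00000000357
#> 2 gene2062  2.58    7.07  7.59 2.17e-12 0.00000000402
#> 3 gene1662 -2.48    8.52 -7.58 2.28e-12 0.00000000402
#> ...

length(decide_de(tab, 0.05))
#> [1] 57
```

The per-group BCV annotations (0.203–0.275) recover the simulated
variability ladder; the top genes' log-fold-changes sit near the true
value ±2; and 57 genes are called at a 5% adjusted-p cutoff out of the 100
truly differential in this comparison, essentially all of them true
positives (voomByGroup's mean FDR here stays near 0.02–0.06, where a
pooled-trend voom overshoots its nominal level).

`autoplot(fit)` overlays the four group trends with their BCVs;
`plot_mds(log_cpm(pb), pb$samples$group)` shows the sample layout.

A command-line wrapper covers the same pipeline from the shell:

```sh
Rscript inst/scripts/pbvoom.R de --counts pb.tsv --meta meta.tsv \
    --method voombygroup --contrast g4-g3 --plot combine --out results/
```

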