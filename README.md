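# liabilityscan

Genome-wide association analysis for binary disease traits with
**single-step genomic BLUP** (ssGBLUP) and a **threshold-liability sire
model** — the setting of dairy-cattle health traits such as clinical
mastitis, where the recorded animals (cows) are mostly ungenotyped and the
genotyped animals are their sires.

The package implements the full analysis chain as composable, pipe-friendly
functions plus one orchestrating pipeline:

1. **Relationship matrices.** Pedigree matrix **A** (tabular method, with
   inbreeding), its sparse inverse (Henderson rules, Meuwissen–Luo
   inbreeding), the genotyped block A22 by the indirect Colleau method, the
   expected-variance-weighted genomic matrix `G = Z D Z'` with
   `D_ii = 1 / (m · 2p_i(1−p_i))`, blending `G* = (1−α)G + αA22`, and the
   single-step inverse

   ```
   H⁻¹ = A⁻¹ + [ 0   0
                 0   G*⁻¹ − A22⁻¹ ]
   ```

2. **Threshold model.** `λ = Xβ + Z_h h + Z_s s + e` with the threshold
   fixed at 0 and residual variance fixed at 1, fitted by a compiled Gibbs
   sampler (truncated-normal data augmentation; blocked Gaussian location
   updates; scaled-inverse-chi-square variance updates using `s'H⁻¹s`).
   Liability-scale heritability is the sire-model form
   `h² = 4σ²_s / (σ²_s + σ²_h + σ²_e)`, computed per retained sample.

3. **Marker effects.** Back-solving `u = D Z' G*⁻¹ a_g` from the genomic
   breeding values of genotyped sires; iterative re-weighting of **G** by
   realized marker variances `2p(1−p)u²` (4 rounds by default); 10-adjacent-
   SNP window variance shares, normalized genome-wide to sum to 1, ranked
   into a top-10 table and a Manhattan plot.

4. **Synthetic data.** A daughter-design simulator (pedigree, gene-dropped
   genotypes with Poisson recombination, liability phenotypes) whose
   defaults encode the target study conditions: sire variance 0.037,
   herd-year variance 0.496, residual 1, incidence 10.91%, 29 autosomes.
   Every downstream stage is testable against this ground truth.

## Worked example

```r
library(liabilityscan)

cfg <- run_config(
  sim   = sim_config(n_founder_sires = 100, n_generations = 3,
                     daughters_per_sire = 10, n_chromosomes = 5,
                     markers_per_chromosome = 60, n_qtl = 20, n_herds = 100),
  gibbs = gibbs_config(n_iterations = 12000, burn_in = 2000, thin = 10),
  output_dir = "scan-out", seed = 11)
res <- run_pipeline(cfg)
```

```
[simulate] seed 11: generating pedigree, genotypes, phenotypes
[input] 6500 pedigree animals, 3000 phenotype records, 300 markers
[qc] 300 genotyped sires and 297 markers survive editing
[relmat] sire pedigree has 500 animals (300 genotyped)
[fit] posterior means: sigma2_s = 0.0590, sigma2_h = 0.6198, h2 = 0.1397
[snp_effects] 30 windows; top-10 windows absorb 47.09% of the variance
```

The fitted chain is a `threshold_fit` with broom-style methods:

```r
tidy(res$fit)
#> # A tibble: 4 × 5
#>   term       estimate std.error conf.low conf.high
#> 1 sigma2_s     0.0590    0.0294   0.0109     0.115
#> 2 sigma2_h     0.620     0.138    0.341      0.879
#> 3 sigma2_e     1         0        1          1
#> 4 h2           0.140     0.0668   0.0282     0.261
```

`sigma2_s` is the sire (transmitting-ability) variance on the liability
scale, `sigma2_h` the herd-year variance; the residual is fixed at 1 for
identifiability, and `h2` is the liability-scale heritability (posterior
mean of the per-sample ratio). The 95% bounds are highest-posterior-density
intervals. With only 3,000 binary records the intervals are wide — the truth
used by the simulator (0.037 and 0.496) is well inside both.

The window scan (here 30 windows of 10 SNPs):

```r
res$top_windows[1:3, c("window_id", "var_pct", "chromosome", "start_bp", "stop_bp")]
#>   window_id  var_pct chromosome start_bp  stop_bp
#> 1         5 5.555715          1 73908357 86718185
#> 2        26 5.396465          5 13699247 23510507
#> 3        30 5.137438          5 85503798 99688768
plot_manhattan(res$windows)   # shares on the y axis sum to 1
```

Every run writes `posterior_summary.tsv/.json`, `effects.tsv` (all
re-weighting rounds), `windows.tsv`, `top_windows.tsv`, `manhattan.tsv/.png`,
`qc_report.tsv` and a `manifest.json` with per-file checksums; two runs with
the same seed produce identical manifests. A thin command-line wrapper is
installed at `inst/cli/liabilityscan.R` for shell use with PLINK PED/MAP and
CSV inputs.

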