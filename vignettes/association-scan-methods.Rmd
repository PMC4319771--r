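---
title: "Single-step GWAS for a binary trait: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step GWAS for a binary trait: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabilityscan)
```

# The problem

Resistance to diseases such as clinical mastitis in dairy cattle is recorded
as a 0/1 outcome on cows, while the genotyped animals are mostly their sires.
Only a small fraction of the population is genotyped, heritability is low,
and the trait is highly polygenic. `liabilityscan` implements the analysis
chain that national dairy evaluations use for exactly this situation:

1. single-step genomic BLUP (ssGBLUP), which merges pedigree and genomic
   relationships into one matrix **H** so genotyped and ungenotyped animals
   are evaluated jointly;
2. a threshold-liability sire model fitted by Gibbs sampling, which maps the
   binary outcome onto a continuous latent liability;
3. back-solving of the sires' genomic breeding values into per-marker
   effects;
4. iterative re-weighting of the genomic relationship matrix by realized
   marker variances, which sharpens regions of genuine signal;
5. ranking of 10-adjacent-SNP windows by the share of genetic variance they
   absorb (the Manhattan-plot quantity).

A synthetic-data module generates pedigrees, linked genotypes and binary
phenotypes with the same statistical structure, so the entire pipeline is
testable without access to proprietary cow records.

# The threshold-liability sire model

Each record (a daughter's lactation) is modeled through an unobserved
liability

$$\lambda = X\beta + Z_h h + Z_s s + e,$$

where $\beta$ holds the overall mean and year-season effects (fixed),
$h \sim N(0, I\sigma^2_h)$ are herd-year effects,
$s \sim N(0, H\sigma^2_s)$ are sire (transmitting-ability) effects
correlated through the single-step relationship matrix **H**, and
$e \sim N(0, I\sigma^2_e)$. The observed outcome is
$y = \mathbf{1}[\lambda > t]$. Two constraints identify the latent scale:
the threshold is fixed at $t = 0$ and the residual variance at
$\sigma^2_e = 1$; every retained posterior sample carries
$\sigma^2_e = 1$ exactly.

Because records are on daughters but the genetic effect is the sire's, the
sire variance is one quarter of the additive genetic variance, and
liability-scale heritability is

$$h^2 = \frac{4\,\sigma^2_s}{\sigma^2_s + \sigma^2_h + \sigma^2_e}.$$

`heritability_from_components(0.037, 0.496, 1)` gives
`r round(heritability_from_components(0.037, 0.496, 1), 4)`. The package
computes $h^2$ per retained Gibbs sample, so the reported posterior mean is
the mean of the ratio, the Bayesian summary, rather than the ratio of
posterior means.

## Relationship matrices

The pedigree numerator relationship matrix **A** is built by the tabular
method (with inbreeding); its sparse inverse comes from Henderson's rules
with Mendelian-sampling variances $d_i = 0.5 - 0.25(F_s + F_d)$, with
inbreeding coefficients from the Meuwissen–Luo algorithm. For the genotyped
block, `pedigree_A_submatrix()` computes $A_{22}$ columns by the indirect
(Colleau) method — two linear passes through the pedigree per genotyped
animal — so the full dense **A** is never formed for large pedigrees.

The genomic matrix is the expected-variance-weighted form
$G = Z D Z'$, where $Z$ contains genotypes centered by allele frequency
(the $-1/0/1$ coding minus $2p-1$, equivalently $0/1/2$ minus $2p$) and the
first-iteration weights are the inverse expected marker variances

$$D_{ii} = \frac{1}{m \cdot 2 p_i (1 - p_i)},$$

read so that $\sum_i D_{ii}\, 2p_i(1-p_i) = 1$: this is the normalization
that puts the mean diagonal of **G** near 1 in an unrelated
Hardy–Weinberg base population, and it is preserved exactly at every
re-weighting round. Allele frequencies default to those observed in the
analyzed genotyped set — the package accepts external frequencies, and with
observed frequencies **G** is centered and therefore rank-deficient by one,
which is one of the reasons blending exists:

$$G^* = (1-\alpha)G + \alpha A_{22}, \qquad \alpha = 0.05 \text{ by default}.$$

The single-step inverse is then

$$H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{*-1} - A_{22}^{-1}\end{bmatrix},$$

with no extra scaling parameters on the correction block. Outside the
genotyped block, $H^{-1}$ is bit-identical to $A^{-1}$ (this is asserted in
the tests, not just documented).

## Gibbs sampler

Each sweep:

1. **Liabilities.** $\lambda_i \mid \cdot \sim N(\text{fitted}_i, 1)$
   truncated to $(0,\infty)$ if $y_i = 1$, to $(-\infty, 0]$ otherwise.
   Truncated draws use inverse-CDF sampling in the body of the distribution
   and Robert's exponential rejection in the far tail, so extreme fitted
   values do not degrade.
2. **Location effects**, in three Gaussian blocks: $\beta \mid h, s$ (its
   precision $X'X$ is constant and factorized once), $h \mid \beta, s$
   (precision is diagonal because each record maps to one herd-year), and
   $s \mid \beta, h$. The sire-block precision is
   $D_c + H^{-1}/\sigma^2_s$ with $D_c$ the diagonal of record counts. A
   one-off generalized eigendecomposition
   $L^{-1} D_c L^{-T} = Q \Lambda Q'$ (where $H^{-1} = LL'$) reduces each
   sire draw to two dense matrix–vector products, so the per-sweep cost does
   not involve re-factorizing the mixed-model equations as $\sigma^2_s$
   moves. Blocked conditional updates leave the stationary distribution
   unchanged relative to a joint location update; the small extra
   autocorrelation is the price of a per-sweep cost independent of the
   variance-component path. In a check mode used only by the tests, the
   liabilities can be declared observed (Gaussian data); the posterior
   means of all location effects then converge to the mixed-model-equation
   solutions, which the test suite verifies against an independent sparse
   solve.
3. **Variances.** Scaled-inverse-chi-square full conditionals:
   $\sigma^2_h \sim (h'h + \nu S)/\chi^2_{q_h+\nu}$ and
   $\sigma^2_s \sim (s'H^{-1}s + \nu S)/\chi^2_{q_s+\nu}$. The default prior
   is $\nu = -2$, $S = 0$ — improper flat priors on both variances — because
   the reference analysis names no priors; both are exposed in
   `gibbs_config()`.

Defaults are 120,000 iterations, 20,000 burn-in, thinning 10. The retained
count is exactly $\lfloor(\text{iters}-\text{burnin})/\text{thin}\rfloor$.
Posterior summaries report the mean, SD, 95% highest-density interval
(shortest interval over the sorted samples), a Geweke z-score and the
effective sample size; the spectral density at zero is estimated by an AR
fit, as is conventional for MCMC output analysis.

# Marker effects, re-weighting and windows

Genomic breeding values of the genotyped sires, $a_g$ (posterior means of
their $s$ solutions), are back-solved into marker effects

$$u = D Z' G^{*-1} a_g.$$

The variance a marker absorbs is its realized variance
$r_i = 2p_i(1-p_i)u_i^2$. In later rounds the expected marker contributions
are replaced by realized ones — weights proportional to $u_i^2$, rescaled to
keep $\sum_i D_{ii} 2p_i(1-p_i) = 1$ — **G** is rebuilt and re-blended, and
$u$ is re-solved with $a_g$ held fixed. Four rounds is the default
stabilization point. Two numerical details:

* the printed re-weighting rule involves an arbitrary global constant;
  because window *shares* are invariant to any global rescaling of the
  weights (and to the scale of $a_g$ — both properties are tested), the
  normalization above is the one safe choice that also keeps **G**'s scale
  stable across rounds;
* weights are floored at $10^{-8}$ times the mean raw weight before
  rescaling, because re-weighting shrinks most markers toward zero and an
  exactly-zero weight row would make the re-weighted **G** singular.

Windows are consecutive, non-overlapping blocks of 10 adjacent SNPs within
each chromosome (final partial block retained); window variance is
$\sum_{i \in w} r_i$ and shares are normalized genome-wide to sum to 1 — the
Manhattan y-axis contract, asserted at $10^{-10}$. Non-overlapping tiling is
the default because the reported window indices of the reference analysis
(maximum ID ≈ number of SNPs / 10) are only consistent with tiling; an
overlapping step-1 sliding mode is available behind a flag for comparison.
Ties in the top-window ranking break by ascending chromosome then start
position. Base-pair coordinates are 1-based inclusive throughout.

The top-10 share is reported at every round rather than only at round 4:
whether a reference top-share used round-4 effects is not recoverable, and
reporting the trajectory costs nothing.

# The synthetic population

`sim_config()` defaults encode the study conditions the analysis targets:
liability-scale sire variance 0.037, herd-year variance 0.496, residual 1,
disease incidence 10.91%, 29 autosomes, and a daughter design with ~10
recorded daughters per sire. Sizes (founder sires, generations, markers per
chromosome, herd-year and year-season class counts) are configuration,
because the source population's empirical distributions beyond those totals
are not published.

Design choices, in the order they matter:

* **The generative model is the sire model.** A daughter's liability is
  year-season + herd-year + half her sire's breeding value + $N(0, 1)$. The
  daughter's own Mendelian deviation is not added separately — it is part of
  the sire-model residual, whose total is fixed at 1. Daughter genotypes are
  still gene-dropped (they exercise QC and relationship code); sire breeding
  values are QTL effects carried by the simulated genotypes plus a polygenic
  remainder dropped through the pedigree, so marker signal and $a_g$ are
  mutually consistent.
* **Recombination**: crossover counts per chromosome are Poisson with mean
  equal to the genetic length (1 Morgan default), positions uniform, no
  interference — implemented as a Poisson process along the marker map, so
  gene dropping vectorizes over thousands of animals.
* **Dams** are unique founders (field daughters of AI sires rarely share
  dams); this keeps inbreeding essentially zero and the sire pedigree
  shallow, matching the data structure the sire model assumes.
* **Threshold calibration is analytic, not empirical.** The threshold is the
  $(1-\text{incidence})$ quantile of the analytic marginal liability:
  year-season effects are fixed effects, so the marginal is an equal-weight
  normal mixture over year-season classes (solved by `uniroot`), with the
  herd-year, sire and residual components entering through their variances.
  Class effects are drawn normal and standardized to exact mean 0 and exact
  target variance — with few classes, raw draws would make the realized
  marginal variance lumpy and the incidence an artifact of the class draw
  rather than a parameter. With 200,000 records the empirical incidence
  lands within two binomial standard errors (±0.14 percentage points) of
  10.91%.
* Missingness is a uniform dropout (default 0) — enough to exercise the
  call-rate edits, with no attempt at platform-specific missingness.

What the simulator does **not** emulate: linkage-disequilibrium patterns of
a real 50k chip, selection or assortative mating, pathogen exposure
heterogeneity, herd-size and daughter-count distributions of field data.
Passing tests therefore demonstrate that the *algorithms* are correct under
the model's own assumptions, not that the model captures every feature of
field mastitis records.

# Editing rules

Defaults: markers and genotyped individuals with call rate below 99% are
removed, then monomorphic markers and markers with minor allele frequency
below 0.05, then non-autosomal markers (labels 1–29); genotyped sires keep
their genotype only with at least 5 phenotyped daughters (they always remain
in the pedigree). "Below" is strict — MAF exactly 0.05 and exactly 5
daughters survive. Frequencies are computed after the individual call-rate
edit, so they reflect the analyzed set; the source text does not fix this
order, so it is documented here and reported in the `QcReport` rather than
inferred. Missing genotypes are mean-imputed (to $2p$) for matrix building
only and never written back to files.

# Problem sizes and runtime choices

The package's own test and verification runs use deliberately scaled
problems: parameter-recovery replicates simulate 3,000 daughters of 300
sires and run 12,000-iteration chains (the posterior for a sire variance of
0.037 is already well formed there, and 20 replicates complete in a few
minutes); the incidence calibration uses the full 200,000 records because it
is cheap; window and matrix identities run on hundreds of markers because
they are exact at any size. The Gibbs core is compiled (RcppArmadillo), so
chain cost is dominated by truncated-normal draws ($O(n)$ per sweep) and two
dense matrix–vector products in the sire block.

# Known limitations

* Single-trait only; no threshold–linear multi-trait extension.
* No REML alternative; variance components come from the Gibbs chain.
* No metafounders, unknown-parent groups, or APY-style sparse $G^{-1}$
  approximations — pedigrees are assumed complete back to founders.
* The sire-block eigendecomposition is dense, sized by the number of
  pedigree animals carrying the genetic effect; it is a one-off cost but
  would need replacing by sparse factor updates beyond a few tens of
  thousands of sires.
* Windows rank variance shares only; no significance testing is attached,
  by design.
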