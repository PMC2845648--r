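---
title: "Relating population differentiation to local recombination rate: methods"
author: "recfst developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating population differentiation to local recombination rate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recfst)
```

# The scientific question

Natural selection leaves a footprint on linked neutral variation: both
hitchhiking around positively selected alleles and background selection
against deleterious alleles perturb allele frequencies over distances that
shrink as the local recombination rate grows. If selection has shaped
allele-frequency differentiation between human populations, SNPs in
low-recombination regions should on average show higher FST than SNPs in
high-recombination regions — and, unlike the analogous diversity–recombination
correlation, an FST–recombination correlation cannot be produced by the
mutagenic effect of recombination itself.

`recfst` implements the full analysis needed to test this on genome-wide SNP
panels: windowed recombination-rate annotation from a genetic map, FST
estimation, equal-occupancy binning with regression/correlation statistics,
and a moving-block-bootstrap (MBB) inference layer that makes the hypothesis
tests honest in the presence of linkage disequilibrium (LD).

# Model and procedure

## Recombination-rate annotation

For each SNP, the rate is the genetic length of a window of $W$ bp (default
$W = 3$ Mb) centered on the SNP, in cM/Mb:
$$\rho = \frac{g(\mathrm{pos} + W/2) - g(\mathrm{pos} - W/2)}{W / 10^6},$$
where $g(\cdot)$ linearly interpolates the cumulative genetic position between
the flanking map markers. A SNP is discarded when its window (i) starts
before the chromosome start, (ii) overlaps a centromere, or (iii) overlaps a
telomere; we additionally discard windows that run past the chromosome end or
outside the marker span (`map_span` — the map supports no extrapolation), and
an optional `extend_mask` (5 Mb in the cautious variant) drops windows coming
within that distance of a centromere or telomere. Filters are applied in a
fixed order and the first failing filter is recorded, so annotation is
deterministic and idempotent. For odd $W$ the start offset rounds down and
the end offset up, keeping the window length exactly $W$.

## FST estimation

For one population pair with sample frequencies $\hat p_i = a_i/n_i$:
$$N = (\hat p_1 - \hat p_2)^2
      - \frac{\hat p_1(1 - \hat p_1)}{n_1 - 1}
      - \frac{\hat p_2(1 - \hat p_2)}{n_2 - 1}, \qquad
  D = \hat p_1(1 - \hat p_2) + \hat p_2(1 - \hat p_1).$$
$N$ is unbiased for the squared true frequency difference; the sampling
correction uses $n - 1$ (flagged open question in the source lineage; the
$n-1$ form is adopted and the near-equality with Weir–Cockerham is enforced
as a test). A set of SNPs is summarized ratio-of-sums,
$F_{ST} = \sum N / \sum D$, which is order-invariant and tames small-$D$
noise; algebraically $N \le D$ always, so $F_{ST} \le 1$. Global
differentiation is the unweighted mean of the pairwise ratio-of-sums values
over all population pairs. For unbinned ("single-SNP") analyses the per-SNP
global value is the mean of the defined pairwise $N/D$; SNPs with all pairs
undefined are dropped. The Weir–Cockerham (1984) estimator, in its
allele-count (haploid-sampling) ANOVA form, is provided purely as an
independent cross-check.

## Binning and regression

SNPs are sorted by $(\rho,\ \mathrm{chrom},\ \mathrm{pos})$ — coordinates
break ties deterministically — and split into $K$ equal-occupancy bins
(default $K = 10$; sizes differ by at most 1, larger bins first). Each bin
contributes one point: $x$ = median $\rho$ of its SNPs (midpoint convention
for even counts), $y$ = its FST. The bin-level fit is unweighted OLS
$F_{ST} = b_0 + b_1\rho$ (optionally $+\,b_2\rho^2$), with the Pearson
correlation $r$, the OLS t-statistic for $b_1$ (df $K - 2$), and the
normalized slope $b_1/b_0$ — the proportional change in FST per cM/Mb, which
is comparable across analyses whose baseline FST differs. Per-bin standard
errors are *not* used as regression weights: uncertainty is carried by the
bootstrap, not by weighting. The naive correlation p-value
($t = r\sqrt{K-2}/\sqrt{1-r^2}$) and the naive single-SNP p-values ignore
LD by construction; they are reported because genome-scale analyses
conventionally print them, with the MBB framework as the calibrated
alternative. P-values below $10^{-12}$ render as `<<10^-12` in text output.

## Moving-block-bootstrap inference

Neighbouring SNPs are correlated through LD, so an iid bootstrap understates
uncertainty. The MBB resamples contiguous runs of $L$ SNPs (genomic order,
overlapping non-circular blocks, $\lceil n/L \rceil$ blocks concatenated and
truncated to $n$). Within each of $B$ replicates (default $B = 1000$), the
resampled SNPs are regrouped by their *original* bin assignment (bin
membership is fixed; the per-bin median $\rho$ is recomputed from the
resampled SNPs — the source procedure is ambiguous on this point and this
reading is flagged), per-bin FST is recomputed, the regression is refit, and
$b_0, b_1\,(b_2), r, t, b_1/b_0$ are recorded. Statistics are summarized by
their mean and SD over replicates; the SD is the standard error used in
two-sided z-tests ($z = \mathrm{mean}/\mathrm{se}$) and in between-analysis
comparisons ($z = (\mathrm{mean}_A - \mathrm{mean}_B)/\sqrt{se_A^2 + se_B^2}$:
one-sided for coding vs non-coding contrasts, two-sided between population
pairs).

Design choices here:

* **Block length $L$** is not stated in the source procedure. Default
  $L = 200$ SNPs: at Perlegen-like density (~2.6 kb/SNP) this spans ~0.5 Mb,
  beyond typical LD range. Sensitivity to $L$ is part of the test surface
  (the $L = 200$ vs $L = 1$ SE inequality and the SE/empirical-SD
  calibration below).
* **Replicates with an empty bin** are rejected and redrawn (logged); more
  than 10% rejections is a hard error rather than a silent bias.
* **Degenerate replicates** in which every bin median of $\rho$ coincides
  get a flat fit ($b_1 = r = t = 0$) by convention, so a dataset of
  identical SNPs yields zero spread rather than an error. User-facing
  `fit_linear()` still treats constant $x$ as an error.
* **RNG**: a single user seed spawns one L'Ecuyer-CMRG substream per
  replicate, so the whole pipeline is deterministic given (seed, $B$, $L$)
  and replicates could be parallelized without changing results.
* **Per-replicate t reference**: the OLS t-statistic is recorded as a plain
  number; only its mean and SD across replicates enter the z-test, so the
  choice of a t vs normal reference for a single replicate is immaterial.

# The synthetic-data generator

Real inputs at the scale of the original analyses (a pedigree genetic map
plus >10^6 uniformly-ascertained genotyped SNPs) are not shippable, so the
package carries a generator whose statistical structure makes the planted
truth analytically recoverable.

* **Genetic map.** Markers every 50–500 kb. The interval rate is a regional
  lognormal component (constant over 2.5 Mb stretches, log-SD 0.55) times
  fine-scale lognormal noise (log-SD 0.325), with the log-location offset by
  $-0.325^2/2$ so that 3 Mb window rates come out with median ≈ 1.2–1.3 and
  mean ≈ 1.4–1.5 cM/Mb — matching the genome-wide window-rate distribution
  of human pedigree maps — and a realistic 5–95% spread of roughly 0.6–3
  cM/Mb. The regional component matters: with iid interval rates, 3 Mb
  windows average the noise away and the binned regression has almost no
  x-range to work with.
* **Allele frequencies.** Balding–Nichols: each SNP draws an ancestral
  frequency $p \sim U(0.05, 0.95)$; each population independently draws a
  frequency from a Beta with mean $p$ and variance $c(\rho)\,p(1-p)$. Under
  this model the expected pairwise ratio-of-sums FST equals the drift $c$,
  so planting $c(\rho) = a + b\rho + q\rho^2$ (clamped to [0.001, 0.99])
  gives exact recovery targets. The default planted line
  $c(\rho) = 0.128 - 0.005\rho$ uses the magnitudes of the fitted
  genome-wide relation, so recovery tests probe realistic effect sizes.
* **LD surrogate.** Within blocks of 50 consecutive SNPs, each population's
  standardized frequency deviations share a latent Gaussian factor with
  mixing weight $\lambda = 0.8$ (a Gaussian copula over the Beta marginals;
  populations stay independent, so FST is unaffected). This is not
  haplotype copying — it delivers exactly the one property the MBB needs,
  positive short-range correlation of per-SNP statistics, with analytic
  control.
* **Counts** are binomial given the frequency and the population's
  chromosome count (default 100, i.e. 50 diploid samples); ~2% of each
  chromosome is covered by simulated 1.5 kb exons for the coding flag.

## What a green test does and does not establish

The generator emulates: heterogeneous window rates with the right
distribution, centromere/telomere filtering, block LD, a planted
FST–recombination relationship, coding/MAF strata. It does **not** emulate:
ascertainment schemes, admixture (African-American-style samples),
demography, haplotype structure, or selection at the haplotype level. Green
recovery tests therefore establish that the *pipeline* measures what it
claims on data satisfying its assumptions — not that any biological claim
about real populations is reproduced.

## Genome size in the validation studies

The calibration and recovery suites simulate ten 50 Mb chromosomes
(~200 independent rate regions). At desk scale this matters: with only two
chromosomes (~40 regions) the bin-median regression acquires a
map-conditional bias — conditional on a lumpy realized $\rho$ field,
within-bin mean and median $\rho$ diverge differentially across bins and the
fitted slope is biased for that map — which the bootstrap, which conditions
on the map as the real analysis does, rightly does not count as noise. With
~200 regions the recovered slope is unbiased (pilot: mean $b_1 = -0.0054$
for planted $-0.005$) and the MBB SE is mildly conservative relative to the
across-panel SD (ratio ≈ 0.85–1.1), which is what the calibration criteria
check. The CLI default of two chromosomes is kept for cheap smoke runs.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| $W$ | 3,000,000 | bp | window for rate estimation; 1 and 5 Mb variants |
| `extend_mask` | 0 | bp | 5 Mb variant for cautious centromere/telomere masking |
| $K$ | 10 | bins | source analysis default; 40-bin variant supported |
| $B$ | 1,000 | replicates | bootstrap default; validation suites use 200 to fit budgets |
| $L$ | 200 | SNPs | ~0.5 Mb at Perlegen density, beyond LD range |
| $\lambda$ | 0.8 | – | latent-factor LD strength in the generator |
| LD block | 50 | SNPs | generator block length (~LD scale at 2.6 kb/SNP) |
| $c(\rho)$ | $0.128 - 0.005\rho$ | – | planted drift, magnitudes of the fitted genome-wide relation |

# Numerical and degenerate-input conventions

* Genetic maps reject decreasing cumulative positions (hard error naming the
  marker); no extrapolation outside the marker span.
* BED inputs (0-based half-open) are converted to 1-based closed intervals
  on read; all internal coordinates are 1-based.
* `fst_ratio_of_sums` errors when $\sum D = 0$ ("no informative SNPs");
  per-SNP FST is `NA` (a value, not an error) when $D = 0$; monomorphic
  SNPs contribute (0, 0) and stay in the table so bin occupancy is stable.
* Equal-occupancy binning breaks rho ties by genomic position; remainder
  SNPs go to the lowest-index bins.
* `correlation_significance` returns $p = 0$ with a degeneracy flag at
  $|r| = 1$; `fit_linear` flags constant-$y$ fits and errors on constant
  $x$.
* MAF is the pooled alternate-allele frequency over all populations, folded
  to $[0, 0.5]$; MAF categories are left-open/right-closed with 0.125,
  0.25, 0.375, 0.5 edges, so MAF = 0.125 falls in category A.
* Chromosome X can be analyzed as an ordinary chromosome with its own map;
  the pipeline accepts whatever chromosome counts the input states (no
  dosage adjustment).

# Known limitations

* The MBB conditions on the observed map and SNP positions; uncertainty in
  the genetic map itself is not propagated.
* The comparison z-tests assume the two analyses are independent; coding and
  non-coding subsets of one panel are only approximately so.
* The generator's LD is block-structured with a hard boundary; real LD
  decays smoothly, so the $L$-sensitivity of the MBB SE is cleaner in
  simulation than it would be on real data.
* Multi-allelic sites, haplotype statistics and ascertainment modelling are
  out of scope.
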