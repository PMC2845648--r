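# recfst

Tools for asking whether allele-frequency differentiation between
populations (FST) depends on the local recombination rate — the genomic
signature expected if hitchhiking and background selection have shaped
between-population differentiation, and one that the mutagenic effect of
recombination cannot mimic.

The package is aimed at population geneticists with genome-wide SNP allele
counts for two or more populations, a marker genetic map, and chromosome
structure annotations (centromeres/telomeres). It provides:

* **Recombination annotation** (`read_genetic_map`, `annotate_snps`): the
  rate around a SNP is the interpolated genetic length of a *W* = 3 Mb
  window centered on it, in cM/Mb, with validity filters (window before the
  chromosome start, centromere/telomere overlap, map span, optional 5 Mb
  extended masking).
* **FST estimation** (`pair_fst_components`, `fst_ratio_of_sums`,
  `global_fst`, `weir_cockerham_fst`): per-SNP variance-corrected components
  `N = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
  `D = p1(1-p2) + p2(1-p1)`, aggregated ratio-of-sums; global FST is the
  mean over population pairs; Weir–Cockerham provided as a cross-check.
* **Binned statistics** (`make_bins`, `bin_fst_profile`, `fit_linear`,
  `fit_quadratic`, `single_snp_analysis`): K equal-occupancy bins by rate,
  regression `FST = b0 + b1*rho` (+ `b2*rho^2`) over (median rho, bin FST)
  points, correlation `r`, OLS `t`, normalized slope `b1/b0`.
* **Moving-block-bootstrap inference** (`bootstrap_framework`, `z_test`,
  `compare_analyses`): B resamples of contiguous SNP runs (block length L,
  default 200 SNPs) so standard errors respect linkage disequilibrium;
  two-sided z-tests per statistic and one/two-sided comparisons between
  analyses (coding vs non-coding SNPs, population pair vs pair).
* **A synthetic-data generator** (`simulate_genetic_map`,
  `simulate_snp_panel`, `write_fixture`): Balding–Nichols panels whose
  per-locus drift follows a planted function `c(rho)` — so the expected FST
  profile is known exactly — with block-structured LD, written in the exact
  input formats the pipeline reads.
* **An orchestrator and CLI** (`run_analysis`, `recfst_cli`; subcommands
  `simulate`, `annotate`, `analyze`, `compare`).

## Worked example

Simulate a ten-chromosome panel with a planted relationship
`c(rho) = 0.128 - 0.005 rho` (the magnitudes of the fitted genome-wide
relation in human data), annotate, bin, and run the bootstrap framework:

```r
library(recfst)
lens <- setNames(rep(5e7, 10), paste0("chr", 1:10))
sm  <- simulate_genetic_map(lens, seed = 42)
sp  <- simulate_snp_panel(sm$map, sm$structure, n_snps = 50000,
                          drift = planted_drift(0.128, -0.005), seed = 43)
ann <- annotate_snps(sp$panel, sm$map, sm$structure, W = 3e6)
pan <- ann$panel

global_fst(pan)
#> [1] 0.1160832

sch  <- make_bins(pan$snps$rho, 10, pan$snps$chrom, pan$snps$pos)
prof <- bin_fst_profile(pan, sch)
fit_linear(prof$rho_median, prof$fst)
#> FST ~ rho regression:
#>   b0 = 0.124046  b1 = -0.00543754
#>   r = -0.5772  t(b1) = -1.999 (df 8)  b1/b0 = -0.043835

bs <- bootstrap_framework(pan, sch, B = 200, L = 200, seed = 7)
g  <- bs$series$global
round(c(b0 = g$mean[["b0"]], se0 = g$se[["b0"]],
        b1 = g$mean[["b1"]], se1 = g$se[["b1"]]), 4)
#>      b0     se0      b1     se1
#>  0.1242  0.0066 -0.0057  0.0041
bootstrap_z(bs, "global", "b1")$p
#> [1] 0.1615434
```

Reading the output: the binned profile recovers the planted slope
(−0.0057 ± 0.0041 vs −0.005 planted; the intercept 0.124 vs 0.128), and the
bootstrap standard error honestly reflects the strong simulated LD — at 50k
SNPs a single desk-scale panel does *not* reach significance, which is
exactly why the original genome-wide analyses needed >10^6 SNPs. The
published hypothesis tests themselves are reproduced from their printed
summaries:

```r
# slope of the genome-wide regression, -0.0049 +/- 0.0007 over 1,000 MBB
# replicates -> two-sided z-test
z_test(-0.0049, 0.0007)$p
#> [1] 2.559625e-12
```

A command-line round trip:

```sh
inst/cli/recfst simulate --chroms 2 --length-mb 50 --n-snps 20000 \
    --pops 3 --planted 0.128,-0.005,0 --seed 1 --out fixture/
inst/cli/recfst analyze --dir fixture/ --bins 10 --bootstraps 1000 \
    --block-len 200 --seed 2 --out report/
```

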