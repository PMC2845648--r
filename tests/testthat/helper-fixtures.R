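# In-code fixtures shared across test files. Everything is generated at test
# time; nothing binary is stored.

# A toy one-chromosome map: markers every 0.5 Mb at a constant 1 cM/Mb
toy_map <- function(chrom = "chr1", len = 2e7, rate = 1) {
  pos <- seq(1, len, by = 5e5)
  genetic_map(rep(chrom, length(pos)), pos, (pos - 1) / 1e6 * rate)
}

toy_structure <- function(chrom = "chr1", len = 2e7,
                          cen = c(9e6, 9.5e6), tel_bp = 5e5) {
  chromosome_structure(
    stats::setNames(len, chrom),
    centromeres = data.frame(chrom = chrom, start = cen[1], end = cen[2]),
    telomeres = data.frame(chrom = rep(chrom, 2),
                           start = c(1, len - tel_bp + 1),
                           end = c(tel_bp, len)))
}

# A panel built directly from allele-count matrices (no map needed)
toy_panel <- function(alt, nchr, chrom = "chr1", pos = NULL, rho = NULL,
                      coding = FALSE) {
  n <- nrow(alt)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  snps <- data.frame(id = paste0("s", seq_len(n)), chrom = chrom, pos = pos,
                     coding = coding)
  if (!is.null(rho)) snps$rho <- rho
  snp_panel(snps, alt, nchr)
}

# Balding-Nichols panel with drift c(rho) and iid SNPs; rho supplied.
# Cheap generator used where the full map-based simulator is overkill.
bn_panel <- function(n_snps, c_of_rho, rho, pops = c("p1", "p2", "p3"),
                     n_chrom = 100, seed = 1) {
  set.seed(seed)
  p <- runif(n_snps, 0.05, 0.95)
  cc <- if (is.function(c_of_rho)) c_of_rho(rho) else rep(c_of_rho, n_snps)
  mult <- 1 / cc - 1
  alt <- sapply(seq_along(pops), function(k)
    rbinom(n_snps, n_chrom, rbeta(n_snps, p * mult, (1 - p) * mult)))
  colnames(alt) <- pops
  nchr <- matrix(n_chrom, n_snps, length(pops), dimnames = list(NULL, pops))
  toy_panel(alt, nchr, rho = rho)
}

# Full simulated dataset: map + structure + annotated panel, one call.
# Ten 50 Mb chromosomes give enough independent recombination-rate regions
# for bin-level regressions to be unbiased at desk scale (see the methods
# vignette).
sim_dataset <- function(n_snps = 20000, drift = planted_drift(0.128, -0.005),
                        seed = 1, lambda = 0.8, ld_block = 50,
                        pops = c("pop1", "pop2", "pop3"), n_chrom = 100,
                        lengths = stats::setNames(rep(5e7, 10),
                                                  paste0("chr", 1:10))) {
  sm <- simulate_genetic_map(lengths, seed = seed)
  sp <- simulate_snp_panel(sm$map, sm$structure, n_snps = n_snps,
                           drift = drift, pops = pops, n_chrom = n_chrom,
                           ld_block = ld_block, lambda = lambda,
                           seed = seed + 5e5)
  ann <- annotate_snps(sp$panel, sm$map, sm$structure)
  list(map = sm$map, structure = sm$structure, sim = sp, panel = ann$panel)
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
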