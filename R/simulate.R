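#' Simulate a marker genetic map and chromosome structure
#'
#' Markers are laid down with uniform spacing in \code{spacing_bp}. The
#' per-interval recombination rate is the product of a regional lognormal
#' component, constant over stretches of \code{region_bp} (recombination
#' rate in real genomes varies on the multi-megabase scale, which is what a
#' 3 Mb window rate picks up), and a fine-scale lognormal noise per marker
#' interval. With the default log-scale SDs (0.55 regional, 0.325 fine) and
#' \code{rate_meanlog = log(1.2) - 0.325^2/2} (the offset cancels the mean
#' inflation of the fine noise once windows average over it), 3 Mb window
#' rates come out with median ~1.2-1.3 cM/Mb and mean ~1.4-1.5 cM/Mb,
#' matching the genome-wide distribution in human pedigree maps, with
#' realistic heterogeneity at the window scale (5-95\% range roughly
#' 0.6-3 cM/Mb). Cumulative cM positions are the integral of the interval
#' rates. Each chromosome gets one centromere interval (centered at ~45\%
#' of its length) and one telomere interval at each end.
#'
#' @param lengths named numeric vector of chromosome lengths in bp
#'   (>= 10 Mb recommended); default two chromosomes of 50 Mb.
#' @param spacing_bp range of inter-marker spacing in bp (default 50-500 kb).
#' @param rate_meanlog log-scale location of the interval rate.
#' @param rate_sdlog_regional,rate_sdlog_fine log-scale SDs of the regional
#'   and fine-scale rate components. Set both to 0 for a constant-rate map.
#' @param region_bp length scale of regional rate variation (default
#'   2.5 Mb).
#' @param centromere_bp centromere interval width (default 3 Mb).
#' @param telomere_bp telomere interval width at each end (default 1 Mb).
#' @param seed integer seed.
#' @return list with \code{map} (a \code{\link{genetic_map}}) and
#'   \code{structure} (a \code{\link{chromosome_structure}}).
#' @export
simulate_genetic_map <- function(lengths = c(chr1 = 5e7, chr2 = 5e7),
                                 spacing_bp = c(5e4, 5e5),
                                 rate_meanlog = log(1.2) - 0.325^2 / 2,
                                 rate_sdlog_regional = 0.55,
                                 rate_sdlog_fine = 0.325,
                                 region_bp = 2.5e6,
                                 centromere_bp = 3e6, telomere_bp = 1e6,
                                 seed = 1) {
  set.seed(as.integer(seed))
  chrom <- character(0); pos <- numeric(0); cm <- numeric(0)
  for (ch in names(lengths)) {
    len <- lengths[[ch]]
    p <- 1
    ps <- p
    while (p < len) {
      p <- min(p + stats::runif(1, spacing_bp[1], spacing_bp[2]), len)
      ps <- c(ps, p)
    }
    region_log <- stats::rnorm(ceiling(len / region_bp), 0,
                               rate_sdlog_regional)
    mid <- (ps[-length(ps)] + ps[-1]) / 2
    rate <- exp(rate_meanlog + region_log[ceiling(mid / region_bp)] +
                  stats::rnorm(length(mid), 0, rate_sdlog_fine))
    g <- c(0, cumsum(rate * diff(ps) / 1e6))
    chrom <- c(chrom, rep(ch, length(ps)))
    pos <- c(pos, ps)
    cm <- c(cm, g)
  }
  cen_mid <- round(unlist(lengths) * 0.45)
  centromeres <- data.frame(chrom = names(lengths),
                            start = cen_mid - centromere_bp / 2,
                            end = cen_mid + centromere_bp / 2)
  telomeres <- data.frame(
    chrom = rep(names(lengths), each = 2),
    start = as.vector(rbind(1, unlist(lengths) - telomere_bp + 1)),
    end = as.vector(rbind(telomere_bp, unlist(lengths))))
  list(map = genetic_map(chrom, pos, cm),
       structure = chromosome_structure(unlist(lengths), centromeres,
                                        telomeres))
}

#' Planted drift function
#'
#' The per-locus Balding-Nichols drift parameter as a function of the local
#' recombination rate: \eqn{c(\rho) = a + b\rho + q\rho^2}, clamped to
#' [0.001, 0.99]. Since the expected pairwise FST under Balding-Nichols
#' equals the drift, planting a linear \code{c(rho)} with the magnitudes of
#' the fitted genome-wide relation (intercept ~0.128, slope ~-0.005 per
#' cM/Mb) gives analytically known recovery targets for the full pipeline.
#'
#' @param a intercept (dimensionless drift).
#' @param b slope per cM/Mb.
#' @param q quadratic coefficient per (cM/Mb)^2 (default 0).
#' @return function of rho returning the clamped drift.
#' @export
planted_drift <- function(a = 0.128, b = -0.005, q = 0) {
  force(a); force(b); force(q)
  function(rho) {
    c_rho <- a + b * rho + q * rho^2
    if (any(!is.finite(c_rho))) stop("drift function is not finite")
    pmin(pmax(c_rho, 0.001), 0.99)
  }
}

#' Simulate a multi-population SNP panel with a planted FST(rho) relationship
#'
#' SNP positions are drawn uniformly over the mappable part of each
#' chromosome (positions whose \code{W} window passes the validity filters).
#' Each SNP gets an ancestral frequency p uniform on \code{p_range}; each
#' population's frequency is Beta with mean p and variance
#' \eqn{c(\rho) p(1-p)} (the Balding-Nichols model), where rho is the SNP's
#' true window recombination rate on the simulated map. As an LD surrogate,
#' SNPs within blocks of \code{ld_block} consecutive SNPs share, per
#' population, a common latent Gaussian factor with mixing weight
#' \code{lambda} (correlation \code{lambda} between the frequency deviations
#' of SNPs in a block; populations remain independent). Allele counts are
#' binomial given the frequency and the population's chromosome count. A
#' fraction of SNPs is flagged coding via simulated exon intervals.
#'
#' @param map,structure from \code{\link{simulate_genetic_map}}.
#' @param n_snps number of SNPs to simulate.
#' @param drift a \code{\link{planted_drift}} function (or any function of
#'   rho returning values in (0, 1)).
#' @param pops character vector of population labels (default 3).
#' @param n_chrom chromosomes sampled per population (default 100; recycled).
#' @param ld_block LD block length in SNPs (default 50; 1 = no blocks).
#' @param lambda latent-factor mixing weight in [0, 1] (default 0.8).
#' @param p_range ancestral-frequency range (default [0.05, 0.95]).
#' @param coding_frac fraction of the genome covered by simulated coding
#'   exons (default 0.02).
#' @param W window length used for the true rho (default 3 Mb).
#' @param seed integer seed.
#' @return list with \code{panel} (a \code{\link{snp_panel}} whose snps
#'   carry \code{rho_true}), \code{exons} (data.frame chrom/start/end,
#'   1-based closed) and \code{truth} (the planted parameters).
#' @export
simulate_snp_panel <- function(map, structure, n_snps, drift = planted_drift(),
                               pops = c("pop1", "pop2", "pop3"),
                               n_chrom = 100, ld_block = 50, lambda = 0.8,
                               p_range = c(0.05, 0.95), coding_frac = 0.02,
                               W = 3e6, seed = 1) {
  stopifnot(ld_block >= 1, lambda >= 0, lambda <= 1, length(pops) >= 2)
  set.seed(as.integer(seed))
  n_chrom <- rep(as.integer(n_chrom), length.out = length(pops))
  chroms <- names(structure$lengths)

  # rejection-sample positions until n_snps pass the window filters
  acc_chrom <- character(0); acc_pos <- numeric(0)
  while (length(acc_pos) < n_snps) {
    need <- n_snps - length(acc_pos)
    draw <- ceiling(need * 1.6) + 100L
    ch <- sample(chroms, draw, replace = TRUE,
                 prob = structure$lengths / sum(structure$lengths))
    p <- floor(stats::runif(draw, 1, structure$lengths[ch] + 1))
    for (cc in unique(ch)) {
      i <- which(ch == cc)
      w <- window_recomb_rate(map, structure, cc, p[i], W = W)
      ok <- w$status == "ok"
      acc_chrom <- c(acc_chrom, rep(cc, sum(ok)))
      acc_pos <- c(acc_pos, p[i][ok])
    }
  }
  o <- order(acc_chrom, acc_pos)
  chrom <- acc_chrom[o][seq_len(n_snps)]
  pos <- acc_pos[o][seq_len(n_snps)]
  o <- order(chrom, pos)
  chrom <- chrom[o]; pos <- pos[o]

  rho <- numeric(n_snps)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    rho[i] <- window_recomb_rate(map, structure, cc, pos[i], W = W)$rho
  }
  c_rho <- drift(rho)
  if (any(c_rho <= 0 | c_rho >= 1)) stop("drift outside (0, 1)")
  p_anc <- stats::runif(n_snps, p_range[1], p_range[2])
  shape_mult <- 1 / c_rho - 1
  a_sh <- p_anc * shape_mult
  b_sh <- (1 - p_anc) * shape_mult

  # block ids: runs of ld_block consecutive SNPs within a chromosome
  block <- integer(n_snps)
  nb <- 0L
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    block[i] <- nb + (seq_along(i) - 1L) %/% ld_block + 1L
    nb <- max(block[i])
  }

  alt <- matrix(0L, n_snps, length(pops), dimnames = list(NULL, pops))
  nchr <- matrix(rep(n_chrom, each = n_snps), n_snps, length(pops),
                 dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    zb <- stats::rnorm(nb)
    z <- sqrt(lambda) * zb[block] + sqrt(1 - lambda) * stats::rnorm(n_snps)
    freq <- stats::qbeta(stats::pnorm(z), a_sh, b_sh)
    alt[, k] <- stats::rbinom(n_snps, n_chrom[k], freq)
  }

  # exon intervals covering ~coding_frac of each chromosome
  exon_bp <- 1500
  ex_chrom <- character(0); ex_start <- numeric(0)
  for (cc in chroms) {
    n_ex <- max(1L, round(coding_frac * structure$lengths[[cc]] / exon_bp))
    ex_chrom <- c(ex_chrom, rep(cc, n_ex))
    ex_start <- c(ex_start,
                  sort(floor(stats::runif(n_ex, 1,
                                          structure$lengths[[cc]] - exon_bp))))
  }
  exons <- data.frame(chrom = ex_chrom, start = ex_start,
                      end = ex_start + exon_bp - 1)
  coding <- rep(FALSE, n_snps)
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    e <- exons[exons$chrom == cc, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos[i], width = 1),
      IRanges::IRanges(start = e$start, end = e$end))
    coding[i[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }

  snps <- data.frame(id = paste0("snp", seq_len(n_snps)), chrom = chrom,
                     pos = pos, coding = coding, rho_true = rho,
                     stringsAsFactors = FALSE)
  truth <- list(drift = drift, lambda = lambda, ld_block = ld_block,
                n_chrom = n_chrom, p_range = p_range, seed = seed, W = W)
  list(panel = snp_panel(snps, alt, nchr), exons = exons, truth = truth)
}

#' Write a simulated data set as pipeline input files
#'
#' Writes the genetic map (TSV), chromosome lengths (TSV), centromere and
#' telomere BEDs, the allele-count table, the exon BED and a truth JSON, in
#' exactly the formats the pipeline readers accept; optionally also a VCF.
#' Files round-trip losslessly through the readers.
#'
#' @param sim_map result of \code{\link{simulate_genetic_map}}.
#' @param sim_panel result of \code{\link{simulate_snp_panel}}.
#' @param dir output directory (created if needed).
#' @param truth_params named list recorded in \code{truth.json} (e.g. the
#'   planted coefficients); stored as given.
#' @param vcf if \code{TRUE}, also write \code{panel.vcf} with diploid
#'   genotypes consistent with the allele counts, plus per-population sample
#'   lists.
#' @return named character vector of the written file paths, invisibly.
#' @export
write_fixture <- function(sim_map, sim_panel, dir, truth_params = list(),
                          vcf = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  map <- sim_map$map
  rows <- do.call(rbind, lapply(names(map$chroms), function(ch)
    data.frame(chrom = ch, pos = map$chroms[[ch]]$pos,
               cm = map$chroms[[ch]]$cm)))
  data.table::fwrite(rows, path("map.tsv"), sep = "\t")
  st <- sim_map$structure
  data.table::fwrite(data.frame(chrom = names(st$lengths),
                                length = unname(st$lengths)),
                     path("lengths.tsv"), sep = "\t")
  write_bed <- function(iv, f)
    data.table::fwrite(data.frame(chrom = iv$chrom, start = iv$start - 1,
                                  end = iv$end),
                       path(f), sep = "\t", col.names = FALSE)
  write_bed(st$centromeres, "centromeres.bed")
  write_bed(st$telomeres, "telomeres.bed")
  write_allele_counts(sim_panel$panel, path("counts.tsv"))
  write_bed(sim_panel$exons, "exons.bed")
  tr <- sim_panel$truth
  tr$drift <- NULL
  jsonlite::write_json(c(truth_params, tr), path("truth.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(map = path("map.tsv"), lengths = path("lengths.tsv"),
             centromeres = path("centromeres.bed"),
             telomeres = path("telomeres.bed"), counts = path("counts.tsv"),
             exons = path("exons.bed"), truth = path("truth.json"))
  if (vcf) {
    files <- c(files, vcf = write_fixture_vcf(sim_panel$panel, path))
  }
  invisible(files)
}

# Minimal VCF 4.2 writer: diploid genotypes consistent with the allele
# counts (alt alleles packed into the leading chromosomes of each sample).
write_fixture_vcf <- function(panel, path) {
  pops <- populations(panel)
  n_dip <- floor(panel$nchr[1, ] / 2)
  samples <- unlist(lapply(pops, function(p)
    paste0(p, "_s", seq_len(n_dip[[p]]))))
  for (p in pops)
    writeLines(paste0(p, "_s", seq_len(n_dip[[p]])),
               path(paste0("samples_", p, ".txt")))
  gt_row <- function(alt, nd) {
    a <- integer(2 * nd)
    a[seq_len(min(alt, 2 * nd))] <- 1L
    paste(a[seq(1, 2 * nd, 2)], a[seq(2, 2 * nd, 2)], sep = "/")
  }
  n <- nrow(panel$snps)
  body <- vapply(seq_len(n), function(i) {
    g <- unlist(lapply(pops, function(p) gt_row(panel$alt[i, p], n_dip[[p]])))
    paste(c(panel$snps$chrom[i], panel$snps$pos[i], panel$snps$id[i],
            "A", "G", ".", "PASS", ".", "GT", g), collapse = "\t")
  }, character(1))
  out <- path("panel.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               body), out)
  out
}

#' Read a simulated fixture directory
#'
#' @param dir a directory written by \code{\link{write_fixture}}.
#' @return list with \code{map}, \code{structure}, \code{panel},
#'   \code{exons} and \code{truth}.
#' @export
read_fixture <- function(dir) {
  path <- function(f) file.path(dir, f)
  list(map = read_genetic_map(path("map.tsv")),
       structure = read_chromosome_structure(path("lengths.tsv"),
                                             path("centromeres.bed"),
                                             path("telomeres.bed")),
       panel = read_allele_counts(path("counts.tsv")),
       exons = read_bed_intervals(path("exons.bed")),
       truth = jsonlite::read_json(path("truth.json"), simplifyVector = TRUE))
}
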