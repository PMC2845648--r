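#' SNP panel: positions and per-population allele counts
#'
#' The central data container: a table of biallelic SNPs with, for each
#' population, the alternate-allele count and the number of genotyped
#' chromosomes (which may vary by SNP when genotypes are missing).
#'
#' @param snps data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   and optionally \code{coding} (logical; default \code{FALSE}); further
#'   columns (e.g. \code{rho}) are carried along.
#' @param alt integer matrix (SNPs x populations) of alternate-allele counts;
#'   column names are the population labels.
#' @param nchr integer matrix of the same shape: genotyped chromosomes per
#'   SNP and population (>= 2 wherever the SNP enters an FST).
#' @return An object of class \code{snp_panel}, rows sorted in genomic order
#'   (chromosome, then position).
#' @export
snp_panel <- function(snps, alt, nchr) {
  stopifnot(is.data.frame(snps), is.matrix(alt), is.matrix(nchr),
            nrow(snps) == nrow(alt), all(dim(alt) == dim(nchr)))
  if (is.null(colnames(alt))) stop("alt matrix needs population column names")
  if (!all(c("id", "chrom", "pos") %in% names(snps)))
    stop("snps needs columns id, chrom, pos")
  if (any(alt < 0) || any(alt > nchr))
    stop("allele counts must satisfy 0 <= alt <= nchr")
  if (is.null(snps$coding)) snps$coding <- FALSE
  o <- order(snps$chrom, snps$pos)
  structure(list(snps = snps[o, , drop = FALSE],
                 alt = alt[o, , drop = FALSE],
                 nchr = nchr[o, , drop = FALSE]),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("snp_panel:", nrow(x$snps), "SNPs,", ncol(x$alt), "populations (",
      paste(colnames(x$alt), collapse = ", "), ")\n")
  cat("  chromosomes:", paste(unique(x$snps$chrom), collapse = ", "), "\n")
  if (!is.null(x$snps$rho))
    cat(sprintf("  rho: median %.3f cM/Mb\n", stats::median(x$snps$rho)))
  invisible(x)
}

#' Population labels of a panel
#' @param panel a \code{\link{snp_panel}}.
#' @return character vector of population labels.
#' @export
populations <- function(panel) colnames(panel$alt)

#' Subset a panel by SNP index
#' @param panel a \code{\link{snp_panel}}.
#' @param i integer or logical index over SNPs (rows kept in given order).
#' @return The subsetted \code{snp_panel}.
#' @export
subset_panel <- function(panel, i) {
  structure(list(snps = panel$snps[i, , drop = FALSE],
                 alt = panel$alt[i, , drop = FALSE],
                 nchr = panel$nchr[i, , drop = FALSE]),
            class = "snp_panel")
}

#' Panel-wide minor allele frequency
#'
#' MAF is the alternate-allele frequency pooled across all genotyped
#' chromosomes of all populations, folded to [0, 0.5].
#'
#' @param panel a \code{\link{snp_panel}}.
#' @return numeric vector of per-SNP MAF in [0, 0.5].
#' @export
panel_maf <- function(panel) {
  p <- rowSums(panel$alt) / rowSums(panel$nchr)
  pmin(p, 1 - p)
}

#' Read an allele-count table
#'
#' Long-format tab-separated table with header
#' (snp_id, chrom, pos, pop, n_chrom, alt_count, coding_flag); one row per
#' SNP and population.
#'
#' @param path file path.
#' @return A \code{\link{snp_panel}}.
#' @export
read_allele_counts <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("snp_id", "chrom", "pos", "pop", "n_chrom", "alt_count")
  if (!all(need %in% names(d)))
    stop("allele-count table must have columns ",
         paste(need, collapse = ", "))
  pops <- sort(unique(d$pop))
  d <- d[order(d$chrom, d$pos, d$pop), , drop = FALSE]
  key <- paste(d$chrom, d$pos, d$snp_id, sep = "\r")
  ukey <- unique(key)
  row <- match(key, ukey)
  col <- match(d$pop, pops)
  n <- length(ukey)
  alt <- matrix(NA_integer_, n, length(pops), dimnames = list(NULL, pops))
  nchr <- alt
  alt[cbind(row, col)] <- as.integer(d$alt_count)
  nchr[cbind(row, col)] <- as.integer(d$n_chrom)
  if (anyNA(alt) || anyNA(nchr))
    stop("allele-count table is not complete over all populations")
  first <- !duplicated(row)
  snps <- data.frame(id = d$snp_id[first], chrom = d$chrom[first],
                     pos = d$pos[first],
                     coding = if ("coding_flag" %in% names(d))
                       as.logical(d$coding_flag[first]) else FALSE,
                     stringsAsFactors = FALSE)
  snp_panel(snps, alt, nchr)
}

#' Write an allele-count table
#'
#' Inverse of \code{\link{read_allele_counts}}.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_allele_counts <- function(panel, path) {
  pops <- populations(panel)
  n <- nrow(panel$snps)
  d <- data.table::data.table(
    snp_id = rep(panel$snps$id, each = length(pops)),
    chrom = rep(panel$snps$chrom, each = length(pops)),
    pos = rep(panel$snps$pos, each = length(pops)),
    pop = rep(pops, n),
    n_chrom = as.integer(t(panel$nchr)),
    alt_count = as.integer(t(panel$alt)),
    coding_flag = rep(as.integer(panel$snps$coding), each = length(pops)))
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' Per-population allele counts from a VCF
#'
#' Reads biallelic SNVs from a VCF and derives per-population alternate
#' allele counts from the genotypes; missing alleles are excluded from the
#' genotyped-chromosome count. Requires the \pkg{VariantAnnotation} package.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param pop_samples named list: population label -> character vector of
#'   sample names in the VCF.
#' @return A \code{\link{snp_panel}}.
#' @export
read_vcf_counts <- function(vcf_path, pop_samples) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_counts requires the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(vcf_path)
  keep <- VariantAnnotation::isSNV(v, singleAltOnly = TRUE)
  v <- v[keep]
  gt <- VariantAnnotation::geno(v)$GT
  rr <- SummarizedExperiment::rowRanges(v)
  pops <- names(pop_samples)
  n <- nrow(gt)
  alt <- matrix(0L, n, length(pops), dimnames = list(NULL, pops))
  nchr <- alt
  for (k in seq_along(pops)) {
    cols <- match(pop_samples[[k]], colnames(gt))
    if (anyNA(cols)) stop("samples missing from VCF: ",
                          paste(pop_samples[[k]][is.na(cols)], collapse = ", "))
    g <- gt[, cols, drop = FALSE]
    a <- gsub("[|]", "/", g)
    alleles <- cbind(sub("/.*", "", a), sub(".*/", "", a))
    dim(alleles) <- c(n, 2L * length(cols))
    called <- alleles == "0" | alleles == "1"
    alt[, k] <- as.integer(rowSums(alleles == "1"))
    nchr[, k] <- as.integer(rowSums(called))
  }
  snps <- data.frame(id = rownames(gt),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = as.numeric(GenomicRanges::start(rr)),
                     coding = FALSE, stringsAsFactors = FALSE)
  snp_panel(snps, alt, nchr)
}
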