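#' Equal-occupancy binning by recombination rate
#'
#' SNPs are sorted by (rho, chromosome, position) — the genomic coordinates
#' break ties deterministically — and split into \code{K} contiguous groups
#' whose sizes differ by at most one; when \code{K} does not divide the SNP
#' count the larger groups come first (lowest bin indices).
#'
#' @param rho numeric vector of recombination rates (cM/Mb).
#' @param K number of bins (>= 2, <= number of SNPs).
#' @param chrom,pos optional tie-break coordinates, same length as \code{rho}.
#' @return An object of class \code{binning_scheme}: list with \code{K},
#'   \code{bin} (per-SNP bin index, input order), \code{counts},
#'   \code{rho_median} (per bin) and \code{edges} (rho at the K-1 internal
#'   boundaries: the largest rho of each lower bin).
#' @export
make_bins <- function(rho, K, chrom = NULL, pos = NULL) {
  n <- length(rho)
  if (K < 2) stop("need at least 2 bins")
  if (n < K) stop("fewer SNPs (", n, ") than bins (", K, ")")
  o <- if (is.null(chrom)) order(rho) else order(rho, chrom, pos)
  sizes <- rep(n %/% K, K) + (seq_len(K) <= n %% K)
  bin <- integer(n)
  bin[o] <- rep.int(seq_len(K), sizes)
  med <- vapply(split(rho, bin), stats::median, numeric(1))
  edges <- vapply(split(rho, bin), max, numeric(1))[-K]
  structure(list(K = as.integer(K), bin = bin, counts = sizes,
                 rho_median = unname(med), edges = unname(edges)),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("binning_scheme:", x$K, "bins,", length(x$bin), "SNPs\n")
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  cat("  median rho:", paste(signif(x$rho_median, 4), collapse = " "), "\n")
  invisible(x)
}

#' Binned FST profile
#'
#' One point per recombination-rate bin: x is the median rho of the SNPs in
#' the bin, y the FST of the bin's SNPs (ratio-of-sums per pair; the global
#' value is the mean over pairs).
#'
#' @param panel an annotated \code{\link{snp_panel}} (with \code{rho}).
#' @param scheme a \code{\link{make_bins}} scheme built from this panel.
#' @param pops population labels (default all).
#' @param mode \code{"global"} (mean over pairs) or \code{"pairwise"}.
#' @return data.frame with columns \code{bin}, \code{n_snps},
#'   \code{rho_median}, \code{fst}, and one \code{fst_<pair>} column per
#'   population pair.
#' @export
bin_fst_profile <- function(panel, scheme, pops = populations(panel),
                            mode = c("global", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(length(scheme$bin) == nrow(panel$snps))
  comp <- panel_pair_components(panel, pops)
  sN <- rowsum(comp$N, scheme$bin)
  sD <- rowsum(comp$D, scheme$bin)
  if (any(sD <= 0)) {
    bad <- which(rowSums(sD <= 0) > 0)[1L]
    stop("bin ", rownames(sD)[bad], " has no informative SNPs")
  }
  f <- sN / sD
  out <- data.frame(bin = seq_len(scheme$K),
                    n_snps = scheme$counts,
                    rho_median = vapply(split(panel$snps$rho, scheme$bin),
                                        stats::median, numeric(1)),
                    fst = if (mode == "global") rowMeans(f) else rowMeans(f))
  colnames(f) <- paste0("fst_", comp$pairs)
  cbind(out, as.data.frame(f))
}

# closed-form OLS of y on (1, x): returns coefficients, se(b1), t, r
ols_line <- function(x, y) {
  K <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  b1 <- sum(xc * yc) / sxx
  b0 <- mean(y) - b1 * mean(x)
  rss <- sum(yc^2) - b1^2 * sxx
  rss <- max(rss, 0)
  se <- sqrt(rss / (K - 2) / sxx)
  syy <- sum(yc^2)
  r <- if (syy > 0) sum(xc * yc) / sqrt(sxx * syy) else 0
  list(b0 = b0, b1 = b1, se_b1 = se, t = if (se > 0) b1 / se else 0, r = r)
}

#' Linear regression of FST on recombination rate
#'
#' Unweighted ordinary least squares of \eqn{F_{ST} = b_0 + b_1 \rho} over
#' bin-level points, with the Pearson correlation \code{r}, the OLS
#' t-statistic for \code{b1} (df = K - 2) and the normalized slope
#' \code{b1/b0} (the proportional change in FST per cM/Mb).
#'
#' @param x,y numeric vectors (>= 3 points, >= 2 distinct x). \code{x} may
#'   also be a two-column data.frame/matrix of points.
#' @return An object of class \code{fst_regression}: list with \code{b0},
#'   \code{b1}, \code{se_b1}, \code{t}, \code{r}, \code{b1_over_b0},
#'   \code{df} and logical \code{degenerate} (constant y).
#' @export
fit_linear <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[[2]]; x <- x[[1]] }
  if (length(x) < 3) stop("need at least 3 points")
  if (length(unique(x)) < 2) stop("all x values are equal")
  degenerate <- length(unique(y)) < 2
  f <- ols_line(x, y)
  if (degenerate) { f$b1 <- 0; f$r <- 0; f$t <- 0 }
  structure(list(b0 = f$b0, b1 = f$b1, se_b1 = f$se_b1, t = f$t, r = f$r,
                 b1_over_b0 = if (f$b0 != 0) f$b1 / f$b0 else NA_real_,
                 df = length(x) - 2L, degenerate = degenerate),
            class = "fst_regression")
}

#' @export
print.fst_regression <- function(x, ...) {
  cat("FST ~ rho regression:\n")
  cat(sprintf("  b0 = %.6g  b1 = %.6g", x$b0, x$b1))
  if (!is.null(x$b2)) cat(sprintf("  b2 = %.6g", x$b2))
  cat("\n")
  cat(sprintf("  r = %.4f  t(b1) = %.4g (df %d)  b1/b0 = %.5g\n",
              x$r, x$t, x$df, x$b1_over_b0))
  invisible(x)
}

#' Quadratic regression of FST on recombination rate
#'
#' OLS on the design (1, x, x^2) with t-statistics for both the linear and
#' quadratic coefficients; the fit is concave when \code{b2 < 0} (the
#' inverse-U shape seen for some population pairs).
#'
#' @param x,y numeric vectors (>= 4 points, >= 3 distinct x).
#' @return An \code{fst_regression} with additional fields \code{b2},
#'   \code{se_b2}, \code{t_b2} and \code{concave}.
#' @export
fit_quadratic <- function(x, y = NULL) {
  if (is.null(y)) { y <- x[[2]]; x <- x[[1]] }
  if (length(x) < 4) stop("need at least 4 points")
  if (length(unique(x)) < 3) stop("need at least 3 distinct x values")
  X <- cbind(1, x, x^2)
  xtx <- crossprod(X)
  if (abs(det(xtx)) < 1e-300) stop("rank-deficient quadratic design")
  inv <- solve(xtx)
  beta <- unname(drop(inv %*% crossprod(X, y)))
  res <- y - drop(X %*% beta)
  df <- length(x) - 3L
  s2 <- sum(res^2) / df
  se <- sqrt(pmax(diag(inv) * s2, 0))
  syy <- sum((y - mean(y))^2)
  r <- if (syy > 0) stats::cor(x, y) else 0
  structure(list(b0 = beta[1], b1 = beta[2], b2 = beta[3],
                 se_b1 = se[2], se_b2 = se[3],
                 t = if (se[2] > 0) beta[2] / se[2] else 0,
                 t_b2 = if (se[3] > 0) beta[3] / se[3] else 0,
                 r = r,
                 b1_over_b0 = if (beta[1] != 0) beta[2] / beta[1] else NA_real_,
                 df = df, concave = beta[3] < 0,
                 degenerate = length(unique(y)) < 2),
            class = "fst_regression")
}

#' P-value for a correlation across bins
#'
#' Two-sided p for a Pearson correlation \code{r} over \code{K} points, from
#' \eqn{t = r\sqrt{K-2}/\sqrt{1-r^2}} against the t-distribution with
#' \code{K - 2} df. This is the "naive" per-fit p-value that ignores
#' estimation noise and LD; the bootstrap framework is the calibrated
#' alternative.
#'
#' @param r correlation in [-1, 1].
#' @param K number of points (>= 3).
#' @return list with \code{p} (two-sided), \code{t} and logical
#'   \code{degenerate} (\code{|r| = 1}, where p = 0).
#' @export
correlation_significance <- function(r, K) {
  stopifnot(K >= 3, abs(r) <= 1)
  if (abs(r) == 1)
    return(list(p = 0, t = sign(r) * Inf, degenerate = TRUE))
  t <- r * sqrt(K - 2) / sqrt(1 - r^2)
  list(p = 2 * stats::pt(-abs(t), df = K - 2), t = t, degenerate = FALSE)
}

#' Single-SNP (unbinned) FST-recombination analysis
#'
#' Pearson correlation and OLS regression of per-SNP global FST on the SNP's
#' window recombination rate, without binning. P-values use the
#' t-distribution with (#SNPs - #coefficients) df and ignore LD, mirroring
#' the naive genome-wide reporting convention; values below 1e-12 render as
#' "<<10^-12" in text output (see \code{\link{format_pvalue}}).
#'
#' @param panel an annotated \code{\link{snp_panel}} with \code{rho}.
#' @param pops population labels (default all); with exactly two labels this
#'   is the pairwise single-SNP analysis.
#' @param model \code{"linear"} or \code{"quadratic"}.
#' @return list with \code{r}, \code{p_r} (correlation p-value), \code{fit}
#'   (an \code{fst_regression}), \code{p_b1} (and \code{p_b2} for quadratic)
#'   and \code{n} (SNPs with defined FST).
#' @export
single_snp_analysis <- function(panel, pops = populations(panel),
                                model = c("linear", "quadratic")) {
  model <- match.arg(model)
  f <- per_snp_global_fst(panel, pops)
  keep <- !is.na(f)
  f <- f[keep]
  rho <- panel$snps$rho[keep]
  n <- length(f)
  if (n < 10) stop("need at least 10 SNPs with defined per-SNP FST")
  if (stats::sd(rho) == 0) stop("zero variance in rho")
  if (stats::sd(f) == 0) stop("zero variance in per-SNP FST")
  r <- stats::cor(rho, f)
  p_r <- correlation_significance(r, n)$p
  if (model == "linear") {
    fit <- fit_linear(rho, f)
    p_b1 <- 2 * stats::pt(-abs(fit$t), df = fit$df)
    list(r = r, p_r = p_r, fit = fit, p_b1 = p_b1, n = n)
  } else {
    fit <- fit_quadratic(rho, f)
    list(r = r, p_r = p_r, fit = fit,
         p_b1 = 2 * stats::pt(-abs(fit$t), df = fit$df),
         p_b2 = 2 * stats::pt(-abs(fit$t_b2), df = fit$df), n = n)
  }
}

#' Render a p-value the way genome-scale analyses print it
#'
#' @param p a p-value.
#' @param floor values below this render as \code{"<<10^-12"} (default
#'   1e-12).
#' @return character scalar.
#' @export
format_pvalue <- function(p, floor = 1e-12) {
  if (p < floor) "<<10^-12" else format(signif(p, 2))
}
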