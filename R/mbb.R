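#' Moving-block scheme
#'
#' Overlapping, non-circular blocks of \code{L} consecutive SNPs (in genomic
#' order) over \code{n} SNPs: start indices \code{1..n-L+1}.
#'
#' @param n number of SNPs.
#' @param L block length in SNPs (1 <= L <= n).
#' @return list of class \code{block_scheme} with \code{n}, \code{L},
#'   \code{n_blocks}.
#' @export
make_blocks <- function(n, L) {
  if (L < 1 || L > n) stop("block length L must satisfy 1 <= L <= n")
  structure(list(n = as.integer(n), L = as.integer(L),
                 n_blocks = as.integer(n - L + 1)), class = "block_scheme")
}

#' One moving-block-bootstrap index resample
#'
#' Draws \code{ceiling(n/L)} block start indices uniformly with replacement,
#' concatenates the blocks and truncates to length \code{n}. Uses the
#' current RNG state, so results are deterministic given a seed.
#'
#' @param scheme a \code{\link{make_blocks}} scheme.
#' @return integer vector of length \code{n} of resampled SNP indices.
#' @export
resample_indices <- function(scheme) {
  n <- scheme$n
  L <- scheme$L
  nb <- ceiling(n / L)
  starts <- sample.int(scheme$n_blocks, nb, replace = TRUE)
  idx <- rep(starts, each = L) + rep.int(seq_len(L) - 1L, nb)
  idx[seq_len(n)]
}

#' Z-test on a bootstrap mean and standard error
#'
#' @param mean statistic value (bootstrap mean).
#' @param se its standard error (bootstrap SD across replicates; > 0).
#' @param alternative \code{"two.sided"} (mean != 0), \code{"less"}
#'   (mean < 0) or \code{"greater"} (mean > 0).
#' @return list with \code{z} and \code{p}.
#' @export
z_test <- function(mean, se, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (se <= 0) stop("standard error must be positive")
  z <- mean / se
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(-z))
  list(z = z, p = p)
}

#' Compare a statistic between two analyses
#'
#' Z-test on the difference of two independently bootstrapped statistics:
#' \eqn{z = (mean_A - mean_B)/\sqrt{se_A^2 + se_B^2}}. Used, e.g., to test a
#' steeper normalized slope in coding SNPs (one-sided) or a different
#' normalized slope between population pairs (two-sided).
#'
#' @param meanA,seA bootstrap mean and SE of analysis A.
#' @param meanB,seB same for analysis B.
#' @param alternative \code{"two.sided"} (A != B), \code{"less"} (A < B) or
#'   \code{"greater"} (A > B).
#' @return list with \code{z} and \code{p}.
#' @export
compare_analyses <- function(meanA, seA, meanB, seB,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (seA <= 0 || seB <= 0) stop("standard errors must be positive")
  z_test(meanA - meanB, sqrt(seA^2 + seB^2), alternative)
}

# Independent per-replicate RNG substreams from a single user seed
# (L'Ecuyer-CMRG), so replicates could be parallelized without changing
# results. Restores the caller's RNG state on exit via the returned restore().
rng_substreams <- function(seed, B) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", B)
  for (b in seq_len(B)) {
    s <- parallel::nextRNGStream(s)
    streams[[b]] <- s
  }
  restore <- function() {
    suppressWarnings(RNGkind(old_kind[1]))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }
  list(streams = streams, restore = restore)
}

# grouped medians of x by integer group 1..K (all groups present)
grouped_median <- function(x, g, K) {
  o <- order(g, x)
  cnt <- tabulate(g, K)
  starts <- cumsum(cnt) - cnt + 1L
  xo <- x[o]
  lo <- xo[starts + (cnt - 1L) %/% 2L]
  hi <- xo[starts + cnt %/% 2L]
  (lo + hi) / 2
}

# Fast per-replicate fits, vectorized over series (columns of Y).
# Returns rows: b0, b1, r, t, ratio [, b2, t_b2] per series.
fit_series <- function(x, Y, quadratic = FALSE) {
  K <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  if (sxx == 0) {
    # degenerate replicate (all bin medians equal): flat fit by convention
    z <- rep(0, ncol(Y))
    out <- rbind(b0 = ym, b1 = z, r = z, t = z, ratio = z)
    if (quadratic) out <- rbind(out, b2 = z, t_b2 = z)
    return(out)
  }
  sxy <- colSums(xc * Yc)
  b1 <- sxy / sxx
  b0 <- ym - b1 * mean(x)
  syy <- colSums(Yc^2)
  r <- ifelse(syy > 0, sxy / sqrt(sxx * syy), 0)
  rss <- pmax(syy - b1^2 * sxx, 0)
  se <- sqrt(rss / (K - 2) / sxx)
  t <- ifelse(se > 0, b1 / se, 0)
  out <- rbind(b0 = b0, b1 = b1, r = r, t = t,
               ratio = ifelse(b0 != 0, b1 / b0, NA_real_))
  if (quadratic) {
    X <- cbind(1, x, x^2)
    inv <- solve(crossprod(X))
    beta <- inv %*% crossprod(X, Y)   # 3 x S
    res <- Y - X %*% beta
    s2 <- colSums(res^2) / (K - 3)
    se2 <- sqrt(pmax(inv[3, 3] * s2, 0))
    out <- rbind(out, b2 = beta[3, ],
                 t_b2 = ifelse(se2 > 0, beta[3, ] / se2, 0))
  }
  out
}

#' Moving-block-bootstrap inference framework
#'
#' Resamples the SNP set \code{B} times with the moving block bootstrap
#' (preserving LD structure), and within each replicate regroups the
#' resampled SNPs by their pre-assigned recombination-rate bin, recomputes
#' per-bin FST (ratio-of-sums per pair; global = mean over pairs) and per-bin
#' median rho from the resampled SNPs, and refits the regression of FST on
#' rho. The per-replicate statistics b0, b1 (b2 for quadratic fits), r, the
#' OLS t for b1 and the normalized slope b1/b0 are summarized by their mean
#' and SD (reported as the standard error) across replicates.
#'
#' Bin membership is fixed at the original assignment and carried by each
#' SNP into resamples; a replicate that leaves any bin empty (or any bin
#' with zero denominator) is rejected and redrawn, and more than 10\%
#' rejections is a hard error.
#'
#' @param panel an annotated \code{\link{snp_panel}} (genomic order, with
#'   \code{rho}).
#' @param scheme a \code{\link{make_bins}} scheme for this panel (default:
#'   built with \code{K} bins).
#' @param K bins used when \code{scheme} is \code{NULL} (default 10).
#' @param B bootstrap replicates (default 1000).
#' @param L block length in SNPs (default 200; at ~2.6 kb/SNP marker density
#'   this spans roughly 0.5 Mb, beyond typical LD range).
#' @param seed integer seed; replicates use independent RNG substreams.
#' @param pops population labels (default all).
#' @param model \code{"linear"} or \code{"quadratic"}.
#' @return An object of class \code{bootstrap_summary}: list with
#'   \code{series} (named list, one per population pair plus \code{global},
#'   each holding \code{replicates} (B x statistic matrix), \code{mean} and
#'   \code{se}), plus \code{B}, \code{L}, \code{K}, \code{seed},
#'   \code{model}, \code{n_snps} and \code{rejected} (redraw count).
#' @export
bootstrap_framework <- function(panel, scheme = NULL, K = 10, B = 1000,
                                L = 200, seed = 1,
                                pops = populations(panel),
                                model = c("linear", "quadratic")) {
  model <- match.arg(model)
  stopifnot(B >= 2)
  if (is.null(panel$snps$rho))
    stop("panel is not annotated with recombination rates")
  if (is.null(scheme))
    scheme <- make_bins(panel$snps$rho, K, panel$snps$chrom, panel$snps$pos)
  comp <- panel_pair_components(panel, pops)
  mbb_core(comp$N, comp$D, panel$snps$rho, scheme$bin, scheme$K,
           B = B, L = L, seed = seed, model = model)
}

# Core kernel, exposed for reuse by the pipeline and simulation studies.
mbb_core <- function(N, D, rho, bin, K, B, L, seed,
                     model = c("linear", "quadratic")) {
  model <- match.arg(model)
  n <- length(rho)
  P <- ncol(N)
  quadratic <- model == "quadratic"
  series <- if (P > 1) c(colnames(N), "global") else colnames(N)
  stats <- c("b0", "b1", "r", "t", "ratio", if (quadratic) c("b2", "t_b2"))
  blocks <- make_blocks(n, L)
  ND <- cbind(N, D)
  rng <- rng_substreams(seed, B)
  on.exit(rng$restore())
  reps <- array(NA_real_, c(B, length(stats), length(series)),
                dimnames = list(NULL, stats, series))
  rejected <- 0L
  for (b in seq_len(B)) {
    assign(".Random.seed", rng$streams[[b]], globalenv())
    repeat {
      if (rejected > 0.1 * B)
        stop("more than 10% of bootstrap replicates rejected (empty bins)")
      idx <- resample_indices(blocks)
      binr <- bin[idx]
      if (any(tabulate(binr, K) == 0L)) { rejected <- rejected + 1L; next }
      rs <- rowsum(ND[idx, , drop = FALSE], binr)
      sD <- rs[, P + seq_len(P), drop = FALSE]
      if (any(sD <= 0)) { rejected <- rejected + 1L; next }
      break
    }
    f <- rs[, seq_len(P), drop = FALSE] / sD
    Y <- if (P > 1) cbind(f, global = rowMeans(f)) else f
    med <- grouped_median(rho[idx], binr, K)
    reps[b, , ] <- fit_series(med, Y, quadratic)
  }
  out_series <- lapply(seq_along(series), function(s) {
    m <- reps[, , s, drop = FALSE]
    dim(m) <- dim(reps)[1:2]
    colnames(m) <- stats
    list(replicates = m, mean = colMeans(m),
         se = apply(m, 2, stats::sd))
  })
  names(out_series) <- series
  structure(list(series = out_series, B = B, L = L, K = K, seed = seed,
                 model = model, n_snps = n, rejected = rejected),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap_summary: B = %d, L = %d, K = %d, %d SNPs, model %s\n",
              x$B, x$L, x$K, x$n_snps, x$model))
  if (x$rejected > 0) cat("  rejected replicates:", x$rejected, "\n")
  for (s in names(x$series)) {
    m <- x$series[[s]]
    cat(" ", s, "\n")
    for (st in names(m$mean)) {
      zt <- if (m$se[st] > 0 && st != "ratio")
        sprintf(" (p = %s)", format_pvalue(z_test(m$mean[st], m$se[st])$p))
      else ""
      cat(sprintf("    %-5s %9.4f +/- %.4f%s\n", st, m$mean[st], m$se[st], zt))
    }
  }
  invisible(x)
}

#' Z-test on one bootstrapped statistic
#'
#' @param summary a \code{\link{bootstrap_framework}} result.
#' @param series series name (a population pair label or \code{"global"}).
#' @param stat one of \code{"b0"}, \code{"b1"}, \code{"r"}, \code{"t"},
#'   \code{"ratio"} (and \code{"b2"}, \code{"t_b2"} for quadratic fits).
#' @param alternative passed to \code{\link{z_test}}.
#' @return list with \code{mean}, \code{se}, \code{z}, \code{p}.
#' @export
bootstrap_z <- function(summary, series = "global", stat = "b1",
                        alternative = "two.sided") {
  m <- summary$series[[series]]
  if (is.null(m)) stop("unknown series: ", series)
  zt <- z_test(m$mean[[stat]], m$se[[stat]], alternative)
  list(mean = m$mean[[stat]], se = m$se[[stat]], z = zt$z, p = zt$p)
}

# MBB standard error of per-bin FST (global series), used for SE studies:
# returns the SE (SD across B replicates) of each bin's FST.
mbb_bin_fst_se <- function(N, D, bin, K, B, L, seed) {
  n <- nrow(N)
  P <- ncol(N)
  ND <- cbind(N, D)
  blocks <- make_blocks(n, L)
  rng <- rng_substreams(seed, B)
  on.exit(rng$restore())
  acc <- matrix(NA_real_, B, K)
  for (b in seq_len(B)) {
    assign(".Random.seed", rng$streams[[b]], globalenv())
    repeat {
      idx <- resample_indices(blocks)
      binr <- bin[idx]
      if (any(tabulate(binr, K) == 0L)) next
      rs <- rowsum(ND[idx, , drop = FALSE], binr)
      sD <- rs[, P + seq_len(P), drop = FALSE]
      if (any(sD <= 0)) next
      break
    }
    f <- rs[, seq_len(P), drop = FALSE] / sD
    acc[b, ] <- if (P > 1) rowMeans(f) else f[, 1]
  }
  apply(acc, 2, stats::sd)
}
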