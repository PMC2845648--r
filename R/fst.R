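#' Per-SNP FST components for one population pair
#'
#' For sample frequencies \eqn{\hat p_i = alt_i/n_i}, the variance-corrected
#' numerator and the heterozygosity denominator are
#' \deqn{N = (\hat p_1-\hat p_2)^2 - \frac{\hat p_1(1-\hat p_1)}{n_1-1}
#'          - \frac{\hat p_2(1-\hat p_2)}{n_2-1},}
#' \deqn{D = \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1).}
#' \code{N} is unbiased for the squared true frequency difference and may be
#' negative; \code{D >= 0} and \code{N <= D} always (so FST never exceeds 1).
#' SNPs monomorphic in both populations contribute (0, 0).
#'
#' @param alt1,n1 alternate-allele count and genotyped chromosomes, pop 1.
#' @param alt2,n2 same for pop 2. All vectors recycled to a common length;
#'   every \code{n} must be >= 2.
#' @return list with numeric vectors \code{N} and \code{D}.
#' @export
pair_fst_components <- function(alt1, n1, alt2, n2) {
  if (any(n1 < 2) || any(n2 < 2))
    stop("sample size n must be >= 2 in both populations")
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  N <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  D <- p1 * (1 - p2) + p2 * (1 - p1)
  list(N = N, D = D)
}

#' Ratio-of-sums FST
#'
#' Aggregates per-SNP components by summing numerators and denominators
#' across SNPs before dividing, which tames the noise of small per-SNP
#' denominators. Order-invariant.
#'
#' @param N,D numeric vectors of per-SNP components, or a list with elements
#'   \code{N} and \code{D} passed as the first argument.
#' @return The FST estimate \eqn{\sum N / \sum D}.
#' @export
fst_ratio_of_sums <- function(N, D = NULL) {
  if (is.list(N) && is.null(D)) { D <- N$D; N <- N$N }
  sD <- sum(D)
  if (sD <= 0) stop("no informative SNPs (sum of denominators is zero)")
  sum(N) / sD
}

#' Per-SNP FST
#'
#' \code{N/D} where defined (\code{D > 0}), \code{NA} otherwise; \code{NA}
#' is a value, not an error.
#'
#' @inheritParams fst_ratio_of_sums
#' @return numeric vector of per-SNP FST values (possibly negative).
#' @export
per_snp_fst <- function(N, D = NULL) {
  if (is.list(N) && is.null(D)) { D <- N$D; N <- N$N }
  ifelse(D > 0, N / D, NA_real_)
}

# (N, D) matrices (SNPs x pairs) for all unordered population pairs
panel_pair_components <- function(panel, pops = populations(panel)) {
  stopifnot(length(pops) >= 2)
  pairs <- utils::combn(pops, 2)
  nm <- apply(pairs, 2, paste, collapse = "-")
  n <- nrow(panel$alt)
  N <- matrix(0, n, ncol(pairs), dimnames = list(NULL, nm))
  D <- N
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    comp <- pair_fst_components(panel$alt[, a], panel$nchr[, a],
                                panel$alt[, b], panel$nchr[, b])
    N[, j] <- comp$N
    D[, j] <- comp$D
  }
  list(N = N, D = D, pairs = nm)
}

#' Pairwise FST for all population pairs
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param pops population labels to use (default all).
#' @return named numeric vector, one ratio-of-sums FST per unordered pair
#'   (names \code{"A-B"}).
#' @export
pairwise_fst <- function(panel, pops = populations(panel)) {
  comp <- panel_pair_components(panel, pops)
  out <- vapply(seq_along(comp$pairs), function(j)
    fst_ratio_of_sums(comp$N[, j], comp$D[, j]), numeric(1))
  names(out) <- comp$pairs
  out
}

#' Global FST
#'
#' Global allele-frequency differentiation: the unweighted mean of the
#' pairwise ratio-of-sums FST over all unordered population pairs, computed
#' on the same SNP set.
#'
#' @inheritParams pairwise_fst
#' @return a single FST value.
#' @export
global_fst <- function(panel, pops = populations(panel)) {
  mean(pairwise_fst(panel, pops))
}

#' Per-SNP global FST
#'
#' The SNP-level analogue of \code{\link{global_fst}}: the unweighted mean of
#' the defined pairwise per-SNP values \code{N/D}; \code{NA} when every pair
#' is undefined. Used by single-SNP (unbinned) correlation analyses.
#'
#' @inheritParams pairwise_fst
#' @return numeric vector, one value (or \code{NA}) per SNP.
#' @export
per_snp_global_fst <- function(panel, pops = populations(panel)) {
  comp <- panel_pair_components(panel, pops)
  f <- comp$N / comp$D
  f[comp$D <= 0] <- NA
  out <- rowMeans(f, na.rm = TRUE)
  out[!is.finite(out)] <- NA
  out
}

#' Weir-Cockerham FST (cross-check estimator)
#'
#' The Weir & Cockerham (1984) theta for allele-count (haploid-sampling)
#' data, aggregated ratio-of-sums across SNPs: per SNP, with populations
#' \eqn{i = 1..r}, sizes \eqn{n_i} and frequencies \eqn{p_i},
#' \eqn{MSP = \sum n_i(p_i-\bar p)^2/(r-1)},
#' \eqn{MSG = \sum n_i p_i(1-p_i)/\sum(n_i-1)} and
#' \eqn{n_c = (\sum n_i - \sum n_i^2/\sum n_i)/(r-1)}; the estimate is
#' \eqn{\sum(MSP - MSG) / \sum(MSP + (n_c-1)MSG)}. Intended as an
#' independent cross-check of \code{\link{fst_ratio_of_sums}}: the two agree
#' closely on genome-scale panels.
#'
#' @inheritParams pairwise_fst
#' @return a single FST value.
#' @export
weir_cockerham_fst <- function(panel, pops = populations(panel)) {
  stopifnot(length(pops) >= 2)
  r <- length(pops)
  ni <- panel$nchr[, pops, drop = FALSE]
  pi <- panel$alt[, pops, drop = FALSE] / ni
  ntot <- rowSums(ni)
  pbar <- rowSums(ni * pi) / ntot
  msp <- rowSums(ni * (pi - pbar)^2) / (r - 1)
  msg <- rowSums(ni * pi * (1 - pi)) / (ntot - r)
  nc <- (ntot - rowSums(ni^2) / ntot) / (r - 1)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  if (sum(den) <= 0) stop("no informative SNPs (sum of denominators is zero)")
  sum(num) / sum(den)
}
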