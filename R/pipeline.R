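#' Analysis configuration
#'
#' Bundles the tunable parameters of the full FST-vs-recombination analysis.
#'
#' @param W recombination window length in bp (default 3 Mb; 1 Mb and 5 Mb
#'   are the standard robustness variants).
#' @param K number of recombination-rate bins (default 10; 40 variant).
#' @param B bootstrap replicates (default 1000).
#' @param L moving-block length in SNPs (default 200).
#' @param seed integer seed for the bootstrap.
#' @param extend_mask extra centromere/telomere masking in bp (default 0;
#'   5 Mb variant).
#' @param model \code{"linear"} or \code{"quadratic"} regression.
#' @param maf_edges right-closed MAF category edges in (0, 0.5] (default
#'   0.125/0.25/0.375/0.5, i.e. categories A-D).
#' @param do_coding,do_maf,do_single_snp stratification switches.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(W = 3e6, K = 10, B = 1000, L = 200, seed = 1,
                            extend_mask = 0,
                            model = c("linear", "quadratic"),
                            maf_edges = c(0.125, 0.25, 0.375, 0.5),
                            do_coding = TRUE, do_maf = FALSE,
                            do_single_snp = TRUE) {
  model <- match.arg(model)
  stopifnot(W > 0, K >= 2, B >= 2, L >= 1, extend_mask >= 0,
            all(diff(maf_edges) > 0), all(maf_edges > 0), all(maf_edges <= 0.5))
  structure(list(W = W, K = K, B = B, L = L, seed = as.integer(seed),
                 extend_mask = extend_mask, model = model,
                 maf_edges = maf_edges, do_coding = do_coding,
                 do_maf = do_maf, do_single_snp = do_single_snp),
            class = "analysis_config")
}

#' Stratify a panel by coding status and MAF category
#'
#' Adds/overwrites the \code{coding} flag from exon intervals (when given)
#' and assigns each SNP one MAF category using left-open, right-closed
#' ranges: with the default edges, A: MAF <= 0.125, B: 0.125 < MAF <= 0.25,
#' C: 0.25 < MAF <= 0.375, D: 0.375 < MAF <= 0.5.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param coding_intervals \code{NULL} (keep the panel's flag), a data.frame
#'   with chrom/start/end (1-based closed), or a BED file path.
#' @param maf_edges ascending edges in (0, 0.5].
#' @return The panel with updated \code{snps$coding}, \code{snps$maf} and
#'   \code{snps$maf_cat} (letters).
#' @export
stratify <- function(panel, coding_intervals = NULL,
                     maf_edges = c(0.125, 0.25, 0.375, 0.5)) {
  stopifnot(all(diff(maf_edges) > 0), all(maf_edges > 0))
  if (!is.null(coding_intervals)) {
    if (is.character(coding_intervals))
      coding_intervals <- read_bed_intervals(coding_intervals)
    if (any(coding_intervals$start > coding_intervals$end))
      stop("malformed coding interval")
    coding <- rep(FALSE, nrow(panel$snps))
    for (cc in unique(panel$snps$chrom)) {
      i <- which(panel$snps$chrom == cc)
      e <- coding_intervals[coding_intervals$chrom == cc, , drop = FALSE]
      if (nrow(e) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = panel$snps$pos[i], width = 1),
        IRanges::IRanges(start = e$start, end = e$end))
      coding[i[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
    panel$snps$coding <- coding
  }
  maf <- panel_maf(panel)
  panel$snps$maf <- maf
  panel$snps$maf_cat <- LETTERS[findInterval(maf, maf_edges, left.open = TRUE,
                                             rightmost.closed = FALSE) + 1L]
  panel
}

naive_stats <- function(panel, scheme, pops, model) {
  prof <- bin_fst_profile(panel, scheme, pops)
  fit <- if (model == "quadratic")
    fit_quadratic(prof$rho_median, prof$fst)
  else fit_linear(prof$rho_median, prof$fst)
  corr <- correlation_significance(fit$r, nrow(prof))
  pair_fits <- lapply(grep("^fst_", names(prof), value = TRUE), function(cn) {
    f <- fit_linear(prof$rho_median, prof[[cn]])
    list(pair = sub("^fst_", "", cn), b0 = f$b0, b1 = f$b1, r = f$r,
         p_r = correlation_significance(f$r, nrow(prof))$p)
  })
  list(profile = prof, fit = unclass(fit), p_r = corr$p, pair_fits = pair_fits)
}

summarize_boot <- function(bs) {
  lapply(bs$series, function(m) {
    stats <- names(m$mean)
    out <- lapply(stats, function(st) {
      e <- list(mean = unname(m$mean[st]), se = unname(m$se[st]))
      if (st != "ratio" && m$se[st] > 0)
        e$p_two_sided <- z_test(e$mean, e$se)$p
      e
    })
    names(out) <- stats
    out
  })
}

#' Run the full analysis
#'
#' Orchestrates: recombination-rate annotation, stratification, binning,
#' naive bin-level fits with correlation p-values, the moving-block
#' bootstrap framework per stratum (global and per population pair), the
#' standard comparisons (coding vs non-coding b0/b1/b1_over_b0, one-sided;
#' b1/b0 between population pairs, two-sided) and single-SNP analyses. The
#' report is a plain list (JSON-serializable) and is byte-identical across
#' runs with identical inputs, config and seed.
#'
#' @param config an \code{\link{analysis_config}}.
#' @param map a \code{\link{genetic_map}} or file path.
#' @param structure a \code{\link{chromosome_structure}}.
#' @param panel a \code{\link{snp_panel}} or allele-count table path.
#' @param coding_intervals optional exon intervals (data.frame or BED path)
#'   overriding the panel's coding flag.
#' @return list of class \code{analysis_report} with elements
#'   \code{config}, \code{filter_log}, \code{n_snps}, \code{strata} (per
#'   stratum: profile, naive fit, bootstrap summaries with z-test p-values),
#'   \code{comparisons}, \code{single_snp} and \code{provenance}.
#' @export
run_analysis <- function(config, map, structure, panel,
                         coding_intervals = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  digests <- list()
  if (is.character(map)) {
    digests$map <- unname(tools::md5sum(map))
    map <- read_genetic_map(map)
  }
  if (is.character(panel)) {
    digests$counts <- unname(tools::md5sum(panel))
    panel <- read_allele_counts(panel)
  }

  ann <- annotate_snps(panel, map, structure, W = config$W,
                       extend_mask = config$extend_mask)
  panel <- stratify(ann$panel, coding_intervals, config$maf_edges)
  pops <- populations(panel)

  strata <- list(all = rep(TRUE, nrow(panel$snps)))
  if (config$do_coding) {
    strata$coding <- panel$snps$coding
    strata$noncoding <- !panel$snps$coding
  }
  if (config$do_maf)
    for (cat in LETTERS[seq_along(config$maf_edges)])
      strata[[paste0("maf_", cat)]] <- panel$snps$maf_cat == cat

  res <- list()
  boots <- list()
  for (s in names(strata)) {
    sub <- subset_panel(panel, which(strata[[s]]))
    if (nrow(sub$snps) < config$K * 2) {
      res[[s]] <- list(skipped = paste0("only ", nrow(sub$snps), " SNPs"))
      next
    }
    scheme <- make_bins(sub$snps$rho, config$K, sub$snps$chrom, sub$snps$pos)
    bs <- bootstrap_framework(sub, scheme, B = config$B,
                              L = min(config$L, nrow(sub$snps)),
                              seed = config$seed, pops = pops,
                              model = config$model)
    boots[[s]] <- bs
    res[[s]] <- list(n_snps = nrow(sub$snps),
                     naive = naive_stats(sub, scheme, pops, config$model),
                     bootstrap = summarize_boot(bs))
  }

  comparisons <- list()
  if (config$do_coding && !is.null(boots$coding) && !is.null(boots$noncoding)) {
    cs <- boots$coding$series$global
    ns <- boots$noncoding$series$global
    one_sided <- function(stat, alt)
      c(compare_analyses(cs$mean[[stat]], cs$se[[stat]],
                         ns$mean[[stat]], ns$se[[stat]], alt),
        list(alternative = alt))
    comparisons$coding_vs_noncoding <- list(
      b0 = one_sided("b0", "greater"),   # higher differentiation in genes
      b1 = one_sided("b1", "less"),      # steeper (more negative) slope
      b1_over_b0 = one_sided("ratio", "less"))
  }
  if (!is.null(boots$all) && length(pops) > 2) {
    pr <- setdiff(names(boots$all$series), "global")
    for (i in seq_along(pr)) for (j in seq_along(pr)) if (i < j) {
      a <- boots$all$series[[pr[i]]]
      b <- boots$all$series[[pr[j]]]
      comparisons[[paste0("ratio:", pr[i], ":vs:", pr[j])]] <-
        c(compare_analyses(a$mean[["ratio"]], a$se[["ratio"]],
                           b$mean[["ratio"]], b$se[["ratio"]], "two.sided"),
          list(alternative = "two.sided"))
    }
  }

  single <- NULL
  if (config$do_single_snp) {
    ss <- single_snp_analysis(panel, pops, model = config$model)
    single <- list(r = ss$r, p_r = ss$p_r, p_r_text = format_pvalue(ss$p_r),
                   b0 = ss$fit$b0, b1 = ss$fit$b1, p_b1 = ss$p_b1, n = ss$n)
  }

  structure(list(
    config = unclass(config),
    filter_log = as.list(ann$log),
    n_snps = nrow(panel$snps),
    strata = res,
    comparisons = comparisons,
    single_snp = single,
    provenance = list(package = "recfst",
                      version = as.character(utils::packageVersion("recfst")),
                      input_digests = digests)),
    class = "analysis_report")
}

#' Write an analysis report
#'
#' Writes \code{report.json} plus one tab-separated bin profile per stratum
#' (\code{profile_<stratum>.tsv}). Output bytes are deterministic for
#' identical inputs/config/seed.
#'
#' @param report an \code{\link{run_analysis}} report.
#' @param dir output directory (created if needed).
#' @return the report path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(report$strata)) {
    prof <- report$strata[[s]]$naive$profile
    if (!is.null(prof))
      data.table::fwrite(prof, file.path(dir, paste0("profile_", s, ".tsv")),
                         sep = "\t")
  }
  slim <- report
  for (s in names(slim$strata)) slim$strata[[s]]$naive$profile <- NULL
  out <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(slim), out, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, null = "null")
  invisible(out)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", x$n_snps, "SNPs,", length(x$strata), "strata\n")
  cat("  filters:", paste(names(x$filter_log), unlist(x$filter_log),
                          sep = "=", collapse = " "), "\n")
  g <- x$strata$all$bootstrap$global
  if (!is.null(g))
    cat(sprintf("  global: b0 = %.4f+/-%.4f  b1 = %.4f+/-%.4f (p = %s)\n",
                g$b0$mean, g$b0$se, g$b1$mean, g$b1$se,
                format_pvalue(g$b1$p_two_sided)))
  invisible(x)
}
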