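#' Published bootstrap summaries of the FST-recombination regression
#'
#' Reference values for worked examples: bootstrap means and standard errors
#' (SD across 1,000 moving-block-bootstrap replicates) of the statistics of
#' the genome-wide regression of FST on the 3 Mb window recombination rate,
#' as published for the Perlegen class A SNP panel (African American,
#' European and Han Chinese samples; 1,110,338 autosomal SNPs, 10
#' recombination-rate bins unless noted). These printed summaries are
#' \emph{inputs} to the z-test and comparison operations — feeding them in
#' reproduces the published hypothesis-test p-values.
#'
#' Analyses: \code{global} (all SNPs), \code{global40} (40 bins),
#' \code{coding} (21,391 coding SNPs), \code{noncoding}, and the pairwise
#' analyses \code{AA-EUR}, \code{AA-CHB}, \code{EUR-CHB}. Statistics:
#' \code{b0}, \code{b1}, \code{r}, \code{t}, \code{ratio} (= b1/b0), and
#' \code{fst} (the genome-wide FST of the stratum, bootstrap SE).
#'
#' @return data.frame with columns \code{analysis}, \code{stat},
#'   \code{mean}, \code{se}, \code{B}.
#' @export
published_fst_summaries <- function() {
  d <- rbind(
    data.frame(analysis = "global", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1280, -0.0049, -0.8862, -6.0926, -0.0379),
               se = c(0.0012, 0.0007, 0.0567, 2.1758, 0.0052)),
    data.frame(analysis = "global40", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1277, -0.0046, -0.6476, -5.4512, -0.0358),
               se = c(0.0011, 0.0007, 0.0678, 0.9889, 0.0049)),
    data.frame(analysis = "coding", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1381, -0.0081, -0.6801, -2.8775, -0.0585),
               se = c(0.0038, 0.0022, 0.1286, 1.0702, 0.0147)),
    data.frame(analysis = "noncoding", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1279, -0.0048, -0.8823, -5.8950, -0.0376),
               se = c(0.0012, 0.0007, 0.0561, 1.9773, 0.0053)),
    data.frame(analysis = "AA-EUR", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1137, -0.0057, -0.7697, -3.5253, -0.0499),
               se = c(0.0014, 0.0008, 0.0589, 0.6955, 0.0064)),
    data.frame(analysis = "AA-CHB", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1547, -0.0067, -0.8448, -4.7959, -0.0430),
               se = c(0.0015, 0.0010, 0.0635, 1.2800, 0.0059)),
    data.frame(analysis = "EUR-CHB", stat = c("b0", "b1", "r", "t", "ratio"),
               mean = c(0.1156, -0.0021, -0.3244, -1.0147, -0.0185),
               se = c(0.0018, 0.0010, 0.1544, 0.5389, 0.0088)),
    data.frame(analysis = c("coding", "noncoding"), stat = "fst",
               mean = c(0.1265, 0.1212), se = c(0.0016, 0.0006)))
  d$B <- 1000L
  d
}

#' Published bin-level correlations from the uniformly-ascertained HapMap
#' subset
#'
#' Pearson correlations between binned FST and median recombination rate
#' over K = 10 bins, as published for 248,886 uniformly-ascertained HapMap
#' SNPs (YRI, CEU and pooled CHB+JPT samples). Inputs to
#' \code{\link{correlation_significance}} worked examples.
#'
#' @return data.frame with columns \code{analysis}, \code{r}, \code{K}.
#' @export
published_hapmap_correlations <- function() {
  data.frame(analysis = c("global", "YRI-CEU", "YRI-ASN", "CEU-ASN"),
             r = c(-0.526, -0.482, -0.634, -0.066),
             K = 10L)
}
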