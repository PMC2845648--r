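#' Construct a genetic map
#'
#' A genetic map holds, per chromosome, an ordered sequence of markers with a
#' physical position (bp, 1-based) and a cumulative genetic position (cM from
#' the chromosome start). It is the substrate for interpolating genetic
#' positions and hence for windowed recombination-rate estimation.
#'
#' @param chrom character vector of chromosome labels, one per marker.
#' @param pos numeric vector of physical positions (bp, 1-based).
#' @param cm numeric vector of cumulative genetic positions (cM, >= 0).
#' @return An object of class \code{genetic_map}: a list with element
#'   \code{chroms}, a named list mapping each chromosome to a list with
#'   numeric vectors \code{pos} and \code{cm}, sorted by \code{pos}.
#' @details Markers are sorted by physical position within each chromosome.
#'   Duplicate physical positions, or genetic positions that decrease with
#'   physical position, are hard errors naming the offending marker.
#' @export
genetic_map <- function(chrom, pos, cm) {
  stopifnot(length(chrom) == length(pos), length(pos) == length(cm))
  if (length(pos) == 0L) stop("genetic map has no markers")
  if (anyNA(pos) || anyNA(cm) || anyNA(chrom))
    stop("genetic map contains missing values")
  if (any(cm < 0)) stop("genetic positions must be >= 0")
  chrom <- as.character(chrom)
  chroms <- lapply(split(data.frame(pos = as.numeric(pos), cm = as.numeric(cm)),
                         chrom), function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (anyDuplicated(d$pos))
      stop("duplicate marker position ", d$pos[duplicated(d$pos)][1L])
    dcm <- diff(d$cm)
    if (any(dcm < 0)) {
      i <- which(dcm < 0)[1L] + 1L
      stop("genetic position decreases at marker (pos=", format(d$pos[i]),
           ", cM=", format(d$cm[i]), ")")
    }
    list(pos = d$pos, cm = d$cm)
  })
  structure(list(chroms = chroms), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  n <- vapply(x$chroms, function(m) length(m$pos), integer(1))
  cat("genetic_map:", length(n), "chromosome(s),", sum(n), "markers\n")
  for (ch in names(x$chroms)) {
    m <- x$chroms[[ch]]
    cat(sprintf("  %s: %d markers, %.3g-%.3g bp, %.4g cM\n", ch,
                length(m$pos), min(m$pos), max(m$pos), max(m$cm)))
  }
  invisible(x)
}

# Read a whitespace/tab table, dropping '#' comment lines; errors carry the
# original line number of the first unparseable row.
read_map_table <- function(path, ncol_min) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0L) stop("no data lines in ", path)
  dat <- strsplit(trimws(lines[keep]), "[\t ]+")
  ncols <- lengths(dat)
  if (any(ncols < ncol_min)) {
    bad <- which(ncols < ncol_min)[1L]
    stop("unparseable line ", lineno[bad], " in ", path,
         ": expected >= ", ncol_min, " fields")
  }
  list(fields = dat, lineno = lineno)
}

#' Read a genetic map from a tab-separated file
#'
#' Native dialect: columns (chromosome, position bp, cumulative cM), with an
#' optional header line and '#' comments ignored.
#'
#' @param path file path.
#' @return A \code{\link{genetic_map}}.
#' @export
read_genetic_map <- function(path) {
  tab <- read_map_table(path, 3L)
  f <- tab$fields
  # header detection: numeric conversion of columns 2-3 fails on first row
  first <- suppressWarnings(as.numeric(c(f[[1]][2], f[[1]][3])))
  start <- if (anyNA(first)) 2L else 1L
  if (start > length(f)) stop("no data rows in ", path)
  rows <- seq(start, length(f))
  chrom <- vapply(f[rows], `[`, character(1), 1L)
  pos <- suppressWarnings(as.numeric(vapply(f[rows], `[`, character(1), 2L)))
  cm <- suppressWarnings(as.numeric(vapply(f[rows], `[`, character(1), 3L)))
  if (anyNA(pos) || anyNA(cm)) {
    bad <- which(is.na(pos) | is.na(cm))[1L]
    stop("unparseable line ", tab$lineno[rows[bad]], " in ", path)
  }
  genetic_map(chrom, pos, cm)
}

#' Read a genetic map in (position, rate, cumulative cM) dialect
#'
#' Some published maps are distributed per chromosome as (bp, cM/Mb rate for
#' the following interval, cumulative cM). Only the position and cumulative
#' map columns are needed; the rate column is ignored after a consistency
#' check is possible by the caller.
#'
#' @param path file path.
#' @param chrom chromosome label to assign to the markers of this file.
#' @return A \code{\link{genetic_map}} for a single chromosome.
#' @export
read_rate_map <- function(path, chrom) {
  tab <- read_map_table(path, 3L)
  f <- tab$fields
  first <- suppressWarnings(as.numeric(c(f[[1]][1], f[[1]][3])))
  start <- if (anyNA(first)) 2L else 1L
  rows <- seq(start, length(f))
  pos <- suppressWarnings(as.numeric(vapply(f[rows], `[`, character(1), 1L)))
  cm <- suppressWarnings(as.numeric(vapply(f[rows], `[`, character(1), 3L)))
  if (anyNA(pos) || anyNA(cm)) {
    bad <- which(is.na(pos) | is.na(cm))[1L]
    stop("unparseable line ", tab$lineno[rows[bad]], " in ", path)
  }
  genetic_map(rep(chrom, length(pos)), pos, cm)
}

#' Chromosome structure: lengths, centromeres, telomeres
#'
#' @param lengths named numeric vector: chromosome -> total length (bp).
#' @param centromeres data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (bp, 1-based closed intervals).
#' @param telomeres data.frame in the same layout (typically two intervals
#'   per chromosome, one at each end).
#' @return An object of class \code{chromosome_structure}.
#' @export
chromosome_structure <- function(lengths, centromeres = NULL, telomeres = NULL) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  if (is.null(centromeres)) centromeres <- empty
  if (is.null(telomeres)) telomeres <- empty
  check_ivs <- function(iv, what) {
    if (nrow(iv) == 0L) return(invisible())
    if (any(iv$start > iv$end)) stop("malformed ", what, " interval")
    len <- lengths[as.character(iv$chrom)]
    if (anyNA(len)) stop(what, " interval on chromosome without a length")
    if (any(iv$start < 1 | iv$end > len))
      stop(what, " interval outside [1, chromosome length]")
  }
  check_ivs(centromeres, "centromere")
  check_ivs(telomeres, "telomere")
  structure(list(lengths = lengths, centromeres = centromeres,
                 telomeres = telomeres), class = "chromosome_structure")
}

# BED is 0-based half-open; convert to 1-based closed on read.
read_bed_intervals <- function(path) {
  if (is.null(path) || !file.exists(path))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  f <- strsplit(trimws(lines[keep]), "[\t ]+")
  data.frame(chrom = vapply(f, `[`, character(1), 1L),
             start = as.numeric(vapply(f, `[`, character(1), 2L)) + 1,
             end = as.numeric(vapply(f, `[`, character(1), 3L)))
}

#' Read chromosome structure from plain-text files
#'
#' @param lengths_path two-column (chrom, length bp) tab-separated file.
#' @param centromeres_path,telomeres_path BED files (0-based half-open,
#'   converted to 1-based closed); either may be \code{NULL} or missing.
#' @return A \code{\link{chromosome_structure}}.
#' @export
read_chromosome_structure <- function(lengths_path, centromeres_path = NULL,
                                      telomeres_path = NULL) {
  tab <- read_map_table(lengths_path, 2L)
  f <- tab$fields
  first <- suppressWarnings(as.numeric(f[[1]][2]))
  start <- if (is.na(first)) 2L else 1L
  rows <- seq(start, length(f))
  lens <- as.numeric(vapply(f[rows], `[`, character(1), 2L))
  names(lens) <- vapply(f[rows], `[`, character(1), 1L)
  chromosome_structure(lens, read_bed_intervals(centromeres_path),
                       read_bed_intervals(telomeres_path))
}

#' Interpolated genetic position
#'
#' Linear interpolation of the cumulative genetic position at arbitrary
#' physical positions, between the nearest flanking markers. Positions outside
#' the marker span return \code{NA} (no extrapolation); an exact marker hit
#' returns that marker's cM.
#'
#' @param map a \code{\link{genetic_map}}.
#' @param chrom a single chromosome label present in the map.
#' @param pos numeric vector of physical positions (bp).
#' @return Numeric vector of genetic positions (cM), \code{NA} outside the
#'   marker span.
#' @export
genetic_position <- function(map, chrom, pos) {
  stopifnot(inherits(map, "genetic_map"), length(chrom) == 1L)
  m <- map$chroms[[as.character(chrom)]]
  if (is.null(m)) stop("unknown chromosome: ", chrom)
  if (length(m$pos) == 1L)
    return(ifelse(pos == m$pos, m$cm, NA_real_))
  stats::approx(m$pos, m$cm, xout = pos, method = "linear", rule = 1)$y
}

interval_overlap <- function(start, end, iv_start, iv_end) {
  # any of the query windows [start, end] overlapping any of the intervals
  hit <- rep(FALSE, length(start))
  for (k in seq_along(iv_start))
    hit <- hit | (start <= iv_end[k] & end >= iv_start[k])
  hit
}

interval_within <- function(start, end, iv_start, iv_end, dist) {
  # window within `dist` bp of an interval (gap <= dist), overlap included
  hit <- rep(FALSE, length(start))
  for (k in seq_along(iv_start)) {
    gap <- pmax(0, iv_start[k] - end, start - iv_end[k])
    hit <- hit | (gap <= dist)
  }
  hit
}

#' Windowed recombination rate around positions
#'
#' For each query position the rate is the genetic length of a window of
#' \code{W} bp centered on the position, divided by \code{W} in Mb, i.e.
#' cM/Mb. The window is \code{[pos - floor(W/2), pos + ceiling(W/2)]}.
#' A window is invalid, with the first failing filter recorded, when:
#' \enumerate{
#'   \item \code{window_start}: the window start is before the chromosome
#'     start (position 1);
#'   \item the window end exceeds the chromosome length (reported as
#'     \code{telomere} if a telomere interval covers the end, else
#'     \code{map_span});
#'   \item \code{centromere}: the window overlaps a centromere interval;
#'   \item \code{telomere}: the window overlaps a telomere interval;
#'   \item \code{extended_mask}: \code{extend_mask > 0} and the window comes
#'     within \code{extend_mask} bp of a centromere or telomere interval;
#'   \item \code{map_span}: either window endpoint lies outside the genetic
#'     map's marker span, so no interpolated position exists.
#' }
#'
#' @param map a \code{\link{genetic_map}}.
#' @param structure a \code{\link{chromosome_structure}}.
#' @param chrom a single chromosome label.
#' @param pos numeric vector of SNP positions (bp).
#' @param W window length in bp (default 3 Mb).
#' @param extend_mask extra masking distance in bp around centromere/telomere
#'   intervals (default 0; 5 Mb reproduces the cautious variant analysis).
#' @return data.frame with columns \code{start}, \code{end}, \code{rho}
#'   (cM/Mb, \code{NA} unless valid) and \code{status} (\code{"ok"} or the
#'   filter name).
#' @export
window_recomb_rate <- function(map, structure, chrom, pos, W = 3e6,
                               extend_mask = 0) {
  stopifnot(W > 0, extend_mask >= 0, length(chrom) == 1L)
  chrom <- as.character(chrom)
  len <- structure$lengths[chrom]
  if (is.na(len)) stop("no chromosome length for ", chrom)
  start <- pos - floor(W / 2)
  end <- pos + ceiling(W / 2)
  status <- rep("ok", length(pos))

  cen <- structure$centromeres
  cen <- cen[cen$chrom == chrom, , drop = FALSE]
  tel <- structure$telomeres
  tel <- tel[tel$chrom == chrom, , drop = FALSE]

  open <- function() status == "ok"
  status[open() & start < 1] <- "window_start"

  past <- open() & end > len
  if (any(past)) {
    in_tel <- interval_overlap(start, end, tel$start, tel$end)
    status[past & in_tel] <- "telomere"
    status[past & !in_tel] <- "map_span"
  }
  i <- open()
  status[i][interval_overlap(start[i], end[i], cen$start, cen$end)] <- "centromere"
  i <- open()
  status[i][interval_overlap(start[i], end[i], tel$start, tel$end)] <- "telomere"
  if (extend_mask > 0) {
    i <- open()
    masks <- rbind(cen, tel)
    status[i][interval_within(start[i], end[i], masks$start, masks$end,
                              extend_mask)] <- "extended_mask"
  }
  g_start <- genetic_position(map, chrom, start)
  g_end <- genetic_position(map, chrom, end)
  status[open() & (is.na(g_start) | is.na(g_end))] <- "map_span"

  rho <- rep(NA_real_, length(pos))
  ok <- status == "ok"
  rho[ok] <- (g_end[ok] - g_start[ok]) / (W / 1e6)
  data.frame(start = start, end = end, rho = rho, status = status,
             stringsAsFactors = FALSE)
}

#' Annotate a SNP panel with windowed recombination rates
#'
#' Applies \code{\link{window_recomb_rate}} chromosome by chromosome, retains
#' SNPs whose window passes all validity filters, and reports counts per
#' filter reason. Retained SNPs are in genomic order (chromosome, then
#' position) and carry a \code{rho} column.
#'
#' @param panel a \code{\link{snp_panel}}.
#' @param map a \code{\link{genetic_map}}.
#' @param structure a \code{\link{chromosome_structure}}.
#' @param W,extend_mask see \code{\link{window_recomb_rate}}.
#' @return list with elements \code{panel} (retained SNPs, with \code{rho}),
#'   \code{log} (named integer counts per status, including \code{ok}) and
#'   \code{status} (per-input-SNP status vector, in panel order).
#' @export
annotate_snps <- function(panel, map, structure, W = 3e6, extend_mask = 0) {
  stopifnot(inherits(panel, "snp_panel"))
  snps <- panel$snps
  n <- nrow(snps)
  status <- character(n)
  rho <- rep(NA_real_, n)
  for (ch in unique(snps$chrom)) {
    i <- which(snps$chrom == ch)
    w <- window_recomb_rate(map, structure, ch, snps$pos[i], W, extend_mask)
    status[i] <- w$status
    rho[i] <- w$rho
  }
  reasons <- c("ok", "window_start", "centromere", "telomere",
               "extended_mask", "map_span")
  log <- vapply(reasons, function(r) sum(status == r), integer(1))
  keep <- which(status == "ok")
  out <- subset_panel(panel, keep)
  out$snps$rho <- rho[keep]
  list(panel = out, log = log, status = status)
}
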