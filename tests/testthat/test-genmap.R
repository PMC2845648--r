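test_that("read_genetic_map parses, sorts and validates", {
  f <- write_lines_tmp(c("# deCODE-style map", "chrom\tpos\tcM",
                         "chr1\t1000000\t1.0", "chr1\t3000000\t2.5",
                         "chr1\t2000000\t2.0"))
  m <- read_genetic_map(f)
  expect_equal(names(m$chroms), "chr1")
  expect_equal(m$chroms$chr1$pos, c(1e6, 2e6, 3e6))  # sorted
  expect_equal(m$chroms$chr1$cm, c(1.0, 2.0, 2.5))

  # headerless variant parses identically
  f2 <- write_lines_tmp(c("chr1\t1000000\t1.0", "chr1\t2000000\t2.0",
                          "chr1\t3000000\t2.5"))
  expect_equal(read_genetic_map(f2), m)

  bad <- write_lines_tmp(c("chr1\t1000000\t2.0", "chr1\t2000000\t1.0"))
  expect_error(read_genetic_map(bad), "genetic position decreases")

  bad2 <- write_lines_tmp(c("chr1\t1000000\t1.0", "chr1\tnot_a_number\t2.0"))
  expect_error(read_genetic_map(bad2), "line 2")
})

test_that("read_rate_map dialect normalizes to the same map", {
  f <- write_lines_tmp(c("pos\trate\tcM", "1000000\t1.0\t1.0",
                         "2000000\t0.5\t2.0", "3000000\t0.5\t2.5"))
  m <- read_rate_map(f, "chr9")
  expect_equal(genetic_position(m, "chr9", 2.5e6), 2.25)
})

test_that("genetic_position interpolates linearly, no extrapolation", {
  m <- genetic_map(c("chr1", "chr1"), c(1e6, 2e6), c(1.0, 2.0))
  expect_equal(genetic_position(m, "chr1", 1.5e6), 1.50)
  expect_equal(genetic_position(m, "chr1", 2e6), 2.0)       # exact marker
  expect_equal(genetic_position(m, "chr1", 1.25e6), 1.25)   # 1 + 0.25*(2-1)
  expect_true(is.na(genetic_position(m, "chr1", 5e6)))      # beyond span
  expect_true(is.na(genetic_position(m, "chr1", 1)))
  expect_error(genetic_position(m, "chrZ", 1.5e6), "unknown chromosome")
})

test_that("interpolated genetic position is non-decreasing in bp", {
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample(1e6:3e7, 20))
    cm <- cumsum(runif(20, 0, 2))
    m <- genetic_map(rep("c", 20), pos, cm)
    q <- sort(runif(200, min(pos), max(pos)))
    g <- genetic_position(m, "c", q)
    expect_true(all(diff(g) >= -1e-12))
  }
})

test_that("window rate: basic value and filter cascade", {
  m <- genetic_map(rep("chr1", 2), c(5e5, 3.5e6), c(0.5, 3.5))
  st <- chromosome_structure(c(chr1 = 2e7))
  w <- window_recomb_rate(m, st, "chr1", 2e6, W = 3e6)
  expect_equal(w$rho, 1.0)   # 3 cM over 3 Mb
  expect_equal(w$status, "ok")

  # (i) window start before chromosome start
  w <- window_recomb_rate(m, st, "chr1", 1e6, W = 3e6)
  expect_equal(w$status, "window_start")
  expect_true(is.na(w$rho))

  # (ii) centromere overlap: window [1.5, 4.5] Mb vs centromere [4, 4.5] Mb
  map2 <- toy_map()
  st2 <- chromosome_structure(c(chr1 = 2e7),
    centromeres = data.frame(chrom = "chr1", start = 4e6, end = 4.5e6))
  w <- window_recomb_rate(map2, st2, "chr1", 3e6, W = 3e6)
  expect_equal(w$status, "centromere")

  # (iii) telomere overlap
  st3 <- toy_structure()
  w <- window_recomb_rate(map2, st3, "chr1", 1.9e6, W = 3e6)
  expect_equal(w$status, "telomere")

  # window end past the chromosome length, telomere interval covers the end
  w <- window_recomb_rate(map2, st3, "chr1", 1.95e7, W = 3e6)
  expect_equal(w$status, "telomere")

  # map_span: map ends before window end, no mask hit
  m_short <- genetic_map(rep("chr1", 2), c(2.1e6, 5e6), c(0, 3))
  w <- window_recomb_rate(m_short, st, "chr1", 4.5e6, W = 3e6)
  expect_equal(w$status, "map_span")

  # extended mask: valid window that comes within 5 Mb of the centromere
  st4 <- chromosome_structure(c(chr1 = 2e7),
    centromeres = data.frame(chrom = "chr1", start = 1.2e7, end = 1.25e7))
  w0 <- window_recomb_rate(map2, st4, "chr1", 7e6, W = 3e6)
  expect_equal(w0$status, "ok")
  w5 <- window_recomb_rate(map2, st4, "chr1", 7e6, W = 3e6, extend_mask = 5e6)
  expect_equal(w5$status, "extended_mask")
})

test_that("rho is invariant to collinear marker insertion and to W on a
           constant-slope map", {
  st <- chromosome_structure(c(chr1 = 2e7))
  m1 <- genetic_map(rep("chr1", 2), c(1e6, 9e6), c(1, 9))
  # insert markers exactly on the line
  m2 <- genetic_map(rep("chr1", 4), c(1e6, 3e6, 6e6, 9e6), c(1, 3, 6, 9))
  for (p in c(3.5e6, 5e6, 7e6)) {
    r1 <- window_recomb_rate(m1, st, "chr1", p, W = 3e6)$rho
    r2 <- window_recomb_rate(m2, st, "chr1", p, W = 3e6)$rho
    expect_equal(r1, r2)
    expect_equal(r1, 1.0)
    # halving W leaves rho unchanged where the slope is constant
    expect_equal(window_recomb_rate(m1, st, "chr1", p, W = 1.5e6)$rho, r1)
  }
  # odd W: start offset rounds down, end offset up; window length exactly W
  w <- window_recomb_rate(m1, st, "chr1", 5e6, W = 3e6 + 1)
  expect_equal(w$end - w$start, 3e6 + 1)
})

test_that("annotate_snps filters, logs and is idempotent", {
  map <- toy_map()
  st <- toy_structure()  # centromere [9, 9.5] Mb, telomeres 0.5 Mb
  pos <- c(1e6,            # window_start (start < 1)
           8e6,            # centromere ([6.5, 9.5] overlaps)
           5e6, 6e6, 1.2e7, 1.3e7, 1.4e7, 1.5e7, 1.6e7, 1.7e7)  # ok
  alt <- matrix(5L, length(pos), 2, dimnames = list(NULL, c("a", "b")))
  nchr <- matrix(10L, length(pos), 2, dimnames = list(NULL, c("a", "b")))
  panel <- toy_panel(alt, nchr, pos = pos)
  ann <- annotate_snps(panel, map, st)
  expect_equal(nrow(ann$panel$snps), 8)
  expect_equal(unname(ann$log[c("window_start", "centromere")]), c(1L, 1L))
  expect_equal(unname(ann$log["ok"]), 8L)
  expect_equal(ann$panel$snps$rho, rep(1.0, 8))
  expect_false(is.unsorted(ann$panel$snps$pos))

  # idempotence: re-annotating the retained set drops nothing
  ann2 <- annotate_snps(ann$panel, map, st)
  expect_equal(ann2$panel$snps$pos, ann$panel$snps$pos)
  expect_equal(unname(ann2$log["ok"]), 8L)

  # empty input
  ann0 <- annotate_snps(subset_panel(panel, integer(0)), map, st)
  expect_equal(nrow(ann0$panel$snps), 0)
  expect_true(all(ann0$log == 0))
})

test_that("chromosome structure readers convert BED coordinates", {
  lens <- write_lines_tmp(c("chr1\t20000000"))
  cen <- write_lines_tmp(c("chr1\t9000000\t9500000"))
  tel <- write_lines_tmp(c("chr1\t0\t500000", "chr1\t19500000\t20000000"))
  st <- read_chromosome_structure(lens, cen, tel)
  expect_equal(st$centromeres$start, 9000001)  # 0-based start + 1
  expect_equal(st$centromeres$end, 9500000)
  expect_equal(st$telomeres$start, c(1, 19500001))
})
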