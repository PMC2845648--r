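test_that("block scheme and resampling basics", {
  expect_equal(make_blocks(10, 1)$n_blocks, 10L)
  expect_equal(make_blocks(10, 10)$n_blocks, 1L)
  expect_equal(make_blocks(5, 2)$n_blocks, 4L)
  expect_error(make_blocks(5, 6), "block length")

  # L = n: the only block is the identity
  set.seed(1)
  expect_equal(resample_indices(make_blocks(8, 8)), 1:8)

  # determinism under a fixed seed
  set.seed(99); i1 <- resample_indices(make_blocks(1000, 50))
  set.seed(99); i2 <- resample_indices(make_blocks(1000, 50))
  expect_identical(i1, i2)
  expect_length(i1, 1000)
  expect_true(all(i1 >= 1 & i1 <= 1000))

  # blocks are contiguous runs: within-block steps are +1
  steps <- diff(i1)
  expect_true(all(steps[-seq(50, 950, by = 50)] == 1))

  # L = 1 is the iid bootstrap over indices: all indices reachable
  set.seed(7)
  i3 <- resample_indices(make_blocks(20, 1))
  expect_true(all(i3 %in% 1:20))
})

test_that("z_test reproduces published hypothesis tests", {
  # global b1 = -0.0049 +/- 0.0007 -> P = 2.6e-12
  expect_equal(z_test(-0.0049, 0.0007)$p, 2.6e-12, tolerance = 0.02)
  # t-statistic -6.0926 +/- 2.1758 -> P = 0.0051
  expect_equal(z_test(-6.0926, 2.1758)$p, 0.0051, tolerance = 0.01)
  expect_equal(z_test(0, 1)$p, 1)
  # two-sided symmetry
  expect_equal(z_test(-0.3, 0.1)$p, z_test(0.3, 0.1)$p)
  # sidedness
  expect_equal(z_test(-1, 1, "less")$p, pnorm(-1))
  expect_equal(z_test(-1, 1, "greater")$p, pnorm(1))
  expect_error(z_test(1, 0), "positive")
})

test_that("compare_analyses reproduces published comparisons", {
  # steeper b1 in coding SNPs: one-sided P = 0.076
  expect_equal(compare_analyses(-0.0081, 0.0022, -0.0048, 0.0007, "less")$p,
               0.076, tolerance = 0.01)
  # b1/b0 between population pairs: two-sided P = 0.004 and 0.021
  expect_equal(compare_analyses(-0.0499, 0.0064, -0.0185, 0.0088)$p,
               0.004, tolerance = 0.03)
  expect_equal(compare_analyses(-0.0430, 0.0059, -0.0185, 0.0088)$p,
               0.021, tolerance = 0.02)
  # identical means: one-sided p = 0.5
  expect_equal(compare_analyses(0.1, 0.01, 0.1, 0.02, "less")$p, 0.5)
  expect_error(compare_analyses(1, 0, 1, 1), "positive")
})

test_that("bootstrap over identical SNP copies has zero spread", {
  n <- 500
  alt <- cbind(a = rep(3L, n), b = rep(7L, n))
  nchr <- matrix(10L, n, 2, dimnames = list(NULL, c("a", "b")))
  pan <- toy_panel(alt, nchr, rho = rep(1.5, n))
  sch <- make_bins(pan$snps$rho, 5, pan$snps$chrom, pan$snps$pos)
  bs <- bootstrap_framework(pan, sch, B = 50, L = 20, seed = 4)
  expect_true(all(bs$series[[1]]$se < 1e-12))
})

test_that("bootstrap framework is deterministic and recomputable", {
  pan <- bn_panel(3000, 0.12, rho = runif(3000, 0.1, 4), seed = 61)
  b1 <- bootstrap_framework(pan, B = 40, L = 50, seed = 17)
  b2 <- bootstrap_framework(pan, B = 40, L = 50, seed = 17)
  expect_identical(b1$series$global$replicates, b2$series$global$replicates)
  b3 <- bootstrap_framework(pan, B = 40, L = 50, seed = 18)
  expect_false(identical(b1$series$global$replicates,
                         b3$series$global$replicates))
  # summary is recomputable from the stored replicate values
  m <- b1$series$global
  expect_equal(unname(colMeans(m$replicates)), unname(m$mean))
  expect_equal(unname(apply(m$replicates, 2, sd)), unname(m$se))
  # series: three pairs plus global
  expect_setequal(names(b1$series), c("p1-p2", "p1-p3", "p2-p3", "global"))
})

test_that("null panel: mean b1 consistent with zero", {
  pan <- bn_panel(20000, 0.12, rho = runif(20000, 0.1, 4), seed = 71)
  bs <- bootstrap_framework(pan, B = 200, L = 1, seed = 5)
  g <- bs$series$global
  # iid panel, L = 1: the z-score against 0 should be ordinary
  expect_lt(abs(g$mean[["b1"]] / g$se[["b1"]]), 4)
})

test_that("with L = 1 the MBB matches an iid bootstrap oracle", {
  # SE of per-bin FST under L = 1 vs a hand-rolled iid bootstrap
  pan <- bn_panel(2000, 0.12, rho = runif(2000, 0.1, 4), seed = 81)
  sch <- make_bins(pan$snps$rho, 4, pan$snps$chrom, pan$snps$pos)
  comp <- recfst:::panel_pair_components(pan, populations(pan))
  se_mbb <- recfst:::mbb_bin_fst_se(comp$N, comp$D, sch$bin, 4,
                                    B = 400, L = 1, seed = 6)
  # independent oracle: plain sample() bootstrap of the same statistic
  set.seed(1234)
  oracle <- replicate(400, {
    idx <- sample.int(2000, replace = TRUE)
    f <- vapply(1:4, function(b) {
      i <- idx[sch$bin[idx] == b]
      mean(colSums(comp$N[i, , drop = FALSE]) /
             colSums(comp$D[i, , drop = FALSE]))
    }, numeric(1))
    f
  })
  se_iid <- apply(oracle, 1, sd)
  expect_equal(se_mbb, se_iid, tolerance = 0.25)  # Monte-Carlo tolerance
})

test_that("quadratic model records b2 and its t-statistic", {
  pan <- bn_panel(3000, function(r) pmax(0.05, 0.1 + 0.02 * r - 0.01 * r^2),
                  rho = runif(3000, 0.1, 4), seed = 91)
  bs <- bootstrap_framework(pan, B = 30, L = 25, seed = 7,
                            model = "quadratic")
  g <- bs$series$global
  expect_true(all(c("b2", "t_b2") %in% colnames(g$replicates)))
  expect_lt(g$mean[["b2"]], 0)  # planted concavity
})

test_that("bootstrap_z wraps the z-test on a summary", {
  pan <- bn_panel(3000, function(r) 0.2 - 0.03 * r,
                  rho = runif(3000, 0.1, 4), seed = 95)
  bs <- bootstrap_framework(pan, B = 60, L = 25, seed = 8)
  zt <- bootstrap_z(bs, "global", "b1")
  expect_equal(zt$z, zt$mean / zt$se)
  expect_lt(zt$mean, 0)
  expect_error(bootstrap_z(bs, "nope", "b1"), "unknown series")
})
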