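test_that("reference ranges interpolate order statistics linearly", {
  rr <- reference_range(1:40)
  expect_equal(rr$p2_5, 1.975)   # position 1 + 39 * 0.025
  expect_equal(rr$p97_5, 39.025)
  expect_equal(rr$median, 20.5)
  expect_equal(rr$n, 40)
  cc <- reference_range(rep(7, 10))
  expect_equal(c(cc$p2_5, cc$median, cc$p97_5), c(7, 7, 7))
  expect_error(reference_range(c(1, NA)), "at least 2")
})

test_that("reference ranges are equivariant under positive affine maps", {
  set.seed(3)
  x <- rlnorm(200, 6, 0.4)
  r1 <- reference_range(x)
  for (ab in list(c(2, 0), c(0.5, 100), c(3.7, -5))) {
    r2 <- reference_range(ab[1] * x + ab[2])
    expect_equal(r2$median, ab[1] * r1$median + ab[2])
    expect_equal(r2$p2_5, ab[1] * r1$p2_5 + ab[2])
    expect_equal(r2$p97_5, ab[1] * r1$p97_5 + ab[2])
  }
})

test_that("normal 95% central range is recovered on a large sample", {
  set.seed(12)
  rr <- reference_range(rnorm(1e5))
  expect_equal(rr$p2_5, -1.96, tolerance = 0.02)
  expect_equal(rr$p97_5, 1.96, tolerance = 0.02)
})

test_that("Friedman omnibus is null on identical columns and detects shifts", {
  set.seed(21)
  base <- rnorm(20, 100, 15)
  tab <- data.frame(a = base, b = base, c = base)
  cmp <- compare_paired(tab, c("a", "b", "c"))
  expect_equal(cmp$p_value, 1)
  expect_true(all(cmp$pairwise$p_adjusted > 0.99))

  shifted <- data.frame(a = base, b = base + 10, c = base + 20)
  cmp2 <- compare_paired(shifted, c("a", "b", "c"))
  expect_lt(cmp2$p_value, 0.001)
  # permutation-null oracle: the observed chi-square is beyond anything the
  # within-block permutation distribution produces
  stat_of <- function(m) unname(stats::friedman.test(m)$statistic)
  obs <- stat_of(as.matrix(shifted))
  perm <- replicate(2000, {
    stat_of(t(apply(as.matrix(shifted), 1, sample)))
  })
  expect_lt(mean(perm >= obs), 0.001)
})

test_that("Dunn post-hoc after Friedman flags only truly different pairs", {
  set.seed(22)
  base <- rnorm(25, 100, 10)
  tab <- data.frame(a = base, b = base, c = base + 30)
  cmp <- compare_paired(tab, c("a", "b", "c"))
  pw <- cmp$pairwise
  ab <- pw$p_adjusted[pw$group1 == "a" & pw$group2 == "b"]
  expect_gt(ab, 0.99)
  expect_lt(max(pw$p_adjusted[pw$group2 == "c" | pw$group1 == "c"]), 0.01)
  # adjusted never below unadjusted
  expect_true(all(pw$p_adjusted >= pw$p_unadjusted - 1e-12))
})

test_that("paired comparison drops incomplete rows and reports the count", {
  tab <- data.frame(a = c(1:10, NA), b = c(2:11, 5), c = c(3:12, 6))
  cmp <- compare_paired(tab, c("a", "b", "c"))
  expect_equal(cmp$n, 10)
  expect_equal(cmp$n_dropped, 1)
  expect_error(compare_paired(tab, c("a", "b")), ">= 3")
})

test_that("Kruskal-Wallis group comparison behaves at both extremes", {
  set.seed(31)
  x <- rnorm(90)
  g <- rep(c("men", "women_no_oc", "women_oc"), each = 30)
  null_cmp <- compare_groups(x, g)
  expect_gt(null_cmp$p_value, 0.001)  # exchangeable data: usually null
  x2 <- x + ifelse(g == "women_oc", 5, 0)  # 5 SD shift
  cmp2 <- compare_groups(x2, g)
  expect_lt(cmp2$p_value, 1e-4)
  pw <- cmp2$pairwise
  expect_lt(min(pw$p_adjusted[pw$group1 == "women_oc" | pw$group2 == "women_oc"]),
            0.001)
  # identical singleton-distribution groups: H = 0
  h0 <- compare_groups(rep(c(5, 5), each = 4), rep(c("a", "b"), each = 4))
  expect_equal(h0$statistic, 0)
  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")), ">= 2")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(41)
  x <- rlnorm(60, 5, 0.5)
  g <- rep(c("a", "b", "c"), 20)
  for (f in list(log, sqrt, function(v) v^3)) {
    expect_equal(compare_groups(f(x), g)$statistic,
                 compare_groups(x, g)$statistic)
  }
  tab <- data.frame(a = x[1:20], b = x[21:40], c = x[41:60])
  expect_equal(compare_paired(log(tab), c("a", "b", "c"))$statistic,
               compare_paired(tab, c("a", "b", "c"))$statistic)
})

test_that("Dunn z-statistics match the textbook formula on a small example", {
  # direct computation, independent of the package internals
  x <- c(12, 15, 11, 8, 30, 25, 28, 31, 18, 20, 17, 22)
  g <- rep(c("lo", "hi", "mid"), each = 4)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  N <- 12
  v0 <- N * (N + 1) / 12  # no ties
  z_hi_lo <- (rbar[["hi"]] - rbar[["lo"]]) / sqrt(v0 * (1 / 4 + 1 / 4))
  cmp <- compare_groups(x, g)
  pw <- cmp$pairwise
  got <- pw$z[pw$group1 == "hi" & pw$group2 == "lo"]
  expect_equal(abs(got), abs(z_hi_lo), tolerance = 1e-12)
  expect_equal(pw$p_unadjusted, 2 * pnorm(-abs(pw$z)), tolerance = 1e-12)
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_unadjusted), tolerance = 1e-12)
})

test_that("Shapiro-Wilk wrapper separates normal from exponential samples", {
  set.seed(51)
  norm_p <- replicate(100, normality_check(rnorm(100))$p_value)
  expect_gte(mean(norm_p > 0.05), 0.90)
  exp_p <- replicate(100, normality_check(rexp(100))$p_value)
  expect_gte(mean(exp_p < 0.05), 0.95)
  expect_error(normality_check(c(1, 2)), "3 <= n")
  deg <- normality_check(rep(1, 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$statistic))
})
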