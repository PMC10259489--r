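test_that("KS statistic matches brute-force ECDF enumeration", {
  ## identical samples
  expect_equal(ksTwoSample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  ## disjoint supports
  expect_equal(ksTwoSample(c(1, 2, 3), c(4, 5, 6))$statistic, 1)
  ## interleaved: ECDFs evaluated at pooled points differ by at most 1/2
  expect_equal(ksTwoSample(c(1, 3), c(2, 4))$statistic, 0.5)
  ## random case against a literal double-loop oracle
  set.seed(50)
  x <- rnorm(23); y <- rnorm(31, 0.4)
  pts <- sort(c(x, y))
  d_brute <- max(vapply(pts, function(p) {
    abs(mean(x <= p) - mean(y <= p))
  }, numeric(1)))
  expect_equal(ksTwoSample(x, y)$statistic, d_brute)
  ## ties are handled through the pooled unique points
  expect_equal(ksTwoSample(c(1, 1, 2), c(1, 2, 2))$statistic, 1 / 3)
  expect_error(ksTwoSample(numeric(0), 1:3), "non-empty")
})

test_that("KS is symmetric, bounded, and monotone-transform invariant", {
  set.seed(51)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(20, sd = 2)
    d1 <- ksTwoSample(x, y)$statistic
    d2 <- ksTwoSample(y, x)$statistic
    expect_equal(d1, d2)
    expect_gte(d1, 0); expect_lte(d1, 1)
    d3 <- ksTwoSample(exp(x), exp(y))$statistic
    expect_equal(d1, d3)
  }
})

test_that("KS p-values agree with stats::ks.test in both regimes", {
  set.seed(52)
  x <- rnorm(30); y <- rnorm(40, 0.5)  # 1200 <= 1e4: exact path
  mine <- ksTwoSample(x, y)
  ref <- stats::ks.test(x, y)
  expect_equal(mine$method, "exact")
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  x2 <- rnorm(200); y2 <- rnorm(200, 0.2)  # asymptotic path
  mine2 <- ksTwoSample(x2, y2)
  ref2 <- stats::ks.test(x2, y2, exact = FALSE)
  expect_equal(mine2$method, "asymptotic")
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-4)
})

test_that("Spearman rho equals Pearson on average ranks, ties included", {
  expect_equal(spearmanRho(1:6, 2 * (1:6) + 3), 1)
  expect_equal(spearmanRho(1:6, -(1:6)^3), -1)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 4)
  ## hand rank computation: rx = 1, 2.5, 2.5, 4; ry = 2, 1, 3.5, 3.5
  rx <- c(1, 2.5, 2.5, 4); ry <- c(2, 1, 3.5, 3.5)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanRho(x, y), brute)
  expect_equal(spearmanRho(x, y), stats::cor(x, y, method = "spearman"))
  expect_warning(out <- spearmanRho(rep(1, 5), 1:5), "rank variance")
  expect_true(is.na(out))
  expect_error(spearmanRho(1:3, 1:4), "paired")
})

test_that("condition comparisons detect shifts and variance changes", {
  ## identical condition: D = 0, mean diff 0, variance ratio 1
  cells <- data.frame(condition = rep(c("WT", "SAME"), each = 50),
                      circularity = rep(seq(0.7, 0.95, length.out = 50), 2))
  st <- compareConditions(cells, "circularity", reference = "WT")
  expect_equal(st$ks_D, 0)
  expect_equal(st$mean_diff, 0)
  expect_equal(st$variance_ratio, 1)
  expect_error(compareConditions(cells, "circularity", reference = "nope"),
               "unknown reference")
  ## power: a -0.1 circularity shift at n = 500 is detected (p < 0.01)
  ## in essentially every draw
  set.seed(53)
  hits <- 0L
  for (i in 1:50) {
    cc <- data.frame(
      condition = rep(c("WT", "MUT"), each = 500),
      circularity = c(rnorm(500, 0.88, 0.05), rnorm(500, 0.78, 0.05)))
    st <- compareConditions(cc, "circularity", reference = "WT")
    hits <- hits + (st$p_value < 0.01)
  }
  expect_equal(hits, 50L)
  ## equal means but doubled SD: variance ratio ~ 4, detected by KS
  set.seed(54)
  cc2 <- data.frame(
    condition = rep(c("WT", "VAR"), each = 500),
    area = c(rnorm(500, 2500, 450), rnorm(500, 2500, 900)))
  st2 <- compareConditions(cc2, "area", reference = "WT")
  expect_equal(st2$variance_ratio, 4, tolerance = 0.35)
  expect_lt(st2$p_value, 0.01)
})
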