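test_that("median polish handles constant and purely additive tables exactly", {
  x <- matrix(7, 5, 6)
  f <- medianPolish(x)
  expect_equal(f@overall, 7)
  expect_equal(f@row, rep(0, 5))
  expect_equal(f@col, rep(0, 6))
  expect_true(all(abs(f@residuals) < 1e-12))
  ## constructed additive table: residuals vanish
  r <- rnorm(8); cc <- rnorm(10)
  y <- 3 + outer(r, rep(1, 10)) + outer(rep(1, 8), cc)
  f2 <- medianPolish(y)
  expect_true(all(abs(f2@residuals) < 1e-9))
  ## decomposition reproduces every cell exactly
  rebuilt <- f2@overall + outer(f2@row, rep(1, 10)) + outer(rep(1, 8), f2@col)
  expect_equal(rebuilt + f2@residuals, y, tolerance = 1e-12)
})

test_that("a single outlier stays in the residuals of the pure polish", {
  x <- matrix(1, 3, 3)
  x[2, 2] <- 11
  f <- medianPolish(x)
  expect_equal(f@residuals[2, 2], 10, tolerance = 1e-9)
  expect_true(all(abs(f@residuals[-5]) < 1e-9))
  ## independent long-iteration oracle: stats::medpolish
  set.seed(20)
  y <- matrix(rnorm(12 * 15), 12, 15)
  y[3, 4] <- y[3, 4] + 10
  mine <- medianPolish(y, max_iter = 1000, tol = 1e-12, init = "zero")
  oracle <- stats::medpolish(y, maxiter = 1000, eps = 1e-12,
                             trace.iter = FALSE)
  expect_equal(mine@residuals, oracle$residuals, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(mine@overall, oracle$overall, tolerance = 1e-6)
  ## the LS-initialized fit agrees with the classical one up to the additive
  ## row+column ambiguity of median-polish fixed points, with zero
  ## row/column medians of its own
  mine2 <- medianPolish(y, max_iter = 1000, tol = 1e-12)
  d <- mine2@residuals - oracle$residuals
  d <- sweep(d, 1, rowMeans(d)); d <- sweep(d, 2, colMeans(d))
  expect_lt(max(abs(d)), 1e-6)
  expect_lt(max(abs(apply(mine2@residuals, 1, stats::median))), 1e-6)
  ## and it keeps the spiked cell fully in its residual
  expect_lt(abs(mine2@residuals[3, 4] - oracle$residuals[3, 4]), 0.01)
})

test_that("masked cells are scored but never inform the fit", {
  x <- 2 + outer(1:6, rep(1, 8)) + outer(rep(1, 6), seq(0, 0.7, 0.1))
  mask <- matrix(TRUE, 6, 8)
  mask[, 8] <- FALSE
  x[, 8] <- x[, 8] + 100  # wild control column must not perturb the fit
  f <- medianPolish(x, mask)
  expect_true(all(abs(f@residuals[, 1:7]) < 1e-9))
  ## control residuals report value - fit: the spike stays visible, and the
  ## unfitted column offset is constant across rows
  expect_true(all(f@residuals[, 8] > 99))
  expect_lt(diff(range(f@residuals[, 8])), 1e-9)
  expect_true("col8" %in% f@degenerate)
})

test_that("B-scores are invariant to additive artifacts and to scale", {
  set.seed(21)
  x <- matrix(rnorm(16 * 24), 16, 24)
  mask <- matrix(TRUE, 16, 24); mask[, 24] <- FALSE
  b <- bscorePlate(x, mask)
  x2 <- x + outer(rnorm(16), rep(1, 24)) + outer(rep(1, 16), rnorm(24))
  expect_lt(max(abs((bscorePlate(x2, mask) - b)[mask])), 1e-9)
  expect_lt(max(abs((bscorePlate(2 * x, mask) - b)[mask])), 1e-9)
  ## formula oracle: residual / (1.4826 * MAD over library residuals)
  fit <- medianPolish(x, mask)
  expect_equal(b, fit@residuals / stats::mad(fit@residuals[mask]),
               tolerance = 1e-12)
  ## an outlier stands out while the bulk stays near zero
  x3 <- x2
  x3[5, 5] <- x3[5, 5] + 10
  b3 <- bscorePlate(x3, mask)
  expect_gt(b3[5, 5], 5)
  ## degenerate plate errors unless the fallback is requested
  const <- matrix(1, 16, 24)
  expect_error(bscorePlate(const, mask, plate_id = "P9"), "P9")
  expect_silent(bscorePlate(const, mask, fallback_residuals = TRUE))
})

test_that("robust Z matches hand-computed median/MAD and self-standardizes", {
  v <- c(1, 2, 3, 4, 100)
  z <- robustZ(v, v)
  ## median 3, raw MAD 1 -> Z(100) = 97 / 1.4826
  expect_equal(z[5], 97 / 1.4826, tolerance = 1e-12)
  expect_equal(z[3], 0)
  expect_error(robustZ(1, c(2, 3)), "at least 3")
  expect_error(robustZ(1, rep(5, 10)), "degenerate")
  ## post-hoc normalization contract on a simulated replicate
  s <- smallScreen()
  ws <- wellScores(s$scores)
  for (r in 1:2) {
    zz <- ws$z[ws$replicate == r & ws$role == "library" &
               ws$feature == "circularity"]
    expect_lt(abs(stats::median(zz)), 1e-9)
    expect_lt(abs(stats::mad(zz) - 1), 1e-9)
  }
})

test_that("replicate merging averages what exists and flags what does not", {
  m <- mergeReplicates(cbind(c(-2, 1.2, NA), c(-1, NA, NA)))
  expect_equal(m$z_mean, c(-1.5, 1.2, NA))
  expect_equal(m$n_replicates, c(2, 1, 0))
  expect_equal(m$single_replicate, c(FALSE, TRUE, FALSE))
  ## brute-force groupby oracle on the scored screen
  s <- smallScreen()
  ol <- oligoScores(s$scores)
  expect_equal(ol$z_mean, rowMeans(cbind(ol$z_rep1, ol$z_rep2), na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("the full chain is invariant to affine rescaling of the input", {
  s <- smallScreen()
  wells <- s$wells
  wells2 <- wells
  wells2$circularity <- 3.5 * wells2$circularity + 2
  z1 <- oligoScores(scoreScreen(wells, features = "circularity",
                                include_cellcount = FALSE))
  z2 <- oligoScores(scoreScreen(wells2, features = "circularity",
                                include_cellcount = FALSE))
  expect_equal(z1$z_mean, z2$z_mean, tolerance = 1e-5)
})

test_that("null screens are calibrated against their own empirical spread", {
  lay <- buildLibraryLayout(120, seed = 30)
  tr <- sampleGroundTruth(lay, seed = 30)
  cells <- simulateCells(lay, tr, replicates = 1:2)
  sc <- scoreScreen(aggregateWells(cells, lay))
  ol <- oligoScores(sc)
  zm <- ol$z_mean[ol$feature == "circularity"]
  expect_lt(abs(stats::median(zm)), 0.1)
  ## averaging two standardized replicates tightens the spread toward
  ## 1/sqrt(2); Monte-Carlo tolerance at 360 oligos
  expect_lt(abs(stats::mad(zm) - 1 / sqrt(2)), 0.12)
  ## plate gradients do not move hit calls at large designed effects
  tr_fx <- sampleGroundTruth(
    lay, hit_spec = list(circularity = list(n = 8, effect = -3)),
    plate_effect_spec = list(row_amp = 0, col_amp = 0, edge = 0), seed = 31)
  tr_grad <- initialize(tr_fx,
    plate_row_amp = tr_fx@plate_row_amp + 1,
    plate_col_amp = tr_fx@plate_col_amp - 0.8)
  calls_flat <- callHits(scoreScreen(aggregateWells(
    simulateCells(lay, tr_fx, replicates = 1:2), lay)))
  calls_grad <- callHits(scoreScreen(aggregateWells(
    simulateCells(lay, tr_grad, replicates = 1:2), lay)))
  expect_setequal(hitList(calls_flat, "shape_hit"),
                  hitList(calls_grad, "shape_hit"))
})
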