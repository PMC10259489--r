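test_that("gene medians take the middle oligo and flag thin evidence", {
  ol <- data.frame(
    gene_id = rep(c("gA", "gB", "gC", "gD"), times = c(3, 3, 2, 1)),
    oligo_id = paste0("o", 1:9),
    feature = "circularity",
    z_mean = c(-2.0, -1.6, -0.3,   -2.0, -0.3, -0.1,   -2.5, -0.4,   1.0))
  gm <- geneMedians(ol)
  expect_equal(gm$median_z[gm$gene_id == "gA"], -1.6)
  expect_equal(gm$median_z[gm$gene_id == "gB"], -0.3)
  ## even count: mean of the middle pair
  expect_equal(gm$median_z[gm$gene_id == "gC"], -1.45)
  expect_equal(gm$n_oligos, c(3, 3, 2, 1))
})

test_that("median rule is equivalent to the explicit two-of-three rule", {
  set.seed(40)
  z <- matrix(rnorm(3000, sd = 1.2), ncol = 3)
  med <- apply(z, 1, stats::median)
  two_of_three <- rowSums(z <= -1.5) >= 2
  expect_identical(med <= -1.5, two_of_three)
  ## and on the upper side
  expect_identical(med >= 1.5, rowSums(z >= 1.5) >= 2)
})

test_that("directional thresholds are inclusive and class-specific", {
  mk <- function(circ, area, lac, lb1, cc = 0) {
    do.call(rbind, lapply(seq_along(circ), function(i) data.frame(
      gene_id = paste0("g", i), oligo_id = paste0("g", i, "_o", 1:3),
      feature = rep(c("circularity", "area", "laminAC_mean", "laminB1_mean",
                      "cellcount"), each = 3),
      z_mean = rep(c(circ[i], area[i], lac[i], lb1[i], cc), each = 3))))
  }
  ol <- mk(circ = c(-1.5, -1.49, 0), area = c(0, 1.5, -1.6),
           lac = c(0, 0, -1.5), lb1 = c(-2, 0, 0))
  calls <- callHits(ol)
  cal <- geneCalls(calls)
  ## boundary: -1.5 exactly is a hit ("or less")
  expect_true(cal$shape_hit[cal$gene_id == "g1"])
  expect_false(cal$shape_hit[cal$gene_id == "g2"])
  expect_true(cal$size_up[cal$gene_id == "g2"])
  expect_false(cal$size_down[cal$gene_id == "g2"])
  expect_true(cal$size_down[cal$gene_id == "g3"])
  expect_true(cal$laminAC_down[cal$gene_id == "g3"])
  expect_true(cal$laminB1_down[cal$gene_id == "g1"])
  ## increased circularity is not a shape hit unless two-sided is requested
  ol_up <- mk(circ = 2, area = 0, lac = 0, lb1 = 0)
  expect_length(hitList(callHits(ol_up), "shape_hit"), 0)
  expect_length(hitList(callHits(ol_up, two_sided_shape = TRUE),
                        "shape_hit"), 1)
})

test_that("viability exclusion removes but does not erase cytotoxic hits", {
  ol <- do.call(rbind, lapply(c(gHit = -0.2, gTox = -2.5), function(ccz) {
    g <- if (ccz < -2) "gTox" else "gHit"
    data.frame(gene_id = g, oligo_id = paste0(g, "_o", 1:3),
               feature = rep(c("circularity", "area", "laminAC_mean",
                               "laminB1_mean", "cellcount"), each = 3),
               z_mean = rep(c(-3, 0, 0, 0, ccz), each = 3))
  }))
  calls <- callHits(ol)
  cal <- geneCalls(calls)
  expect_true(all(cal$shape_hit))  # the flag survives for audit
  expect_equal(hitList(calls, "shape_hit"), "gHit")
  expect_true(cal$excluded_cytotoxic[cal$gene_id == "gTox"])
  ## boundary is inclusive: exactly -2 is excluded
  relaxed <- applyViabilityFilter(calls, threshold = -3)
  expect_setequal(hitList(relaxed, "shape_hit"), c("gHit", "gTox"))
})

test_that("recovery evaluation matches designed truth on a simulated screen", {
  s <- smallScreen()
  calls <- callHits(s$scores)
  rec <- evaluateRecovery(calls, s$truth)
  ## designed shape hits at -4 SD are all recovered
  expect_equal(rec$recall[rec$class == "shape_hit"], 1)
  expect_equal(rec$recall[rec$class == "size_up"], 1)
  ## all designed cytotoxic genes are flagged and excluded from lists
  cal <- geneCalls(calls)
  cyto <- cytotoxicGenes(s$truth)
  expect_true(all(cal$excluded_cytotoxic[cal$gene_id %in% cyto]))
  for (cls in c("shape_hit", "size_up", "size_down")) {
    expect_length(intersect(hitList(calls, cls), cyto), 0)
  }
  ## exclusion soundness: nothing with cell-count median <= -2 in any list
  bad <- cal$gene_id[!is.na(cal$median_cellcount) & cal$median_cellcount <= -2]
  expect_length(intersect(hitList(calls, "shape_hit"), bad), 0)
  ## pure size hits are not called as shape hits
  ge <- geneEffects(s$truth)
  size_only <- rownames(ge)[ge[, "area"] != 0 & ge[, "circularity"] == 0]
  expect_length(intersect(hitList(calls, "shape_hit"), size_only), 0)
})

test_that("screen comparison reports Spearman rho and hit overlap", {
  s <- smallScreen()
  calls <- callHits(s$scores)
  cmp <- compareScreens(calls, calls)
  expect_equal(cmp@rho, 1)
  expect_setequal(cmp@hits_both, hitList(calls, "shape_hit"))
  expect_length(cmp@hits_a_only, 0)
  ## sign-flipped scores give rho = -1
  flipped <- initialize(calls, calls = within(geneCalls(calls), {
    median_circularity <- -median_circularity
  }))
  expect_equal(compareScreens(calls, flipped)@rho, -1)
  ## disjoint gene sets are an error
  other <- initialize(calls, calls = within(geneCalls(calls), {
    gene_id <- paste0(gene_id, "_x")
  }))
  expect_error(compareScreens(calls, other), "shared")
})

test_that("effect size increases never reduce the recovered |median Z|", {
  lay <- denseLayout(24, seed = 44)
  med_at <- function(eff, seed) {
    tr <- sampleGroundTruth(
      lay, hit_spec = list(circularity = list(n = 2, effect = eff)),
      cells_mean = 60, cells_dispersion = 15, seed = seed)
    cells <- simulateCells(lay, tr, replicates = 1:2)
    calls <- geneCalls(callHits(scoreScreen(aggregateWells(cells, lay))))
    des <- rownames(geneEffects(tr))[geneEffects(tr)[, "circularity"] != 0]
    mean(abs(calls$median_circularity[calls$gene_id %in% des]))
  }
  ## in expectation over seeds: the robust scale is slightly inflated by its
  ## own hits at toy scale, so single draws can saturate
  m <- rowMeans(vapply(c(44, 45, 46, 47),
                       function(s) vapply(c(-1, -2, -4), med_at, numeric(1),
                                          seed = s),
                       numeric(3)))
  expect_true(all(diff(m) > 0))
})
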