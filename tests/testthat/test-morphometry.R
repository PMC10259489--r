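test_that("circularity formula is exact, directional, and guarded", {
  r <- c(1, 5, 50)
  expect_equal(circularity(pi * r^2, 2 * pi * r), rep(1, 3))
  ## same area, larger perimeter -> less round
  expect_lt(circularity(100, 40), circularity(100, 36))
  ## ellipse a=20, b=10 against the elliptic-integral oracle
  P <- ellipsePerimeter(20, 10)
  expect_equal(circularity(200 * pi, P), 0.8412, tolerance = 1e-4)
  expect_error(circularity(0, 10), "positive")
  expect_error(circularity(10, -1), "positive")
})

test_that("Crofton perimeter is nearly unbiased on digital disks", {
  for (r in c(25, 30, 50)) {
    n <- 2 * r + 20
    m <- outer(seq_len(n), seq_len(n),
               function(i, j) (i - n / 2)^2 + (j - n / 2)^2 <= r^2)
    ## discretization bias shrinks with radius; ~1.2% at r = 25
    expect_lt(abs(croftonPerimeter(m) / (2 * pi * r) - 1), 0.015)
  }
  expect_lt(abs(croftonPerimeter(
    outer(1:120, 1:120, function(i, j) (i - 60)^2 + (j - 60)^2 <= 2500)) /
    (2 * pi * 50) - 1), 0.005)
})

test_that("segmentation thresholds, fills, filters and excludes borders", {
  expect_equal(max(segmentNuclei(matrix(0, 50, 50))), 0)
  expect_error(segmentNuclei(array(1, c(4, 4, 2))), "2-D")
  ## three disks, one intersecting the border -> two labels
  shs <- list(nucleusShape(c(30, 30), 12, 12),
              nucleusShape(c(80, 40), 12, 12),
              nucleusShape(c(5, 80), 12, 12))
  fld <- renderField(shs, image_size = c(110, 110), noise_sd = 10, seed = 3)
  mask <- segmentNuclei(fld$images$dapi)
  expect_equal(max(mask), 2)
  expect_equal(sum(fld$truth$on_border), 1)
  ## border invariant: no labeled pixels on boundary rows/columns
  expect_true(all(mask[1, ] == 0) && all(mask[nrow(mask), ] == 0))
  expect_true(all(mask[, 1] == 0) && all(mask[, ncol(mask)] == 0))
  ## labels contiguous, disjoint, areas bounded by the image
  expect_equal(sort(unique(as.vector(mask[mask > 0]))), 1:2)
  expect_lte(sum(mask > 0), length(mask))
  ## two interior disks r=10: each area within 5% of pi r^2
  shs2 <- list(nucleusShape(c(25, 25), 10, 10), nucleusShape(c(70, 60), 10, 10))
  fld2 <- renderField(shs2, image_size = c(100, 100), noise_sd = 0)
  m2 <- segmentNuclei(fld2$images$dapi)
  areas <- tabulate(m2[m2 > 0])
  expect_equal(length(areas), 2)
  expect_true(all(abs(areas / (pi * 100) - 1) < 0.05))
  ## min_area removes specks
  img <- matrix(0, 40, 40); img[20, 20] <- 100; img[5:15, 5:15] <- 100
  expect_equal(max(segmentNuclei(img, threshold = 50, min_area = 10)), 1)
  ## holes are filled
  donut <- matrix(0, 60, 60)
  donut[outer(1:60, 1:60, function(i, j)
    (i - 30)^2 + (j - 30)^2 <= 400 & (i - 30)^2 + (j - 30)^2 >= 36)] <- 100
  seg <- segmentNuclei(donut, threshold = 50)
  expect_gte(sum(seg > 0), pi * 400 * 0.95)
})

test_that("measured geometry matches analytic circle and ellipse values", {
  disk <- nucleusShape(c(60, 60), 50, 50,
                       intensity = c(dapi = 3000, laminAC = 100))
  fld <- renderField(list(disk), image_size = c(120, 120),
                     channels = c("dapi", "laminAC"), noise_sd = 0)
  m <- measureNuclei(segmentNuclei(fld$images$dapi),
                     list(laminAC = fld$images$laminAC))
  expect_equal(m$circularity, 1, tolerance = 0.02)
  expect_equal(m$area, pi * 2500, tolerance = 0.02)
  ## uniform channel -> exact mean for the label
  expect_equal(m$laminAC_mean, 100)
  ell <- nucleusShape(c(45, 60), 20, 10, orientation = 0.4)
  fld2 <- renderField(list(ell), image_size = c(90, 120), noise_sd = 0)
  m2 <- measureNuclei(segmentNuclei(fld2$images$dapi), list())
  expect_equal(m2$length / m2$width, 2, tolerance = 0.05)
  expect_equal(m2$circularity, 0.8412, tolerance = 0.03 * 0.8412)
  expect_error(measureNuclei(matrix(0L, 4, 4), list(x = matrix(0, 5, 5))),
               "dimensions")
})

test_that("measured circularity is stable across scale and monotone in lobulation", {
  circ_of <- function(sh, size) {
    fld <- renderField(list(sh), image_size = size, noise_sd = 0)
    measureNuclei(segmentNuclei(fld$images$dapi), list())$circularity
  }
  c1 <- circ_of(nucleusShape(c(35, 35), 25, 25), c(70, 70))
  c2 <- circ_of(nucleusShape(c(70, 70), 50, 50), c(140, 140))
  expect_lt(abs(c2 - c1) / c1, 0.01)
  cs <- vapply(c(0, 0.15, 0.3), function(am) {
    lob <- if (am > 0) list(c(4, am, 0)) else list()
    circ_of(nucleusShape(c(60, 60), 30, 30, lobes = lob), c(120, 120))
  }, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("well aggregation is an exact arithmetic mean with QC flags", {
  rec <- data.frame(plate_id = "P01", well = "A01", role = "library",
                    gene_id = "g1", oligo_id = "g1_o1",
                    area = c(100, 200, 300), perimeter = 1, length = 2,
                    width = 1, circularity = 0.9, laminAC_mean = 5,
                    laminB1_mean = 5)
  ws <- aggregateWells(rec, min_count = 2)
  expect_equal(ws$area, 200)
  expect_equal(ws$n_nuclei, 3)
  expect_equal(ws$qc_flag, "ok")
  ws2 <- aggregateWells(rec, min_count = 50)
  expect_equal(ws2$qc_flag, "low_count")
  ## brute-force mean oracle on a simulated table
  s <- smallScreen()
  cells <- s$cells
  one <- cells[cells$replicate == 1 & cells$plate_id == cells$plate_id[1] &
               cells$well == cells$well[1], ]
  ws3 <- aggregateWells(one)
  expect_equal(ws3$circularity, sum(one$circularity) / nrow(one),
               tolerance = 1e-12)
  ## zero-nuclei wells appear with NA means when the layout is supplied
  full <- aggregateWells(cells, s$layout)
  empty <- full[full$role == "empty", ]
  expect_true(all(empty$n_nuclei == 0))
  expect_true(all(is.na(empty$circularity)))
  ## mixed metadata within one well is a consistency error
  bad <- rec
  bad$gene_id <- c("g1", "g2", "g1")
  expect_error(aggregateWells(bad), "disagree")
})
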