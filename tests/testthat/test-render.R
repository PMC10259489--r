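test_that("analytic truth matches circle and ellipse geometry oracles", {
  disk <- nucleusShape(c(60, 60), 50, 50)
  expect_equal(shapeArea(disk), pi * 50^2, tolerance = 1e-4)
  expect_equal(shapeCircularity(disk), 1, tolerance = 1e-4)
  ell <- nucleusShape(c(0, 0), 20, 10)
  P <- ellipsePerimeter(20, 10)
  expect_equal(shapePerimeter(ell), P, tolerance = 1e-4)
  expect_equal(shapeCircularity(ell), 4 * pi * (pi * 200) / P^2,
               tolerance = 1e-4)
})

test_that("polygon area and perimeter converge when vertex count doubles", {
  set.seed(10)
  for (i in 1:10) {
    sh <- nucleusShape(c(0, 0), a = runif(1, 15, 40), b = runif(1, 8, 15),
                       orientation = runif(1, 0, pi),
                       lobes = list(c(sample(2:6, 1), runif(1, 0, 0.45),
                                      runif(1, 0, 2 * pi))))
    a720 <- shapeArea(sh, 720); a1440 <- shapeArea(sh, 1440)
    p720 <- shapePerimeter(sh, 720); p1440 <- shapePerimeter(sh, 1440)
    expect_lt(abs(a1440 - a720) / a1440, 0.001)
    expect_lt(abs(p1440 - p720) / p1440, 0.001)
  }
})

test_that("rendered fields carry exact truth and honest pixel data", {
  disk <- nucleusShape(c(60, 60), 50, 50)
  fld <- renderField(list(disk), image_size = c(120, 120), noise_sd = 0,
                     seed = 1)
  expect_equal(fld$truth$circularity, 1, tolerance = 1e-4)
  expect_equal(fld$truth$area, pi * 2500, tolerance = 1e-3)
  expect_false(fld$truth$on_border)
  img <- fld$images$dapi
  expect_true(is.integer(img))
  expect_true(all(img >= 0 & img <= 65535))
  ## noise-free image has exactly two levels: background and paint
  expect_equal(sort(unique(as.vector(img))), c(400L, 3000L))
  ## raster area close to analytic
  expect_lt(abs(sum(img == 3000L) / (pi * 2500) - 1), 0.01)
})

test_that("an empty shape list renders background only", {
  fld <- renderField(list(), image_size = c(40, 40), noise_sd = 0)
  expect_equal(nrow(fld$truth), 0)
  expect_true(all(fld$images$dapi == 400L))
})

test_that("overlapping interiors and impossible placements are errors", {
  a <- nucleusShape(c(30, 30), 15, 15)
  b <- nucleusShape(c(35, 30), 15, 15)
  expect_error(renderField(list(a, b), image_size = c(64, 64)), "overlap")
  expect_error(
    sampleFieldShapes(50, image_size = c(100, 100), a_range = c(25, 30),
                      max_tries = 200, seed = 1),
    "could not place")
})

test_that("rendering is deterministic given config and seed", {
  shs <- sampleFieldShapes(5, image_size = c(320, 320), seed = 3)
  f1 <- renderField(shs, image_size = c(320, 320), seed = 4)
  f2 <- renderField(shs, image_size = c(320, 320), seed = 4)
  expect_identical(f1$images, f2$images)
  expect_identical(f1$truth, f2$truth)
})

test_that("shapesFromRecords reproduces the records' analytic geometry", {
  set.seed(11)
  rec <- data.frame(area = rnorm(10, 2500, 300),
                    length = rnorm(10, 72, 6), width = rnorm(10, 46, 4),
                    circularity = pmin(rnorm(10, 0.85, 0.06), 1),
                    laminAC_mean = 1200, laminB1_mean = 1100)
  rec$length <- pmax(rec$length, rec$width)
  flds <- shapesFromRecords(rec, image_size = c(512, 512),
                            cells_per_field = 5, seed = 2)
  shapes <- do.call(c, flds)
  expect_length(shapes, 10)
  got_area <- vapply(shapes, shapeArea, numeric(1))
  got_circ <- vapply(shapes, shapeCircularity, numeric(1))
  expect_equal(got_area, rec$area, tolerance = 1e-3)
  ## circularity matched except where capped by the target's ellipse bound
  reachable <- rec$circularity <= vapply(shapes, function(s) {
    shapeCircularity(nucleusShape(c(0, 0), s@a / s@b, 1))
  }, numeric(1))
  expect_equal(got_circ[reachable], rec$circularity[reachable],
               tolerance = 1e-3)
})
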