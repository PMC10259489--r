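## shared fixtures and independent oracles

## perimeter of an ellipse by numerical complete elliptic integral
ellipsePerimeter <- function(a, b) {
  4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                       0, pi / 2, rel.tol = 1e-12)$value
}

## small dense plate format (96-well): B-scoring is well-posed at toy scale
denseLayout <- function(n_genes = 20, seed = 5) {
  buildLibraryLayout(n_genes, n_rows = 8L, n_cols = 12L,
                     controls_per_plate = c(neg_ctrl = 2L, lethal_ctrl = 1L,
                                            lmna_ctrl = 1L),
                     seed = seed)
}

## a small scored screen used by several test files (cached per session)
smallScreen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- denseLayout(28, seed = 5)
      tr <- sampleGroundTruth(
        lay,
        hit_spec = list(circularity = list(n = 3, effect = -4),
                        area = list(n = 2, effect = 3)),
        cytotoxic_spec = list(n = 2, range = c(0.05, 0.1)),
        cells_mean = 60, cells_dispersion = 30, seed = 5)
      cells <- simulateCells(lay, tr, replicates = 1:2)
      wells <- aggregateWells(cells, lay, min_count = 20)
      cache <<- list(layout = lay, truth = tr, cells = cells, wells = wells,
                     scores = scoreScreen(wells))
    }
    cache
  }
})
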