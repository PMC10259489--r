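#' Default baseline feature distribution
#'
#' Population mean and SD per feature for simulated fibroblast nuclei, in
#' pixel units at a nominal scale where a typical nucleus covers ~2500 px^2.
#' Circularity is dimensionless; intensities are arbitrary fluorescence units.
#'
#' @return data.frame with columns `feature`, `mean`, `sd`.
#' @export
#' @examples
#' defaultBaseline()
defaultBaseline <- function() {
  data.frame(
    feature = screenFeatures(),
    mean = c(0.88, 2500, 72, 46, 1200, 1100),
    sd   = c(0.05, 450, 9, 6, 250, 220),
    stringsAsFactors = FALSE
  )
}

#' Sample the ground truth of a synthetic screen
#'
#' Draws the designed effects a synthetic screen will carry: which genes are
#' hits on which feature (additive shifts of the per-cell feature
#' distribution, in units of the baseline population SD), which genes are
#' cytotoxic (multiplier on expected cell count), and per-plate spatial
#' artifacts (additive, row/column-separable linear gradients plus an edge
#' offset -- the structure a B-score median polish is designed to remove).
#' Hit genes are disjoint across features (and disjoint from cytotoxic genes)
#' unless `allow_overlap = TRUE`. Deterministic given `seed`.
#'
#' @param layout a [ScreenLayout-class]; genes and plates are taken from it.
#' @param hit_spec named list, one entry per feature (see [screenFeatures()]),
#'   each a list with `n` (number of hit genes) and `effect` (shift in SD
#'   units; scalar, or `mean`/`sd` pair for a Gaussian effect-size
#'   distribution as `list(n =, mean =, sd =)`).
#' @param cytotoxic_spec list with `n` and `range` (multiplier range in
#'   (0, 1]).
#' @param plate_effect_spec list with maximum amplitudes (SD units) for
#'   `row_amp`, `col_amp`, `edge`; per plate and feature the realized
#'   amplitude is uniform on (-amp, amp). Use zeros for artifact-free plates.
#' @param baseline data.frame as [defaultBaseline()].
#' @param control_effects named list of per-role feature shifts (SD units);
#'   default gives the LMNA positive control reduced circularity and lamin
#'   A/C intensity.
#' @param cells_mean,cells_dispersion negative-binomial cell seeding model
#'   per well (mean ~300 so that most wells exceed 250 analyzed nuclei).
#' @param allow_overlap allow one gene to be a hit on several features.
#' @param seed integer master seed.
#' @return A [GroundTruth-class] object.
#' @export
#' @examples
#' lay <- buildLibraryLayout(50, seed = 1)
#' tr <- sampleGroundTruth(lay,
#'   hit_spec = list(circularity = list(n = 5, effect = -3)), seed = 1)
#' table(geneEffects(tr)[, "circularity"])
sampleGroundTruth <- function(layout,
                              hit_spec = list(),
                              cytotoxic_spec = list(n = 0, range = c(0.1, 0.5)),
                              plate_effect_spec = list(row_amp = 0.5,
                                                       col_amp = 0.5,
                                                       edge = 0.25),
                              baseline = defaultBaseline(),
                              control_effects = list(
                                lmna_ctrl = c(circularity = -2.5,
                                              laminAC_mean = -3)),
                              cells_mean = 300, cells_dispersion = 20,
                              allow_overlap = FALSE, seed = 1L) {
  feats <- screenFeatures()
  .checkTrue(all(names(hit_spec) %in% feats),
             "hit_spec names must be features: ",
             paste(setdiff(names(hit_spec), feats), collapse = ", "))
  .checkTrue(all(baseline$sd >= 0), "negative baseline SD")
  genes <- sort(unique(libraryTable(layout)$gene_id))
  n_genes <- length(genes)

  ge <- matrix(0, n_genes, length(feats),
               dimnames = list(genes, feats))
  cyto <- stats::setNames(rep(1, n_genes), genes)

  withChildSeed(seed, "truth", expr = {
    pool <- genes
    for (f in names(hit_spec)) {
      sp <- hit_spec[[f]]
      n <- sp$n %||% 0L
      .checkTrue(n <= length(pool),
                 "hit count exceeds available genes for feature ", f)
      if (n == 0) next
      pick <- sample(pool, n)
      if (!is.null(sp$effect)) {
        eff <- rep_len(sp$effect, n)
      } else {
        eff <- stats::rnorm(n, sp$mean %||% 0, sp$sd %||% 0)
      }
      .checkTrue(all(is.finite(eff)), "effect sizes must be finite")
      ge[pick, f] <- eff
      if (!allow_overlap) pool <- setdiff(pool, pick)
    }
    n_cyto <- cytotoxic_spec$n %||% 0L
    if (n_cyto > 0) {
      rng <- cytotoxic_spec$range %||% c(0.1, 0.5)
      .checkTrue(all(rng > 0 & rng <= 1),
                 "cytotoxic multipliers must lie in (0, 1]")
      .checkTrue(n_cyto <= length(pool), "cytotoxic count exceeds genes")
      pick <- sample(pool, n_cyto)
      cyto[pick] <- stats::runif(n_cyto, rng[1], rng[2])
    }
  })

  ## per-plate artifact amplitudes (SD units), features + cellcount
  plates <- plateIds(layout)
  cols <- c(feats, "cellcount")
  amp <- function(maxamp, key) {
    m <- matrix(0, length(plates), length(cols),
                dimnames = list(plates, cols))
    if (isTRUE(maxamp > 0)) {
      for (p in plates) {
        m[p, ] <- withChildSeed(seed, "plate_fx", key, p, expr = {
          stats::runif(length(cols), -maxamp, maxamp)
        })
      }
    }
    m
  }
  row_amp <- amp(plate_effect_spec$row_amp %||% 0, "row")
  col_amp <- amp(plate_effect_spec$col_amp %||% 0, "col")
  edge <- amp(plate_effect_spec$edge %||% 0, "edge")

  new("GroundTruth", gene_effects = ge, cytotoxic = cyto,
      control_effects = control_effects,
      plate_row_amp = row_amp, plate_col_amp = col_amp, plate_edge = edge,
      baseline = baseline, cells_mean = cells_mean,
      cells_dispersion = cells_dispersion, seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
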