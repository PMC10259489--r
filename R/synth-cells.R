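## Realized additive plate effect (feature units) for wells at (row, col)
## given per-plate amplitudes in SD units. Gradients are linear and
## row/column-separable; the edge offset applies to boundary wells.
.plateEffect <- function(truth, plate, feature, row, col, n_rows, n_cols,
                         sd_unit) {
  g_row <- if (n_rows > 1) 2 * (row - (n_rows + 1) / 2) / (n_rows - 1) else 0
  g_col <- if (n_cols > 1) 2 * (col - (n_cols + 1) / 2) / (n_cols - 1) else 0
  on_edge <- row == 1 | row == n_rows | col == 1 | col == n_cols
  sd_unit * (truth@plate_row_amp[plate, feature] * g_row +
             truth@plate_col_amp[plate, feature] * g_col +
             truth@plate_edge[plate, feature] * on_edge)
}

#' Simulate per-nucleus morphometry tables for a screen
#'
#' Draws single-cell feature values for every well of the layout under the
#' designed ground truth: per-cell value = baseline mean + gene effect +
#' additive plate spatial effect + Gaussian cell-level noise. Cell counts per
#' well are negative-binomial, scaled by the gene's cytotoxicity multiplier;
#' lethal-control wells get near-zero counts (<= 5); empty wells none.
#' Circularity is clipped to (0, 1]; the per-nucleus perimeter is derived
#' from area and circularity so the circularity identity holds exactly;
#' length/width are ordered so length >= width.
#'
#' Each (replicate, plate, well) has its own child random stream derived from
#' the master seed, so any subset is reproducible in isolation and replicates
#' are independent.
#'
#' @param layout a [ScreenLayout-class].
#' @param truth a [GroundTruth-class] over the same genes.
#' @param replicates integer vector of replicate ids to simulate (default
#'   `1:2`, the two biological replicates of a screen).
#' @param seed master seed (defaults to the truth's seed).
#' @return data.frame with one row per nucleus: `replicate`, `plate_id`,
#'   `well`, `row`, `col`, `role`, `gene_id`, `oligo_id`, `nucleus_id`,
#'   `area`, `perimeter`, `length`, `width`, `circularity`, `laminAC_mean`,
#'   `laminB1_mean`.
#' @export
#' @examples
#' lay <- buildLibraryLayout(5, seed = 1)
#' tr <- sampleGroundTruth(lay, seed = 1)
#' cells <- simulateCells(lay, tr, replicates = 1L)
#' head(cells)
simulateCells <- function(layout, truth, replicates = 1:2,
                          seed = truth@seed) {
  w <- layoutWells(layout)
  genes <- rownames(truth@gene_effects)
  lib_genes <- unique(w$gene_id[w$role == "library"])
  if (!all(lib_genes %in% genes)) {
    stop("layout contains genes absent from the ground truth: ",
         paste(setdiff(lib_genes, genes), collapse = ", "), call. = FALSE)
  }
  feats <- screenFeatures()
  base <- truth@baseline
  mu_f <- stats::setNames(base$mean, base$feature)[feats]
  sd_f <- stats::setNames(base$sd, base$feature)[feats]
  mu_n <- truth@cells_mean
  size_n <- truth@cells_dispersion
  sd_n <- sqrt(mu_n + mu_n^2 / size_n)

  out_meta <- vector("list", length(replicates) * nrow(w))
  out_feat <- vector("list", length(replicates) * nrow(w))
  k <- 0L
  for (rep_id in replicates) {
    for (i in seq_len(nrow(w))) {
      role <- w$role[i]
      if (role == "empty") next
      plate <- w$plate_id[i]
      ## designed per-feature shift (SD units) for this well
      shift <- stats::setNames(numeric(length(feats)), feats)
      mult <- 1
      if (role == "library") {
        g <- w$gene_id[i]
        shift <- truth@gene_effects[g, feats]
        mult <- truth@cytotoxic[[g]]
      } else if (role %in% names(truth@control_effects)) {
        ce <- truth@control_effects[[role]]
        shift[names(ce)] <- ce
      }
      pe <- vapply(feats, function(f) {
        .plateEffect(truth, plate, f, w$row[i], w$col[i],
                     layout@n_rows, layout@n_cols, sd_f[[f]])
      }, numeric(1))
      pe_n <- .plateEffect(truth, plate, "cellcount", w$row[i], w$col[i],
                           layout@n_rows, layout@n_cols, sd_n)
      fx <- withChildSeed(seed, "cells", rep_id, plate, w$well[i], expr = {
        if (role == "lethal_ctrl") {
          n <- min(stats::rpois(1, 2), 5L)
        } else {
          mu_w <- max(mu_n * mult + pe_n, 1)
          n <- stats::rnbinom(1, mu = mu_w, size = size_n)
        }
        if (n == 0) NULL else {
          m <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
          for (f in feats) {
            m[, f] <- mu_f[[f]] + sd_f[[f]] * shift[[f]] + pe[[f]] +
              stats::rnorm(n, 0, sd_f[[f]])
          }
          m
        }
      })
      if (is.null(fx)) next
      ## feature sanity: positivity, circularity in (0, 1], length >= width
      fx[, "area"] <- pmax(fx[, "area"], 1)
      fx[, "circularity"] <- pmin(pmax(fx[, "circularity"], 1e-6), 1)
      l <- pmax(fx[, "length"], fx[, "width"], 1)
      wdt <- pmax(pmin(fx[, "length"], fx[, "width"]), 0.5)
      fx[, "length"] <- l
      fx[, "width"] <- wdt
      fx[, "laminAC_mean"] <- pmax(fx[, "laminAC_mean"], 0)
      fx[, "laminB1_mean"] <- pmax(fx[, "laminB1_mean"], 0)
      k <- k + 1L
      out_meta[[k]] <- data.frame(
        replicate = rep_id, plate_id = plate, well = w$well[i],
        row = w$row[i], col = w$col[i], role = role,
        gene_id = w$gene_id[i], oligo_id = w$oligo_id[i],
        nucleus_id = seq_len(nrow(fx)), stringsAsFactors = FALSE
      )
      out_feat[[k]] <- fx
    }
  }
  if (k == 0L) stop("no cells simulated", call. = FALSE)
  meta <- do.call(rbind, out_meta[seq_len(k)])
  fx <- as.data.frame(do.call(rbind, out_feat[seq_len(k)]))
  fx$perimeter <- sqrt(4 * pi * fx$area / fx$circularity)
  cbind(meta, fx[, c("area", "perimeter", "length", "width", "circularity",
                     "laminAC_mean", "laminB1_mean")])
}
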