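#' Gene-level median Z-scores over oligos
#'
#' Collapses per-oligo replicate-mean Z-scores to one value per gene and
#' feature: the sample median (middle value for 3 oligos; for an even count,
#' the mean of the middle pair). For three oligos the median lies beyond a
#' threshold on one side exactly when at least two of the three oligos lie
#' beyond it on that side -- the screen's "two out of three" rule. Genes with
#' fewer than 2 scored oligos are flagged unscorable for hit calling.
#'
#' @param scores a [ScreenScores-class] or its `oligoScores()` data.frame.
#' @return data.frame, one row per gene x feature: `gene_id`, `feature`,
#'   `median_z`, `sd_z` (SD over oligos, the error-bar surrogate), `min_z`,
#'   `max_z`, `n_oligos`.
#' @export
geneMedians <- function(scores) {
  ol <- if (is(scores, "ScreenScores")) oligoScores(scores) else scores
  .checkTrue(all(c("gene_id", "feature", "z_mean") %in% names(ol)),
             "need gene_id/feature/z_mean columns")
  ol <- ol[!is.na(ol$z_mean), , drop = FALSE]
  key <- paste(ol$gene_id, ol$feature, sep = "\r")
  sp <- split(ol$z_mean, key)
  first <- !duplicated(key)
  out <- data.frame(gene_id = ol$gene_id[first], feature = ol$feature[first],
                    stringsAsFactors = FALSE)
  k <- key[first]
  out$median_z <- vapply(sp[k], stats::median, numeric(1))
  out$sd_z <- vapply(sp[k], function(v) if (length(v) > 1) stats::sd(v)
                     else NA_real_, numeric(1))
  out$min_z <- vapply(sp[k], min, numeric(1))
  out$max_z <- vapply(sp[k], max, numeric(1))
  out$n_oligos <- vapply(sp[k], length, numeric(1))
  rownames(out) <- NULL
  out
}

.HIT_CLASSES <- data.frame(
  class = c("shape_hit", "size_up", "size_down", "laminAC_down",
            "laminB1_down"),
  feature = c("circularity", "area", "area", "laminAC_mean", "laminB1_mean"),
  side = c(-1, 1, -1, -1, -1),
  stringsAsFactors = FALSE
)

## directional hit decision for one gene/feature given its oligo summary row:
## >= 3 oligos: median beyond the (inclusive) threshold; exactly 2 oligos:
## both beyond (reduced evidence); < 2: unscorable.
.beyond <- function(med, minz, maxz, n, thr, side) {
  ifelse(n >= 3, if (side < 0) med <= thr else med >= thr,
  ifelse(n == 2, if (side < 0) maxz <= thr else minz >= thr, NA))
}

#' Call gene-level hits with directional thresholds
#'
#' Applies the screen's hit definitions to gene medians of replicate-averaged
#' robust Z-scores (thresholds inclusive): shape hits have circularity median
#' Z <= -1.5 (decreased roundness; set `two_sided_shape` for both sides),
#' size hits have area median Z >= +1.5 (`size_up`) or <= -1.5 (`size_down`),
#' and lamin A/C / lamin B1 level hits have intensity median Z <= -1.5.
#' Genes whose cell-count median Z falls at or below `viability_threshold`
#' are flagged `excluded_cytotoxic` and removed from hit lists (their flags
#' are kept for audit). Genes with exactly 2 scored oligos require both
#' oligos beyond the threshold and are flagged `reduced_evidence`.
#'
#' @param scores a [ScreenScores-class] (or `oligoScores()` data.frame
#'   including a `"cellcount"` feature).
#' @param threshold magnitude of the hit threshold on median Z (default 1.5).
#' @param viability_threshold cell-count median-Z exclusion cutoff
#'   (default -2, applied as `<=`).
#' @param two_sided_shape also call increased-circularity shape hits.
#' @return A [GeneCallSet-class].
#' @export
#' @seealso [hitList()], [applyViabilityFilter()], [evaluateRecovery()]
callHits <- function(scores, threshold = 1.5, viability_threshold = -2,
                     two_sided_shape = FALSE) {
  gm <- geneMedians(scores)
  .checkTrue(nrow(gm) > 0, "no scored genes")
  miss <- setdiff(unique(.HIT_CLASSES$feature), unique(gm$feature))
  .checkTrue(length(miss) == 0,
             "missing feature column(s) for hit calling: ",
             paste(miss, collapse = ", "))
  genes <- sort(unique(gm$gene_id))
  calls <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  wide <- function(col) {
    m <- matrix(NA_real_, length(genes),
                length(unique(gm$feature)),
                dimnames = list(genes, unique(gm$feature)))
    m[cbind(gm$gene_id, gm$feature)] <- gm[[col]]
    m
  }
  med <- wide("median_z"); sdv <- wide("sd_z")
  minz <- wide("min_z"); maxz <- wide("max_z"); nol <- wide("n_oligos")
  for (f in colnames(med)) {
    calls[[paste0("median_", f)]] <- med[, f]
    calls[[paste0("sd_", f)]] <- sdv[, f]
  }
  calls$n_oligos <- apply(nol, 1, max, na.rm = TRUE)
  thr <- abs(threshold)
  for (i in seq_len(nrow(.HIT_CLASSES))) {
    cls <- .HIT_CLASSES$class[i]; f <- .HIT_CLASSES$feature[i]
    side <- .HIT_CLASSES$side[i]
    hit <- .beyond(med[, f], minz[, f], maxz[, f], nol[, f],
                   side * thr, side)
    if (cls == "shape_hit" && two_sided_shape) {
      hit <- hit | .beyond(med[, f], minz[, f], maxz[, f], nol[, f],
                           thr, 1)
    }
    calls[[cls]] <- hit %in% TRUE
  }
  calls$unscorable <- apply(nol, 1, function(v) all(is.na(v) | v < 2))
  calls$reduced_evidence <- apply(nol, 1, function(v) any(v == 2, na.rm = TRUE))
  cal <- new("GeneCallSet", calls = calls,
             thresholds = c(shape = -thr, size = thr, laminAC = -thr,
                            laminB1 = -thr),
             viability_threshold = viability_threshold,
             two_sided_shape = two_sided_shape)
  applyViabilityFilter(cal, viability_threshold)
}

#' Apply (or re-apply) the cell-number viability exclusion
#'
#' Genes whose cell-count median Z is at or below the threshold are flagged
#' `excluded_cytotoxic`; [hitList()] omits excluded genes. Flags are kept so
#' excluded candidates remain auditable.
#'
#' @param calls a [GeneCallSet-class] (its calls must include
#'   `median_cellcount`).
#' @param threshold exclusion cutoff on the cell-count median Z (<=).
#' @return The updated [GeneCallSet-class].
#' @export
applyViabilityFilter <- function(calls, threshold = -2) {
  cal <- geneCalls(calls)
  .checkTrue("median_cellcount" %in% names(cal),
             "cell-count medians unavailable; score with include_cellcount")
  cc <- cal$median_cellcount
  cal$excluded_cytotoxic <- !is.na(cc) & cc <= threshold
  ## genes with no cell-count score cannot be cleared: mark unscorable
  cal$unscorable <- cal$unscorable | is.na(cc)
  initialize(calls, calls = cal, viability_threshold = threshold)
}

#' @rdname compareScreens
#' @param feature gene-level feature to correlate (Spearman on paired
#'   median Z).
#' @param hit_class hit class for the overlap sets.
#' @aliases compareScreens,GeneCallSet,GeneCallSet-method
#' @export
setMethod("compareScreens", signature("GeneCallSet", "GeneCallSet"),
  function(a, b, feature = "circularity", hit_class = "shape_hit", ...) {
    ca <- geneCalls(a); cb <- geneCalls(b)
    col <- paste0("median_", feature)
    .checkTrue(col %in% names(ca) && col %in% names(cb),
               "feature not scored in both screens: ", feature)
    shared <- intersect(ca$gene_id, cb$gene_id)
    if (length(shared) == 0) stop("no shared genes", call. = FALSE)
    pa <- ca[match(shared, ca$gene_id), col]
    pb <- cb[match(shared, cb$gene_id), col]
    ok <- !is.na(pa) & !is.na(pb)
    .checkTrue(sum(ok) >= 3, "need at least 3 paired scores")
    paired <- data.frame(gene_id = shared[ok], score_a = pa[ok],
                         score_b = pb[ok])
    rho <- spearmanRho(paired$score_a, paired$score_b)
    ha <- hitList(a, hit_class); hb <- hitList(b, hit_class)
    new("ScreenComparison", paired = paired, rho = rho, feature = feature,
        hits_both = intersect(ha, hb),
        hits_a_only = setdiff(ha, hb), hits_b_only = setdiff(hb, ha))
  })

#' Evaluate hit recovery against simulation ground truth
#'
#' For each hit class, compares called genes (after viability exclusion) with
#' the designed truth: recall over designed genes, precision over calls, and
#' the false-positive rate among null genes (genes with zero designed effect
#' on every feature and no designed cytotoxicity).
#'
#' @param calls a [GeneCallSet-class].
#' @param truth the [GroundTruth-class] the screen was simulated from.
#' @return data.frame per class: `class`, `n_designed`, `n_called`, `tp`,
#'   `recall`, `precision`, `n_null`, `fp`, `fpr`.
#' @export
evaluateRecovery <- function(calls, truth) {
  ge <- geneEffects(truth)
  cal <- geneCalls(calls)
  .checkTrue(all(cal$gene_id %in% rownames(ge)),
             "calls contain genes absent from the truth")
  cyto <- cytotoxicGenes(truth)
  null_genes <- rownames(ge)[rowSums(ge != 0) == 0 &
                             !rownames(ge) %in% cyto]
  null_genes <- intersect(null_genes, cal$gene_id)
  out <- lapply(seq_len(nrow(.HIT_CLASSES)), function(i) {
    cls <- .HIT_CLASSES$class[i]; f <- .HIT_CLASSES$feature[i]
    side <- .HIT_CLASSES$side[i]
    designed <- rownames(ge)[sign(ge[, f]) == side]
    called <- hitList(calls, cls)
    tp <- length(intersect(called, designed))
    fp_null <- length(intersect(called, null_genes))
    data.frame(
      class = cls,
      n_designed = length(designed), n_called = length(called), tp = tp,
      recall = if (length(designed)) tp / length(designed) else NA_real_,
      precision = if (length(called)) tp / length(called) else NA_real_,
      n_null = length(null_genes), fp = fp_null,
      fpr = if (length(null_genes)) fp_null / length(null_genes) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
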