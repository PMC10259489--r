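#' Tukey median polish with cell masking and canonical re-centering
#'
#' Fits the two-way additive decomposition
#' `x[i, j] = overall + row[i] + col[j] + residual[i, j]` by alternating
#' row/column median sweeps over the fitted (masked-in) cells, iterating
#' until the largest effect update falls below `tol` or `max_iter` sweeps
#' are reached. Residuals are returned for all cells: masked-out cells are
#' scored against the fit (`value - overall - row - col`) but never inform it.
#'
#' Median polish fixed points are not unique: two converged fits can differ
#' by an additive row-plus-column matrix whose row and column medians vanish,
#' so the classical zero-initialized polish is not exactly invariant under
#' additive row/column shifts of the data. With `init = "mean"` (default)
#' the effects are initialized at the least-squares two-way fit (alternating
#' row/column mean sweeps over the fitted cells, run to convergence) before
#' the median sweeps start. The LS projection maps additively shifted data
#' to identical starting residuals, and every subsequent median sweep is a
#' deterministic function of those residuals, so the final residuals -- and
#' hence B-scores -- are exactly invariant under additive plate gradients.
#' The median sweeps re-absorb any outlier leakage of the LS start (a single
#' spiked cell ends up fully in its own residual), so robustness is
#' preserved. `init = "zero"` gives the classical Tukey polish. See the
#' methods vignette.
#'
#' @param x numeric matrix (a plate of per-well values; `NA`s allowed).
#' @param mask logical matrix: `TRUE` for cells that inform the fit
#'   (library wells). Default: all non-`NA` cells.
#' @param max_iter maximum polish sweeps.
#' @param tol convergence tolerance on the largest effect update.
#' @param init effect initialization: `"mean"` (least-squares start; shift-
#'   invariant fit) or `"zero"` (classical).
#' @return A [MedianPolishFit-class].
#' @export
#' @examples
#' x <- matrix(5, 4, 6)
#' f <- medianPolish(x)
#' f@overall  # 5; all effects and residuals 0
medianPolish <- function(x, mask = NULL, max_iter = 100L, tol = 1e-9,
                         init = c("mean", "zero")) {
  init <- match.arg(init)
  .checkTrue(is.matrix(x) && is.numeric(x[1]), "x must be a numeric matrix")
  if (is.null(mask)) mask <- !is.na(x)
  .checkTrue(identical(dim(mask), dim(x)), "mask dimensions must match x")
  mask <- mask & !is.na(x)
  .checkTrue(sum(rowSums(mask) > 0) >= 2 && sum(colSums(mask) > 0) >= 2,
             "need fitted cells in at least 2 rows and 2 columns")
  nr <- nrow(x); nc <- ncol(x)
  z <- x
  z[!mask] <- NA
  row_eff <- numeric(nr); col_eff <- numeric(nc); overall <- 0
  degr <- rowSums(mask) == 0
  degc <- colSums(mask) == 0
  if (init == "mean") {
    ## least-squares start: alternating mean sweeps over the fitted cells
    for (k in seq_len(200L)) {
      rm_ <- rowMeans(z, na.rm = TRUE); rm_[is.nan(rm_)] <- 0
      z <- z - rm_; row_eff <- row_eff + rm_
      cm_ <- colMeans(z, na.rm = TRUE); cm_[is.nan(cm_)] <- 0
      z <- sweep(z, 2, cm_); col_eff <- col_eff + cm_
      if (max(abs(rm_), abs(cm_)) < 1e-13) break
    }
    g <- mean(row_eff[!degr]); row_eff <- row_eff - g; overall <- overall + g
    g <- mean(col_eff[!degc]); col_eff <- col_eff - g; overall <- overall + g
  }
  converged <- FALSE
  it <- 0L
  med0 <- function(v) { m <- stats::median(v, na.rm = TRUE); if (is.na(m)) 0 else m }
  for (it in seq_len(max_iter)) {
    rd <- apply(z, 1, med0)
    z <- z - rd; row_eff <- row_eff + rd
    d1 <- stats::median(col_eff[!degc])
    col_eff <- col_eff - d1; overall <- overall + d1
    cd <- apply(z, 2, med0)
    z <- sweep(z, 2, cd); col_eff <- col_eff + cd
    d2 <- stats::median(row_eff[!degr])
    row_eff <- row_eff - d2; overall <- overall + d2
    if (max(abs(rd), abs(cd), abs(d1), abs(d2)) < tol) {
      converged <- TRUE
      break
    }
  }
  row_eff[degr] <- 0
  col_eff[degc] <- 0
  resid <- x - overall - outer(row_eff, rep(1, nc)) - outer(rep(1, nr), col_eff)
  degen <- c(if (any(degr)) paste0("row", which(degr)),
             if (any(degc)) paste0("col", which(degc)))
  new("MedianPolishFit", overall = overall, row = row_eff, col = col_eff,
      residuals = resid, iterations = it, converged = converged,
      degenerate = as.character(degen))
}

#' B-scores of one plate
#'
#' The B-score of well (i, j) is the median-polish residual divided by the
#' scaled median absolute deviation (1.4826 x MAD) of the residuals over the
#' plate's library wells. Row/column plate artifacts that are additive are
#' removed exactly; the robust scale makes plates comparable. Scores are
#' returned for library and control wells alike, but only library wells
#' inform the fit and the scale.
#'
#' @param x numeric matrix of per-well values (one plate, one feature).
#' @param library_mask logical matrix marking library wells.
#' @param mad_constant scale constant (1.4826, Gaussian-consistent; set 1 to
#'   disable).
#' @param plate_id used in error messages.
#' @param fallback_residuals if `TRUE`, a degenerate plate (zero residual
#'   MAD) returns raw residuals instead of erroring.
#' @param ... passed to [medianPolish()].
#' @return numeric matrix of B-scores (NA where the value was NA).
#' @export
#' @examples
#' x <- matrix(rnorm(16 * 24), 16, 24)
#' b <- bscorePlate(x, matrix(TRUE, 16, 24))
bscorePlate <- function(x, library_mask, mad_constant = 1.4826,
                        plate_id = "plate", fallback_residuals = FALSE, ...) {
  fit <- medianPolish(x, mask = library_mask, ...)
  resid <- fit@residuals
  lib <- resid[library_mask & !is.na(resid)]
  s <- stats::mad(lib, constant = mad_constant)
  if (!is.finite(s) || s == 0) {
    if (fallback_residuals) return(resid)
    stop("degenerate plate '", plate_id,
         "': residual MAD over library wells is zero", call. = FALSE)
  }
  resid / s
}

#' Robust Z-scores against a reference set
#'
#' `Z = (value - median(reference)) / (1.4826 * MAD(reference))`. In the
#' screen chain the reference is the pooled library-well B-scores of one
#' replicate, and Z is computed for every well against it.
#'
#' @param values numeric vector to standardize.
#' @param reference numeric reference values (>= 3 non-NA required).
#' @param mad_constant scale constant (1.4826 default).
#' @return numeric vector of Z-scores.
#' @export
#' @examples
#' robustZ(c(1, 2, 3, 4, 100), c(1, 2, 3, 4, 100))[5]  # 97/1.4826
robustZ <- function(values, reference, mad_constant = 1.4826) {
  ref <- reference[!is.na(reference)]
  .checkTrue(length(ref) >= 3, "need at least 3 reference values")
  s <- stats::mad(ref, constant = mad_constant)
  if (!is.finite(s) || s == 0) {
    stop("degenerate scale: reference MAD is zero", call. = FALSE)
  }
  (values - stats::median(ref)) / s
}

#' Average per-oligo Z-scores over replicates
#'
#' @param z matrix or data.frame of per-replicate Z values (one column per
#'   replicate, one row per oligo x feature); `NA` marks a missing replicate.
#' @return data.frame with `z_mean` (mean of available replicates),
#'   `n_replicates`, and `single_replicate` flag; rows with no replicate get
#'   `NA` (unscored).
#' @export
#' @examples
#' mergeReplicates(cbind(c(-2, 1.2), c(-1, NA)))
mergeReplicates <- function(z) {
  z <- as.matrix(z)
  n <- rowSums(!is.na(z))
  zm <- rowMeans(z, na.rm = TRUE)
  zm[n == 0] <- NA_real_
  data.frame(z_mean = zm, n_replicates = n, single_replicate = n == 1)
}

#' Score a screen: B-score, robust Z, replicate-mean Z
#'
#' Runs the full normalization chain on per-well summaries: (1) per plate and
#' feature, B-scores via median polish over library wells; (2) per replicate,
#' robust Z-scores of the pooled B-scores, standardized against all library
#' wells of the replicate; (3) per (gene, oligo, feature), the arithmetic
#' mean Z over replicates. Cell count (`n_nuclei`) is scored through the
#' identical chain as feature `"cellcount"`.
#'
#' @param wells per-well data.frame from [aggregateWells()] (needs
#'   `replicate`, `plate_id`, `well`, `row`, `col`, `role`, `gene_id`,
#'   `oligo_id`, `n_nuclei`, and the feature columns).
#' @param features features to score.
#' @param include_cellcount score `n_nuclei` as `"cellcount"`.
#' @param mad_constant MAD scale constant (1.4826).
#' @param plate_dims optional c(rows, cols); inferred from the data when
#'   absent.
#' @param ... passed to [bscorePlate()] / [medianPolish()].
#' @return A [ScreenScores-class].
#' @export
#' @examples
#' lay <- buildLibraryLayout(10, seed = 1)
#' tr <- sampleGroundTruth(lay, seed = 1)
#' cells <- simulateCells(lay, tr, replicates = 1:2)
#' sc <- scoreScreen(aggregateWells(cells, lay))
#' head(oligoScores(sc))
scoreScreen <- function(wells, features = screenFeatures(),
                        include_cellcount = TRUE, mad_constant = 1.4826,
                        plate_dims = NULL, ...) {
  need <- c("replicate", "plate_id", "well", "row", "col", "role",
            "gene_id", "oligo_id", "n_nuclei")
  miss <- setdiff(c(need, features), names(wells))
  .checkTrue(length(miss) == 0, "wells is missing columns: ",
             paste(miss, collapse = ", "))
  if (is.null(plate_dims)) plate_dims <- c(max(wells$row), max(wells$col))
  feats <- features
  if (include_cellcount) {
    wells$cellcount <- as.numeric(wells$n_nuclei)
    feats <- c(feats, "cellcount")
  }
  reps <- sort(unique(wells$replicate))
  plates <- sort(unique(wells$plate_id))

  ws_list <- list()
  for (r in reps) {
    wr <- wells[wells$replicate == r, , drop = FALSE]
    for (f in feats) {
      bmat_all <- wr[, c("plate_id", "well", "row", "col", "role",
                         "gene_id", "oligo_id")]
      bmat_all$value <- wr[[f]]
      bmat_all$b_score <- NA_real_
      for (p in plates) {
        sel <- wr$plate_id == p
        if (!any(sel)) next
        m <- matrix(NA_real_, plate_dims[1], plate_dims[2])
        lm <- matrix(FALSE, plate_dims[1], plate_dims[2])
        idx <- cbind(wr$row[sel], wr$col[sel])
        m[idx] <- wr[[f]][sel]
        lm[idx] <- wr$role[sel] == "library" & !is.na(wr[[f]][sel])
        b <- bscorePlate(m, lm, mad_constant = mad_constant,
                         plate_id = paste0(p, "/", f, "/rep", r), ...)
        bmat_all$b_score[sel] <- b[idx]
      }
      lib_b <- bmat_all$b_score[bmat_all$role == "library"]
      bmat_all$z <- robustZ(bmat_all$b_score, lib_b,
                            mad_constant = mad_constant)
      bmat_all$replicate <- r
      bmat_all$feature <- f
      ws_list[[length(ws_list) + 1L]] <- bmat_all
    }
  }
  well_scores <- do.call(rbind, ws_list)
  well_scores <- well_scores[, c("replicate", "plate_id", "well", "row",
                                 "col", "role", "gene_id", "oligo_id",
                                 "feature", "value", "b_score", "z")]

  ## per-oligo table: each (gene, oligo, replicate) is one library well
  lib <- well_scores[well_scores$role == "library", , drop = FALSE]
  key <- paste(lib$gene_id, lib$oligo_id, lib$feature, sep = "\r")
  ukey <- !duplicated(key)
  oligo <- lib[ukey, c("gene_id", "oligo_id", "feature")]
  rownames(oligo) <- key[ukey]
  zmat <- matrix(NA_real_, nrow(oligo), length(reps),
                 dimnames = list(rownames(oligo), paste0("z_rep", reps)))
  bmat <- matrix(NA_real_, nrow(oligo), length(reps),
                 dimnames = list(rownames(oligo), paste0("b_rep", reps)))
  for (i in seq_along(reps)) {
    li <- lib[lib$replicate == reps[i], , drop = FALSE]
    ki <- paste(li$gene_id, li$oligo_id, li$feature, sep = "\r")
    zmat[ki, i] <- li$z
    bmat[ki, i] <- li$b_score
  }
  merged <- mergeReplicates(zmat)
  oligo <- cbind(oligo, as.data.frame(bmat), as.data.frame(zmat), merged)
  rownames(oligo) <- NULL
  new("ScreenScores", well_scores = well_scores, oligo_scores = oligo,
      features = feats, replicates = as.integer(reps),
      mad_constant = mad_constant)
}
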