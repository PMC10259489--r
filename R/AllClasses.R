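#' @import methods
NULL

.WELL_ROLES <- c("library", "neg_ctrl", "lethal_ctrl", "lmna_ctrl", "empty")

#' ScreenLayout: plate maps for an siRNA screen
#'
#' Holds the well-level map of a multi-plate screen: plate format, the role of
#' every well (library / negative control / lethal transfection control /
#' LMNA positive control / empty), and the (gene, oligo) assignment of library
#' wells. Each (gene, oligo) pair occupies exactly one well across the screen.
#'
#' @slot plate_ids character, the plates in order.
#' @slot n_rows,n_cols integer plate format (16 x 24 for 384-well).
#' @slot wells data.frame with columns `plate_id`, `well`, `row`, `col`,
#'   `role`, `gene_id`, `oligo_id` (gene/oligo are `NA` off library wells).
#' @slot seed integer seed used to build the layout.
#'
#' @seealso [buildLibraryLayout()]
#' @export
setClass("ScreenLayout",
  representation(plate_ids = "character", n_rows = "integer",
                 n_cols = "integer", wells = "data.frame", seed = "integer"))

setValidity("ScreenLayout", function(object) {
  w <- object@wells
  need <- c("plate_id", "well", "row", "col", "role", "gene_id", "oligo_id")
  if (!all(need %in% names(w))) {
    return(paste("wells must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(w$role %in% .WELL_ROLES)) return("unknown well role")
  if (nrow(w) != length(object@plate_ids) * object@n_rows * object@n_cols) {
    return("wells must enumerate every well of every plate")
  }
  lib <- w[w$role == "library", ]
  if (anyNA(lib$gene_id) || anyNA(lib$oligo_id)) {
    return("library wells must carry a (gene, oligo) assignment")
  }
  key <- paste(lib$gene_id, lib$oligo_id)
  if (anyDuplicated(key)) {
    return("each (gene, oligo) pair must appear in exactly one well")
  }
  ctl <- w[w$role %in% c("neg_ctrl", "lethal_ctrl", "lmna_ctrl", "empty"), ]
  if (!all(is.na(ctl$gene_id))) return("control/empty wells have no gene")
  TRUE
})

#' GroundTruth: designed effects of a synthetic screen
#'
#' Records everything needed to regenerate a synthetic screen bit-identically:
#' per-gene additive feature effects (in units of the baseline population SD),
#' per-gene cytotoxicity multipliers on cell count, per-plate spatial artifact
#' parameters (row/column gradients and edge offsets, additive), the baseline
#' feature distribution, control-well effects, and the master seed.
#'
#' @slot gene_effects numeric matrix, genes x features, in baseline-SD units.
#' @slot cytotoxic named numeric in (0, 1]; multiplier on expected cell count.
#' @slot control_effects named list: per control role, a feature->SD-shift
#'   vector (e.g. the LMNA positive control lowers circularity and lamin A/C).
#' @slot plate_row_amp,plate_col_amp,plate_edge numeric matrices,
#'   plates x (features + cellcount): gradient/edge amplitudes in SD units.
#' @slot baseline data.frame with `feature`, `mean`, `sd`.
#' @slot cells_mean,cells_dispersion negative-binomial cell-count model
#'   (mean and size) for library wells.
#' @slot seed integer master seed.
#'
#' @seealso [sampleGroundTruth()]
#' @export
setClass("GroundTruth",
  representation(gene_effects = "matrix", cytotoxic = "numeric",
                 control_effects = "list",
                 plate_row_amp = "matrix", plate_col_amp = "matrix",
                 plate_edge = "matrix", baseline = "data.frame",
                 cells_mean = "numeric", cells_dispersion = "numeric",
                 seed = "integer"))

setValidity("GroundTruth", function(object) {
  if (any(!is.finite(object@gene_effects))) return("effects must be finite")
  if (any(object@cytotoxic <= 0 | object@cytotoxic > 1)) {
    return("cytotoxic multipliers must lie in (0, 1]")
  }
  if (!identical(rownames(object@gene_effects), names(object@cytotoxic))) {
    return("gene_effects rownames and cytotoxic names must agree")
  }
  b <- object@baseline
  if (!all(c("feature", "mean", "sd") %in% names(b))) {
    return("baseline needs feature/mean/sd")
  }
  if (any(b$sd < 0)) return("baseline SDs must be non-negative")
  if (object@cells_mean <= 0 || object@cells_dispersion <= 0) {
    return("cell-count mean and dispersion must be positive")
  }
  TRUE
})

#' NucleusShape: generative boundary model for one rendered nucleus
#'
#' An ellipse (semi-axes `a >= b > 0`, orientation) optionally perturbed by
#' radial Fourier "lobulation" terms: the boundary point at ellipse parameter
#' t is scaled by 1 + sum_k amp_k cos(k t + phase_k). With zero lobulation the
#' boundary is an exact ellipse. Area and perimeter are computed from the
#' polygonal boundary at arbitrary vertex density.
#'
#' @slot center numeric(2), (x, y) in pixels.
#' @slot a,b semi-major/semi-minor axes in pixels.
#' @slot orientation radians.
#' @slot lobes numeric matrix with columns `k`, `amp`, `phase`; `k >= 2`,
#'   `0 <= amp < 0.5`.
#' @slot intensity named numeric, per-channel mean intensity.
#'
#' @seealso [nucleusShape()], [renderField()]
#' @export
setClass("NucleusShape",
  representation(center = "numeric", a = "numeric", b = "numeric",
                 orientation = "numeric", lobes = "matrix",
                 intensity = "numeric"))

setValidity("NucleusShape", function(object) {
  if (length(object@center) != 2) return("center must be (x, y)")
  if (!(object@a >= object@b && object@b > 0)) return("need a >= b > 0")
  lb <- object@lobes
  if (nrow(lb) > 0) {
    if (!all(colnames(lb) == c("k", "amp", "phase"))) {
      return("lobes columns must be k/amp/phase")
    }
    if (any(lb[, "k"] < 2)) return("lobulation harmonics must have k >= 2")
    if (any(lb[, "amp"] < 0 | lb[, "amp"] >= 0.5)) {
      return("lobulation amplitudes must lie in [0, 0.5)")
    }
  }
  TRUE
})

#' MedianPolishFit: two-way additive fit of one plate
#'
#' Decomposition `value[i, j] = overall + row[i] + col[j] + residual[i, j]`
#' obtained by Tukey median polish over the fitted (library) cells, followed
#' by a canonical mean re-centering of the residuals (see the methods
#' vignette). Residuals are reported for all cells; masked-out (control,
#' empty) wells are scored against the fit but never inform it.
#'
#' @slot overall numeric grand effect.
#' @slot row,col numeric effect vectors.
#' @slot residuals numeric matrix, all cells.
#' @slot iterations integer sweeps used.
#' @slot converged logical.
#' @slot degenerate character, names of fully-masked rows/columns whose
#'   effects were pinned to zero.
#'
#' @seealso [medianPolish()], [bscorePlate()]
#' @export
setClass("MedianPolishFit",
  representation(overall = "numeric", row = "numeric", col = "numeric",
                 residuals = "matrix", iterations = "integer",
                 converged = "logical", degenerate = "character"))

setValidity("MedianPolishFit", function(object) {
  if (length(object@row) != nrow(object@residuals)) return("row length")
  if (length(object@col) != ncol(object@residuals)) return("col length")
  TRUE
})

#' ScreenScores: per-well and per-oligo screen statistics
#'
#' Output of the normalization chain: per-plate B-scores, per-replicate
#' robust Z-scores for every well, and the replicate-averaged Z per
#' (gene, oligo, feature).
#'
#' @slot well_scores data.frame: one row per (replicate, plate, well,
#'   feature) with `value`, `b_score`, `z`.
#' @slot oligo_scores data.frame: one row per (gene, oligo, feature) with
#'   per-replicate z columns, `z_mean`, `n_replicates`, `single_replicate`.
#' @slot features character, features scored (including `"cellcount"`).
#' @slot replicates integer, replicate ids scored.
#' @slot mad_constant numeric, the MAD scale constant used (1.4826).
#'
#' @seealso [scoreScreen()]
#' @export
setClass("ScreenScores",
  representation(well_scores = "data.frame", oligo_scores = "data.frame",
                 features = "character", replicates = "integer",
                 mad_constant = "numeric"))

#' GeneCallSet: gene-level hit calls
#'
#' Gene-level medians of oligo Z-scores per feature, directional hit flags
#' (shape = decreased circularity; size up/down = area; lamin A/C and lamin
#' B1 = decreased intensity), and the cell-number viability exclusion.
#' Excluded genes keep their flags for audit but are removed from hit lists.
#'
#' @slot calls data.frame, one row per gene.
#' @slot thresholds named numeric hit thresholds per class.
#' @slot viability_threshold numeric, cell-count median-Z cutoff (<= -2).
#' @slot two_sided_shape logical, whether shape calling was two-sided.
#'
#' @seealso [callHits()], [hitList()]
#' @export
setClass("GeneCallSet",
  representation(calls = "data.frame", thresholds = "numeric",
                 viability_threshold = "numeric", two_sided_shape = "logical"))

#' ScreenComparison: paired comparison of two screens
#'
#' Paired gene-level scores from two screens with their Spearman rank
#' correlation and the overlap of the hit sets.
#'
#' @slot paired data.frame with `gene_id`, `score_a`, `score_b`.
#' @slot rho numeric Spearman coefficient.
#' @slot feature character, the compared feature.
#' @slot hits_both,hits_a_only,hits_b_only character gene vectors.
#'
#' @seealso [compareScreens()]
#' @export
setClass("ScreenComparison",
  representation(paired = "data.frame", rho = "numeric", feature = "character",
                 hits_both = "character", hits_a_only = "character",
                 hits_b_only = "character"))

setValidity("ScreenComparison", function(object) {
  if (length(object@rho) == 1 && !is.na(object@rho) &&
      (object@rho < -1 || object@rho > 1)) {
    return("rho must lie in [-1, 1]")
  }
  TRUE
})
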