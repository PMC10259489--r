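#' @rdname accessors
#' @aliases layoutWells,ScreenLayout-method
setMethod("layoutWells", "ScreenLayout", function(x) x@wells)

#' @rdname accessors
#' @aliases libraryTable,ScreenLayout-method
setMethod("libraryTable", "ScreenLayout", function(x) {
  w <- x@wells
  w[w$role == "library", , drop = FALSE]
})

#' @rdname accessors
#' @aliases plateIds,ScreenLayout-method
setMethod("plateIds", "ScreenLayout", function(x) x@plate_ids)

#' @rdname accessors
#' @aliases geneEffects,GroundTruth-method
setMethod("geneEffects", "GroundTruth", function(x) x@gene_effects)

#' @rdname accessors
#' @aliases cytotoxicGenes,GroundTruth-method
setMethod("cytotoxicGenes", "GroundTruth", function(x) {
  names(x@cytotoxic)[x@cytotoxic < 1]
})

#' @rdname accessors
#' @aliases baseline,GroundTruth-method
setMethod("baseline", "GroundTruth", function(x) x@baseline)

#' @rdname accessors
#' @aliases wellScores,ScreenScores-method
setMethod("wellScores", "ScreenScores", function(x) x@well_scores)

#' @rdname accessors
#' @aliases oligoScores,ScreenScores-method
setMethod("oligoScores", "ScreenScores", function(x) x@oligo_scores)

#' @rdname accessors
#' @aliases geneCalls,GeneCallSet-method
setMethod("geneCalls", "GeneCallSet", function(x) x@calls)

#' @rdname accessors
#' @aliases hitList,GeneCallSet-method
setMethod("hitList", "GeneCallSet", function(x, class = "shape_hit") {
  cls <- match.arg(class, c("shape_hit", "size_up", "size_down",
                            "laminAC_down", "laminB1_down"))
  cal <- x@calls
  cal$gene_id[cal[[cls]] & !cal$excluded_cytotoxic %in% TRUE]
})

setMethod("show", "ScreenLayout", function(object) {
  w <- object@wells
  cat("ScreenLayout:", length(object@plate_ids), "plate(s),",
      object@n_rows, "x", object@n_cols, "wells\n")
  print(table(role = w$role))
  lib <- w[w$role == "library", ]
  cat(length(unique(lib$gene_id)), "genes x",
      length(unique(lib$oligo_id)), "oligos =", nrow(lib), "library wells\n")
})

setMethod("show", "GroundTruth", function(object) {
  ge <- object@gene_effects
  cat("GroundTruth:", nrow(ge), "genes,", ncol(ge), "features, seed",
      object@seed, "\n")
  n_hit <- colSums(ge != 0)
  cat("designed effects per feature:\n")
  print(n_hit)
  cat(sum(object@cytotoxic < 1), "cytotoxic gene(s)\n")
})

setMethod("show", "NucleusShape", function(object) {
  cat(sprintf("NucleusShape: center (%.1f, %.1f), a=%.1f b=%.1f, %d lobe(s)\n",
              object@center[1], object@center[2], object@a, object@b,
              nrow(object@lobes)))
})

setMethod("show", "MedianPolishFit", function(object) {
  cat("MedianPolishFit:", nrow(object@residuals), "x", ncol(object@residuals),
      "| overall", format(object@overall, digits = 4),
      "|", object@iterations, "sweep(s),",
      if (object@converged) "converged" else "NOT converged", "\n")
  if (length(object@degenerate)) {
    cat("fully-masked (effect pinned to 0):",
        paste(object@degenerate, collapse = ", "), "\n")
  }
})

setMethod("show", "ScreenScores", function(object) {
  cat("ScreenScores:", nrow(object@oligo_scores), "oligo x feature rows |",
      length(object@replicates), "replicate(s) | features:",
      paste(object@features, collapse = ", "), "\n")
})

setMethod("show", "GeneCallSet", function(object) {
  cal <- object@calls
  cat("GeneCallSet:", nrow(cal), "genes\n")
  for (cls in c("shape_hit", "size_up", "size_down", "laminAC_down",
                "laminB1_down")) {
    cat(sprintf("  %-13s %d hit(s)\n", cls, length(hitList(object, cls))))
  }
  cat("  excluded (cell-number Z <=", object@viability_threshold, "):",
      sum(cal$excluded_cytotoxic, na.rm = TRUE), "\n")
})

setMethod("show", "ScreenComparison", function(object) {
  cat("ScreenComparison (", object@feature, "): ",
      nrow(object@paired), " paired genes, Spearman rho = ",
      format(object@rho, digits = 4), "\n", sep = "")
  cat("hits in both:", length(object@hits_both),
      "| A only:", length(object@hits_a_only),
      "| B only:", length(object@hits_b_only), "\n")
})
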