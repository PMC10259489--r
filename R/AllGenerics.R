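#' Accessors for screen objects
#'
#' @param x a nucscreen S4 object.
#' @param ... passed to methods.
#' @return `layoutWells`/`libraryTable`: data.frame; `plateIds`: character;
#'   `geneEffects`: matrix; `baseline`: data.frame; `wellScores`/
#'   `oligoScores`/`geneCalls`: data.frame; `hitList`: character vector of
#'   gene ids.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("layoutWells", function(x) standardGeneric("layoutWells"))

#' @rdname accessors
#' @export
setGeneric("libraryTable", function(x) standardGeneric("libraryTable"))

#' @rdname accessors
#' @export
setGeneric("plateIds", function(x) standardGeneric("plateIds"))

#' @rdname accessors
#' @export
setGeneric("geneEffects", function(x) standardGeneric("geneEffects"))

#' @rdname accessors
#' @export
setGeneric("cytotoxicGenes", function(x) standardGeneric("cytotoxicGenes"))

#' @rdname accessors
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))

#' @rdname accessors
#' @export
setGeneric("wellScores", function(x) standardGeneric("wellScores"))

#' @rdname accessors
#' @export
setGeneric("oligoScores", function(x) standardGeneric("oligoScores"))

#' @rdname accessors
#' @export
setGeneric("geneCalls", function(x) standardGeneric("geneCalls"))

#' @param class hit class: one of `"shape_hit"`, `"size_up"`, `"size_down"`,
#'   `"laminAC_down"`, `"laminB1_down"`.
#' @rdname accessors
#' @export
setGeneric("hitList", function(x, class = "shape_hit") standardGeneric("hitList"))

#' Compare two screens
#'
#' @param a,b two [GeneCallSet-class] objects (or gene-level score tables).
#' @param ... passed to methods.
#' @export
setGeneric("compareScreens", function(a, b, ...) standardGeneric("compareScreens"))
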