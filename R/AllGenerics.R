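#' @include AllClasses.R
NULL

#' Accessors for sulcus masks and centroid paths
#'
#' Small read-only accessors for the scoring containers: the view,
#' hemisphere, label and rater of a [SulcusMask-class], its frame size and
#' pixel set, and the points/axis of a [CentroidPath-class].
#'
#' @param x a [SulcusMask-class] or [CentroidPath-class] object.
#' @return `viewId`, `hemisphere`, `sulcusLabel`, `raterId` and `pathAxis`
#'   return length-1 character vectors; `maskDim` an integer pair
#'   `c(rows, cols)`; `maskPixels` and `pathPoints` an integer matrix with
#'   columns `row`, `col`; `nPixels` an integer count.
#' @examples
#' m <- SulcusMask("lateral_left", "left", "S.C", "R1", c(20, 20),
#'                 cbind(row = 5:10, col = 10))
#' viewId(m); nPixels(m)
#' @name mask-accessors
NULL

#' @rdname mask-accessors
#' @export
setGeneric("viewId", function(x) standardGeneric("viewId"))
#' @rdname mask-accessors
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))
#' @rdname mask-accessors
#' @export
setGeneric("sulcusLabel", function(x) standardGeneric("sulcusLabel"))
#' @rdname mask-accessors
#' @export
setGeneric("raterId", function(x) standardGeneric("raterId"))
#' @rdname mask-accessors
#' @export
setGeneric("maskDim", function(x) standardGeneric("maskDim"))
#' @rdname mask-accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname mask-accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))
#' @rdname mask-accessors
#' @export
setGeneric("pathPoints", function(x) standardGeneric("pathPoints"))
#' @rdname mask-accessors
#' @export
setGeneric("pathAxis", function(x) standardGeneric("pathAxis"))

#' @rdname mask-accessors
setMethod("viewId", "SulcusMask", function(x) x@view)
#' @rdname mask-accessors
setMethod("hemisphere", "SulcusMask", function(x) x@hemisphere)
#' @rdname mask-accessors
setMethod("sulcusLabel", "SulcusMask", function(x) x@label)
#' @rdname mask-accessors
setMethod("raterId", "SulcusMask", function(x) x@rater)
#' @rdname mask-accessors
setMethod("maskDim", "SulcusMask", function(x) x@dim)
#' @rdname mask-accessors
setMethod("maskPixels", "SulcusMask", function(x) x@pixels)
#' @rdname mask-accessors
setMethod("nPixels", "SulcusMask", function(x) nrow(x@pixels))
#' @rdname mask-accessors
setMethod("pathPoints", "CentroidPath", function(x) x@points)
#' @rdname mask-accessors
setMethod("pathAxis", "CentroidPath", function(x) x@axis)

#' Registry accessors
#'
#' @param x a [LabelRegistry-class].
#' @return `mergeMap` returns the named source -> canonical character
#'   vector; `allLabels` every resolvable abbreviation (entries plus
#'   canonical extras); `canonicalLabels` the distinct post-merge label set;
#'   `nomenclature` the entry table as a data.frame.
#' @examples
#' reg <- loadNomenclature()
#' length(canonicalLabels(reg))
#' @name registry-accessors
NULL

#' @rdname registry-accessors
#' @export
setGeneric("mergeMap", function(x) standardGeneric("mergeMap"))
#' @rdname registry-accessors
#' @export
setGeneric("allLabels", function(x) standardGeneric("allLabels"))
#' @rdname registry-accessors
#' @export
setGeneric("canonicalLabels", function(x) standardGeneric("canonicalLabels"))
#' @rdname registry-accessors
#' @export
setGeneric("nomenclature", function(x) standardGeneric("nomenclature"))

#' @rdname registry-accessors
setMethod("mergeMap", "LabelRegistry", function(x) x@mergeMap)
#' @rdname registry-accessors
setMethod("allLabels", "LabelRegistry", function(x)
    c(x@entries$abbreviation, x@extras$abbreviation))
#' @rdname registry-accessors
setMethod("canonicalLabels", "LabelRegistry", function(x)
    unique(canonicalize(allLabels(x), x)))
#' @rdname registry-accessors
setMethod("nomenclature", "LabelRegistry", function(x) x@entries)

#' @describeIn LabelRegistry-class number of nomenclature entries
#'   (canonical extras not counted).
#' @param x a [LabelRegistry-class].
#' @export
setMethod("length", "LabelRegistry", function(x) nrow(x@entries))

#' Aggregate table accessors
#'
#' @param x an [AggregateTable-class].
#' @return `tableCells` the long-format per-(label, hemisphere, view) cell
#'   table; `tableMarginals` the per-(label, hemisphere) means across
#'   present views.
#' @name aggregate-accessors
NULL

#' @rdname aggregate-accessors
#' @export
setGeneric("tableCells", function(x) standardGeneric("tableCells"))
#' @rdname aggregate-accessors
#' @export
setGeneric("tableMarginals", function(x) standardGeneric("tableMarginals"))

#' @rdname aggregate-accessors
setMethod("tableCells", "AggregateTable", function(x) x@cells)
#' @rdname aggregate-accessors
setMethod("tableMarginals", "AggregateTable", function(x) x@marginals)

#' Extract the four measures of a SimilarityScore
#'
#' @param x a [SimilarityScore-class].
#' @return named numeric vector (`dice`, `mmed`, `mmedn`, `siss`).
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname scoreValues
setMethod("scoreValues", "SimilarityScore", function(x)
    c(dice = x@dice, mmed = x@mmed, mmedn = x@mmedn, siss = x@siss))

setMethod("show", "LabelRegistry", function(object) {
    cat("LabelRegistry with", nrow(object@entries), "nomenclature entries,",
        length(object@mergeMap), "merge rules,",
        length(canonicalLabels(object)), "canonical labels\n")
    ex <- object@extras
    if (nrow(ex))
        cat("  extras:", paste(ex$abbreviation, collapse = ", "), "\n")
})

setMethod("show", "SulcusMask", function(object) {
    cat(sprintf("SulcusMask %s [%s/%s] rater=%s: %d px on %dx%d frame\n",
                object@label, object@view, object@hemisphere, object@rater,
                nrow(object@pixels), object@dim[1L], object@dim[2L]))
})

setMethod("show", "CentroidPath", function(object) {
    cat(sprintf("CentroidPath: %d points, %s axis\n",
                nrow(object@points), object@axis))
})

setMethod("show", "SimilarityScore", function(object) {
    cat(sprintf(
        "SimilarityScore: dice=%.3f mmed=%.2f px mmedn=%.3f siss=%.3f%s\n",
        object@dice, object@mmed, object@mmedn, object@siss,
        if (object@saturated) " (saturated)" else ""))
})

setMethod("show", "AggregateTable", function(object) {
    cat("AggregateTable:", nrow(object@cells), "cells,",
        nrow(object@marginals), "label/hemisphere marginals\n")
    if (nrow(object@cells)) {
        w <- wideTable(object)
        print(utils::head(w, 10L))
        if (nrow(w) > 10L) cat("...", nrow(w) - 10L, "more rows\n")
    }
})

#' Construct a SulcusMask
#'
#' Validating constructor: pixel rows are deduplicated and ordered, and
#' coordinates are checked against the frame.
#'
#' @param view one of [sulcusViews].
#' @param hemisphere `"left"`, `"right"` or `"unassigned"`.
#' @param label sulcus abbreviation.
#' @param rater rater identifier (`"reference"` for ground truth masks).
#' @param dim integer `c(rows, cols)` frame size.
#' @param pixels 2-column matrix of 1-based `(row, col)` coordinates.
#' @return a [SulcusMask-class] object.
#' @examples
#' SulcusMask("superior", "left", "S.C", "R1", c(10, 10),
#'            cbind(row = 5, col = 2:8))
#' @export
SulcusMask <- function(view, hemisphere, label, rater, dim, pixels) {
    pixels <- as.matrix(pixels)
    if (ncol(pixels) != 2L)
        stop("pixels must have two columns (row, col)")
    storage.mode(pixels) <- "integer"
    colnames(pixels) <- c("row", "col")
    pixels <- unique(pixels)
    pixels <- pixels[order(pixels[, 1L], pixels[, 2L]), , drop = FALSE]
    new("SulcusMask", view = view, hemisphere = hemisphere, label = label,
        rater = rater, dim = as.integer(dim), pixels = pixels)
}
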