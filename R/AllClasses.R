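#' @import methods
NULL

#' Anatomical views of the endocast
#'
#' The five fixed 2D projections on which sulci are drawn and scored.
#' Reliability tables are split by hemisphere within each view; the two
#' lateral views carry a single, fixed hemisphere.
#'
#' @export
sulcusViews <- c("anterior", "superior", "posterior",
                 "lateral_left", "lateral_right")

#' @rdname sulcusViews
#' @export
sulcusHemispheres <- c("left", "right", "unassigned")

## sentinel used in correction files for drawings that match no real sulcus
.NO_SULCUS <- "NONE"

#' LabelRegistry: the sulcus nomenclature and its merge rules
#'
#' Holds the 42-entry sulcus nomenclature, a merge map collapsing
#' anatomically grouped labels onto canonical ones (e.g. the five
#' pre-central variants onto \code{S.Pe.C}), and any canonical labels that
#' exist only as merge targets. Occipital sulci drawn beyond the official
#' list can be registered as extras that canonicalize to \code{Occipital}.
#'
#' @slot entries data.frame with columns \code{index}, \code{abbreviation},
#'   \code{full_name}, \code{group}; one row per nomenclature entry.
#' @slot extras data.frame with the same columns for labels that are not
#'   nomenclature rows: merge targets such as \code{S.Pe.C}
#'   (group \code{"canonical"}) and user-registered occipital variants
#'   (group \code{"occipital_extra"}).
#' @slot mergeMap named character vector, source abbreviation ->
#'   canonical abbreviation.
#'
#' @seealso [loadNomenclature()], [canonicalize()], [addOccipitalLabel()]
#' @export
setClass("LabelRegistry",
         representation(entries = "data.frame",
                        extras = "data.frame",
                        mergeMap = "character"))

setValidity("LabelRegistry", function(object) {
    msgs <- character()
    need <- c("index", "abbreviation", "full_name", "group")
    if (!all(need %in% names(object@entries)))
        return(paste("entries must have columns",
                     paste(need, collapse = ", ")))
    abbr <- c(object@entries$abbreviation, object@extras$abbreviation)
    if (anyDuplicated(abbr))
        msgs <- c(msgs, paste("duplicate abbreviation:",
                              paste(unique(abbr[duplicated(abbr)]),
                                    collapse = ", ")))
    idx <- object@entries$index
    idx <- idx[!is.na(idx)]
    if (anyDuplicated(idx))
        msgs <- c(msgs, "nomenclature indices must be unique")
    mm <- object@mergeMap
    if (length(mm)) {
        if (is.null(names(mm)) || any(!nzchar(names(mm))))
            msgs <- c(msgs, "mergeMap must be a named character vector")
        bad <- setdiff(unname(mm), abbr)
        if (length(bad))
            msgs <- c(msgs, paste("unknown merge target:",
                                  paste(unique(bad), collapse = ", ")))
        ## idempotence: a merge target may not itself be a merge source
        twice <- intersect(unname(mm), names(mm))
        if (length(twice))
            msgs <- c(msgs, paste("merge target is also a merge source:",
                                  paste(twice, collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' SulcusMask: one sulcus drawing (or reference sulcus) as a pixel set
#'
#' A binary mask on a fixed-size 2D raster grid, carrying the metadata
#' needed for scoring and aggregation. Pixel coordinates are 1-based
#' \code{(row, col)} with the origin at the top-left of the view image, so
#' isolation from a label image is translation-free: mask coordinates equal
#' coordinates in the source image.
#'
#' @slot view one of [sulcusViews].
#' @slot hemisphere \code{"left"}, \code{"right"} or \code{"unassigned"}.
#' @slot label sulcus abbreviation (resolvable in a [LabelRegistry-class]).
#' @slot rater rater identifier, or \code{"reference"} for ground truth.
#' @slot dim integer \code{c(rows, cols)} of the view frame.
#' @slot pixels integer matrix with columns \code{row}, \code{col}; one row
#'   per foreground pixel, deduplicated, within the frame.
#'
#' @seealso [SulcusMask()], [diceScore()], [scorePair()]
#' @export
setClass("SulcusMask",
         representation(view = "character", hemisphere = "character",
                        label = "character", rater = "character",
                        dim = "integer", pixels = "matrix"))

setValidity("SulcusMask", function(object) {
    msgs <- character()
    if (length(object@view) != 1L || !object@view %in% sulcusViews)
        msgs <- c(msgs, paste("view must be one of:",
                              paste(sulcusViews, collapse = ", ")))
    if (length(object@hemisphere) != 1L ||
        !object@hemisphere %in% sulcusHemispheres)
        msgs <- c(msgs, "hemisphere must be left, right or unassigned")
    if (length(object@label) != 1L || !nzchar(object@label))
        msgs <- c(msgs, "label must be a non-empty string")
    if (length(object@dim) != 2L || any(object@dim < 1L))
        msgs <- c(msgs, "dim must be two positive integers (rows, cols)")
    px <- object@pixels
    if (!is.matrix(px) || ncol(px) != 2L || !is.numeric(px))
        msgs <- c(msgs, "pixels must be a 2-column numeric matrix")
    else {
        if (nrow(px) == 0L)
            msgs <- c(msgs, "mask has no foreground pixels")
        else if (any(px < 1L) || any(px[, 1L] > object@dim[1L]) ||
                 any(px[, 2L] > object@dim[2L]))
            msgs <- c(msgs, "pixels outside the view frame")
    }
    if (length(msgs)) msgs else TRUE
})

#' CentroidPath: single-pixel-wide streamline of a drawn stroke
#'
#' The ordered central streamline summarizing a hand-drawn sulcus of
#' arbitrary width: exactly one pixel per occupied coordinate of the
#' independent axis, sorted along that axis.
#'
#' @slot points integer matrix with columns \code{row}, \code{col}.
#' @slot axis \code{"horizontal"} (independent axis = columns) or
#'   \code{"vertical"} (independent axis = rows).
#'
#' @seealso [extractCentroid()], [mmed()]
#' @export
setClass("CentroidPath",
         representation(points = "matrix", axis = "character"))

setValidity("CentroidPath", function(object) {
    msgs <- character()
    if (!object@axis %in% c("horizontal", "vertical"))
        msgs <- c(msgs, "axis must be 'horizontal' or 'vertical'")
    pts <- object@points
    if (!is.matrix(pts) || ncol(pts) != 2L || nrow(pts) == 0L)
        msgs <- c(msgs, "points must be a non-empty 2-column matrix")
    else {
        ind <- if (identical(object@axis, "horizontal")) pts[, 2L]
               else pts[, 1L]
        if (anyDuplicated(ind))
            msgs <- c(msgs,
                      "one point per independent-axis coordinate required")
        if (is.unsorted(ind))
            msgs <- c(msgs, "points must be sorted along the axis")
    }
    if (length(msgs)) msgs else TRUE
})

#' SimilarityScore: the four agreement measures for one drawing/reference pair
#'
#' @slot dice Dice overlap of the full-width drawing vs the reference,
#'   in \[0, 1\].
#' @slot mmed mean minimum Euclidean distance (pixels) from the drawing's
#'   centroid streamline to the reference pixel set; directed, >= 0.
#' @slot mmedn normalized MMED in \[0, 1\] (0 when saturated).
#' @slot siss arithmetic mean of \code{dice} and \code{mmedn}.
#' @slot saturated TRUE when \code{mmed} reached the normalization
#'   threshold, i.e. the drawing shows no spatial similarity.
#'
#' @seealso [scorePair()]
#' @export
setClass("SimilarityScore",
         representation(dice = "numeric", mmed = "numeric",
                        mmedn = "numeric", siss = "numeric",
                        saturated = "logical"))

setValidity("SimilarityScore", function(object) {
    tol <- 1e-9
    msgs <- character()
    if (object@dice < -tol || object@dice > 1 + tol)
        msgs <- c(msgs, "dice must lie in [0, 1]")
    if (object@mmed < 0)
        msgs <- c(msgs, "mmed must be non-negative")
    if (object@mmedn < -tol || object@mmedn > 1 + tol)
        msgs <- c(msgs, "mmedn must lie in [0, 1]")
    if (object@saturated && object@mmedn != 0)
        msgs <- c(msgs, "mmedn must be 0 when saturated")
    if (abs(object@siss - (object@dice + object@mmedn) / 2) > tol)
        msgs <- c(msgs, "siss must equal (dice + mmedn)/2")
    if (length(msgs)) msgs else TRUE
})

#' AggregateTable: mean SISS per sulcus, hemisphere and view
#'
#' The reporting container: one cell per (canonical label, hemisphere, view)
#' holding the unweighted mean SISS over the raters who drew that cell,
#' plus per-(label, hemisphere) marginal means across the views in which the
#' cell is present. Absent cells are genuinely missing, never zero-filled.
#'
#' @slot cells data.frame with columns \code{label}, \code{hemisphere},
#'   \code{view}, \code{mean_siss}, \code{n_raters}.
#' @slot marginals data.frame with columns \code{label}, \code{hemisphere},
#'   \code{mean_siss}, \code{n_views}.
#'
#' @seealso [meanTable()], [wideTable()], [classifyZones()]
#' @export
setClass("AggregateTable",
         representation(cells = "data.frame", marginals = "data.frame"))

setValidity("AggregateTable", function(object) {
    msgs <- character()
    cl <- object@cells
    need <- c("label", "hemisphere", "view", "mean_siss", "n_raters")
    if (!all(need %in% names(cl)))
        return(paste("cells must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(cl)) {
        if (any(cl$mean_siss < 0 | cl$mean_siss > 1))
            msgs <- c(msgs, "cell means must lie in [0, 1]")
        if (any(cl$n_raters < 1L))
            msgs <- c(msgs, "present cells need n_raters >= 1")
    }
    if (length(msgs)) msgs else TRUE
})
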