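## ---- scoring core ---------------------------------------------------------

#' Dice overlap between two binary masks
#'
#' The Sørensen–Dice coefficient \eqn{2|A \cap B| / (|A| + |B|)} over the
#' two pixel sets: 1 for identical masks, 0 for disjoint ones. Symmetric.
#' Both masks must be non-empty and live on the same view frame; drawings
#' are compared at their full drawn width.
#'
#' @param A,B [SulcusMask-class] objects on the same frame.
#' @return numeric in \[0, 1\].
#' @examples
#' m <- SulcusMask("superior", "left", "S.C", "R1", c(10, 10),
#'                 cbind(5, 2:8))
#' diceScore(m, m)
#' @export
diceScore <- function(A, B) {
    stopifnot(is(A, "SulcusMask"), is(B, "SulcusMask"))
    .checkSameFrame(A, B)
    if (nPixels(A) == 0L || nPixels(B) == 0L)
        stop("dice is undefined for an empty mask")
    ka <- .pixelKey(maskPixels(A), maskDim(A))
    kb <- .pixelKey(maskPixels(B), maskDim(B))
    2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}

#' Extract the centroid streamline of a drawn stroke
#'
#' Reduces a stroke of arbitrary width to a single-pixel-wide ordered
#' streamline: the independent axis is the axis along which the stroke's
#' bounding box is longer (ties favour horizontal, i.e. columns); at every
#' occupied independent-axis coordinate the transverse coordinate is
#' estimated by the per-coordinate conditional mean of the stroke's pixels
#' (a bin-width-1 regressogram), rounded half-away-from-zero to an integer
#' pixel and clipped to the stroke's bounding box. On an already
#' single-pixel-wide stroke the streamline is the stroke itself.
#'
#' @param A a non-empty [SulcusMask-class].
#' @return a [CentroidPath-class].
#' @examples
#' bar <- SulcusMask("superior", "left", "S.C", "R1", c(20, 20),
#'                   as.matrix(expand.grid(row = 5:7, col = 1:10)))
#' pathPoints(extractCentroid(bar))   # all at row 6
#' @export
extractCentroid <- function(A) {
    stopifnot(is(A, "SulcusMask"))
    px <- maskPixels(A)
    if (nrow(px) == 0L)
        stop("cannot extract a centroid from an empty mask")
    spanR <- diff(range(px[, 1L])) + 1L
    spanC <- diff(range(px[, 2L])) + 1L
    horizontal <- spanC >= spanR
    ind <- if (horizontal) px[, 2L] else px[, 1L]
    tra <- if (horizontal) px[, 1L] else px[, 2L]
    mu <- tapply(tra, ind, mean)
    est <- .roundHalfOut(unname(mu))
    est <- pmin(max(tra), pmax(min(tra), est))
    iv <- as.integer(names(mu))
    o <- order(iv)
    pts <- if (horizontal) cbind(row = est[o], col = iv[o])
           else cbind(row = iv[o], col = est[o])
    storage.mode(pts) <- "integer"
    new("CentroidPath", points = pts,
        axis = if (horizontal) "horizontal" else "vertical")
}

#' Mean minimum Euclidean distance from a streamline to a reference sulcus
#'
#' For each point of the drawing's centroid streamline, the Euclidean
#' distance to the nearest pixel of the reference mask is taken; MMED is
#' the mean of those minima, in pixel units. The measure is directed
#' (streamline to reference): the reference keeps its full pixel set
#' because its shape is too complex to reduce to a streamline.
#'
#' @param A_centroid a [CentroidPath-class] (or a [SulcusMask-class], whose
#'   centroid is extracted first).
#' @param B a non-empty [SulcusMask-class] reference.
#' @return numeric >= 0, pixels.
#' @examples
#' p <- new("CentroidPath", points = cbind(row = 1L, col = 1L),
#'          axis = "horizontal")
#' B <- SulcusMask("superior", "left", "S.C", "reference", c(10, 10),
#'                 cbind(4, 5))
#' mmed(p, B)   # 3-4-5 triangle: 5
#' @export
mmed <- function(A_centroid, B) {
    if (is(A_centroid, "SulcusMask"))
        A_centroid <- extractCentroid(A_centroid)
    stopifnot(is(A_centroid, "CentroidPath"), is(B, "SulcusMask"))
    a <- pathPoints(A_centroid)
    b <- maskPixels(B)
    if (nrow(a) == 0L || nrow(b) == 0L)
        stop("mmed is undefined for an empty operand")
    ## row/col offsets between every streamline point and reference pixel;
    ## modest sizes (<= a few thousand pixels) keep this dense form cheap
    dr <- outer(a[, 1L], b[, 1L], "-")
    dc <- outer(a[, 2L], b[, 2L], "-")
    mins <- sqrt(apply(dr * dr + dc * dc, 1L, min))
    mean(mins)
}

#' Normalize an MMED value to a similarity in \[0, 1\]
#'
#' Distances below the saturation threshold map linearly onto similarity,
#' \eqn{1 - m/T}; at and beyond the threshold the similarity is 0 — a
#' distance that large means the drawing bears no spatial relation to the
#' reference. The function is continuous and non-increasing on
#' \eqn{[0, \infty)}. The default threshold is 100 pixels.
#'
#' @param m MMED value, >= 0.
#' @param threshold saturation threshold in pixels.
#' @return numeric in \[0, 1\].
#' @examples
#' normalizeMmed(c(0, 5, 100, 150))
#' @export
normalizeMmed <- function(m, threshold = 100) {
    if (any(m < 0))
        stop("MMED must be non-negative")
    if (threshold <= 0)
        stop("threshold must be positive")
    ifelse(m < threshold, 1 - m / threshold, 0)
}

#' Combine Dice and normalized MMED into the SISS index
#'
#' The similarity index for shape and spatial comparison is the arithmetic
#' mean of the Dice overlap and the normalized MMED, so both components
#' operate on the same \[0, 1\] scale: 0 means no similarity or proximity,
#' 1 perfect agreement.
#'
#' @param dice Dice value(s) in \[0, 1\].
#' @param mmedn normalized MMED value(s) in \[0, 1\].
#' @return numeric in \[0, 1\].
#' @examples
#' sissScore(0.5, 0.95)
#' @export
sissScore <- function(dice, mmedn) {
    if (any(dice < 0 | dice > 1))
        stop("dice must lie in [0, 1]")
    if (any(mmedn < 0 | mmedn > 1))
        stop("mmedn must lie in [0, 1]")
    (dice + mmedn) / 2
}

#' Score one drawing against its reference sulcus
#'
#' The full per-pair computation: Dice on the full-width drawing versus the
#' reference pixels; centroid extraction on the drawing only; MMED from the
#' centroid streamline to all reference pixels; normalization at
#' `threshold`; SISS as the mean of the two components.
#'
#' @param drawing rater [SulcusMask-class].
#' @param reference ground-truth [SulcusMask-class] on the same frame.
#' @param threshold MMED saturation threshold in pixels (default 100).
#' @return a [SimilarityScore-class].
#' @examples
#' r <- SulcusMask("superior", "left", "S.C", "reference", c(30, 30),
#'                 cbind(15, 3:25))
#' d <- SulcusMask("superior", "left", "S.C", "R1", c(30, 30),
#'                 cbind(15, 3:25))
#' scorePair(d, r)
#' @export
scorePair <- function(drawing, reference, threshold = 100) {
    stopifnot(is(drawing, "SulcusMask"), is(reference, "SulcusMask"))
    .checkSameFrame(drawing, reference)
    d <- diceScore(drawing, reference)
    m <- mmed(extractCentroid(drawing), reference)
    sat <- m >= threshold
    mn <- normalizeMmed(m, threshold)
    new("SimilarityScore", dice = d, mmed = m, mmedn = mn,
        siss = sissScore(d, mn), saturated = sat)
}
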