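## ---- cohort scoring and reporting ----------------------------------------

#' Score a cohort of rater drawings against the reference sulci
#'
#' Runs the per-pair scoring over every drawing of every rater. Without
#' `corrections` this is the raw-label analysis (labels taken as the raters
#' wrote them); with `corrections` the corrected analysis (mislabelled
#' drawings reassigned, possibly to two sulci, and no-sulcus drawings
#' dropped) is run instead. Labels of drawings and references are
#' canonicalized through the registry before matching. Drawings whose
#' (view, hemisphere, label) has no reference sulcus are excluded from the
#' score table and reported separately: marks without a corresponding real
#' sulcus are a documented phenomenon, not an error.
#'
#' @param drawings list of rater [SulcusMask-class] objects.
#' @param references list of ground-truth [SulcusMask-class] objects.
#' @param registry a [LabelRegistry-class].
#' @param corrections optional correction data.frame
#'   (see [correctionTable()]).
#' @param threshold MMED saturation threshold in pixels.
#' @return list with elements \code{scores} (data.frame: rater, view,
#'   hemisphere, label, dice, mmed, mmedn, siss, saturated, corrected) and
#'   \code{unmatched} (data.frame of excluded drawings).
#' @seealso [meanTable()], [identificationRate()], [classifyZones()]
#' @export
scoreCohort <- function(drawings, references, registry,
                        corrections = NULL, threshold = 100) {
    stopifnot(is(registry, "LabelRegistry"))
    refKey <- vapply(references, function(r)
        .cellKey(viewId(r), hemisphere(r),
                 canonicalize(sulcusLabel(r), registry)), character(1))
    if (anyDuplicated(refKey))
        stop("duplicate reference sulcus for: ",
             paste(unique(refKey[duplicated(refKey)]), collapse = ", "))
    refs <- stats::setNames(references, refKey)

    drawings <- applyCorrections(drawings, corrections, registry)
    corrFlag <- attr(drawings, "corrected")

    rows <- list(); unmatched <- list()
    for (i in seq_along(drawings)) {
        m <- drawings[[i]]
        lab <- canonicalize(sulcusLabel(m), registry)
        key <- .cellKey(viewId(m), hemisphere(m), lab)
        if (is.null(refs[[key]])) {
            unmatched[[length(unmatched) + 1L]] <- data.frame(
                rater = raterId(m), view = viewId(m),
                hemisphere = hemisphere(m), label = lab,
                n_pixels = nPixels(m), stringsAsFactors = FALSE)
            next
        }
        s <- scorePair(m, refs[[key]], threshold = threshold)
        rows[[length(rows) + 1L]] <- data.frame(
            rater = raterId(m), view = viewId(m),
            hemisphere = hemisphere(m), label = lab,
            dice = s@dice, mmed = s@mmed, mmedn = s@mmedn, siss = s@siss,
            saturated = s@saturated, corrected = corrFlag[i],
            stringsAsFactors = FALSE)
    }
    empty <- data.frame(rater = character(), view = character(),
                        hemisphere = character(), label = character(),
                        dice = numeric(), mmed = numeric(),
                        mmedn = numeric(), siss = numeric(),
                        saturated = logical(), corrected = logical(),
                        stringsAsFactors = FALSE)
    list(scores = if (length(rows)) do.call(rbind, rows) else empty,
         unmatched = if (length(unmatched)) do.call(rbind, unmatched)
                     else empty[c("rater", "view", "hemisphere", "label")])
}

## accept either the scoreCohort() result or a bare score data.frame
.scoresFrame <- function(scores) {
    if (is.list(scores) && !is.data.frame(scores) &&
        !is.null(scores$scores))
        scores <- scores$scores
    if (!is.data.frame(scores) || !"siss" %in% names(scores))
        stop("expected a score table with a 'siss' column")
    scores
}

#' Aggregate scores into the per-sulcus reliability table
#'
#' Cell mean = unweighted mean SISS over the raters who drew that
#' (label, hemisphere, view); the per-(label, hemisphere) marginal is the
#' unweighted mean over the views in which the cell is present — absent
#' cells are skipped, never counted as zero.
#'
#' @param scores a score data.frame or the result of [scoreCohort()].
#' @return an [AggregateTable-class].
#' @examples
#' sc <- data.frame(rater = c("R1", "R2"), view = "superior",
#'                  hemisphere = "left", label = "S.C",
#'                  siss = c(0.4, 0.6))
#' tableCells(meanTable(sc))
#' @export
meanTable <- function(scores) {
    scores <- .scoresFrame(scores)
    if (nrow(scores) == 0L)
        stop("cannot aggregate an empty score table")
    key <- .cellKey(scores$view, scores$hemisphere, scores$label)
    cells <- do.call(rbind, lapply(split(scores, key), function(d)
        data.frame(label = d$label[1L], hemisphere = d$hemisphere[1L],
                   view = d$view[1L], mean_siss = mean(d$siss),
                   n_raters = length(unique(d$rater)),
                   stringsAsFactors = FALSE)))
    cells <- cells[order(cells$label, cells$hemisphere, cells$view), ]
    rownames(cells) <- NULL
    mk <- paste(cells$label, cells$hemisphere, sep = "|")
    marg <- do.call(rbind, lapply(split(cells, mk), function(d)
        data.frame(label = d$label[1L], hemisphere = d$hemisphere[1L],
                   mean_siss = mean(d$mean_siss), n_views = nrow(d),
                   stringsAsFactors = FALSE)))
    rownames(marg) <- NULL
    new("AggregateTable", cells = cells, marginals = marg)
}

#' Spread an AggregateTable into the wide reporting layout
#'
#' One row per canonical label; one column per (view, hemisphere)
#' combination plus the left/right marginal averages. Missing cells are
#' `NA` (rendered as dashes by [writeAggregateTable()]).
#'
#' @param x an [AggregateTable-class].
#' @param digits rounding applied to the displayed means (default 2,
#'   matching the reporting convention; `NULL` for full precision).
#' @return a data.frame.
#' @export
wideTable <- function(x, digits = 2) {
    stopifnot(is(x, "AggregateTable"))
    cols <- list(c("anterior", "left"), c("anterior", "right"),
                 c("superior", "left"), c("superior", "right"),
                 c("posterior", "left"), c("posterior", "right"),
                 c("lateral_left", "left"), c("lateral_right", "right"))
    nm <- c("anterior_left", "anterior_right", "superior_left",
            "superior_right", "posterior_left", "posterior_right",
            "lateral_left", "lateral_right")
    cl <- x@cells
    labs <- unique(cl$label)
    out <- data.frame(label = labs, stringsAsFactors = FALSE)
    for (k in seq_along(cols)) {
        v <- cols[[k]][1L]; h <- cols[[k]][2L]
        out[[nm[k]]] <- vapply(labs, function(lb) {
            i <- which(cl$label == lb & cl$view == v & cl$hemisphere == h)
            if (length(i)) cl$mean_siss[i] else NA_real_
        }, numeric(1))
    }
    mg <- x@marginals
    for (h in c("left", "right"))
        out[[paste0("average_", h)]] <- vapply(labs, function(lb) {
            i <- which(mg$label == lb & mg$hemisphere == h)
            if (length(i)) mg$mean_siss[i] else NA_real_
        }, numeric(1))
    if (!is.null(digits))
        out[-1L] <- lapply(out[-1L], round, digits = digits)
    rownames(out) <- NULL
    out
}

#' @rdname wideTable
#' @param path output CSV path; missing cells are written as \code{"-"}.
#' @export
writeAggregateTable <- function(x, path, digits = 2) {
    w <- wideTable(x, digits = digits)
    w[-1L] <- lapply(w[-1L], function(cc) ifelse(is.na(cc), "-",
                                                 format(cc)))
    utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Fraction of raters who identified each sulcus in each view
#'
#' @param scores a score data.frame or [scoreCohort()] result.
#' @param nTotalRaters cohort size used as the denominator (the full
#'   cohort, not per-view participation).
#' @return data.frame with columns \code{label}, \code{hemisphere},
#'   \code{view}, \code{n_raters}, \code{rate}.
#' @examples
#' sc <- data.frame(rater = paste0("R", 1:7), view = "superior",
#'                  hemisphere = "left", label = "S.C", siss = 0.5)
#' identificationRate(sc, 14)$rate   # 0.5
#' @export
identificationRate <- function(scores, nTotalRaters) {
    if (nTotalRaters < 1L)
        stop("nTotalRaters must be >= 1")
    scores <- .scoresFrame(scores)
    if (nrow(scores) == 0L)
        return(data.frame(label = character(), hemisphere = character(),
                          view = character(), n_raters = integer(),
                          rate = numeric(), stringsAsFactors = FALSE))
    key <- .cellKey(scores$view, scores$hemisphere, scores$label)
    out <- do.call(rbind, lapply(split(scores, key), function(d)
        data.frame(label = d$label[1L], hemisphere = d$hemisphere[1L],
                   view = d$view[1L],
                   n_raters = length(unique(d$rater)),
                   stringsAsFactors = FALSE)))
    out$rate <- out$n_raters / nTotalRaters
    rownames(out) <- NULL
    out
}

#' Classify sulci into reliability zones
#'
#' Summarizes, per (label, hemisphere), whether sulcal identification is
#' reliable: \code{green} when in at least one view the mean SISS exceeds
#' `sissGreen` and more than `minRate` of the cohort drew the sulcus there;
#' \code{yellow} when the best such view reaches only
#' (`sissYellow`, `sissGreen`]; \code{red} otherwise (score too low, or
#' never drawn by enough raters). Boundaries are strict as stated.
#'
#' @param table an [AggregateTable-class] (typically from the
#'   corrected-label analysis).
#' @param rates data.frame from [identificationRate()].
#' @param sissGreen,sissYellow,minRate zone thresholds.
#' @return data.frame with columns \code{label}, \code{hemisphere},
#'   \code{zone}, \code{best_view_siss}, \code{best_view_rate}.
#' @examples
#' sc <- data.frame(rater = paste0("R", 1:6), view = "superior",
#'                  hemisphere = "left", label = "S.C", siss = 0.55)
#' tb <- meanTable(sc)
#' classifyZones(tb, identificationRate(sc, 14))
#' @export
classifyZones <- function(table, rates, sissGreen = 0.5,
                          sissYellow = 0.4, minRate = 0.2) {
    stopifnot(is(table, "AggregateTable"))
    cl <- merge(table@cells,
                rates[c("label", "hemisphere", "view", "rate")],
                by = c("label", "hemisphere", "view"), all.x = TRUE)
    cl$rate[is.na(cl$rate)] <- 0
    mk <- paste(cl$label, cl$hemisphere, sep = "|")
    out <- do.call(rbind, lapply(split(cl, mk), function(d) {
        q <- d[d$rate > minRate, , drop = FALSE]
        best <- if (nrow(q)) max(q$mean_siss) else NA_real_
        zone <- if (!is.na(best) && best > sissGreen) "green"
                else if (!is.na(best) && best > sissYellow) "yellow"
                else "red"
        data.frame(label = d$label[1L], hemisphere = d$hemisphere[1L],
                   zone = zone,
                   best_view_siss = if (is.na(best)) max(d$mean_siss)
                                    else best,
                   best_view_rate = max(d$rate),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Read / write long-format score tables
#'
#' @param scores a score data.frame or [scoreCohort()] result.
#' @param path CSV path.
#' @return `readScores` the score data.frame; `writeScores` the path,
#'   invisibly.
#' @export
writeScores <- function(scores, path) {
    utils::write.csv(.scoresFrame(scores), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("rater", "view", "hemisphere", "label", "dice", "mmed",
              "mmedn", "siss")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("malformed score table, missing column(s): ",
             paste(miss, collapse = ", "))
    tab$rater <- as.character(tab$rater)
    tab
}
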