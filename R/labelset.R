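## ---- nomenclature and label handling -------------------------------------

## merge rules collapsing anatomically grouped labels onto one canonical
## label: central sylvian -> central; the five pre-central variants ->
## S.Pe.C; retro-central transverse ramus -> F.I.P.Po.C.inf
.defaultMergeMap <- c(
    "S.C.sylvian"       = "S.C",
    "S.Pe.C.median"     = "S.Pe.C",
    "S.Pe.C.marginal"   = "S.Pe.C",
    "S.Pe.C.sup"        = "S.Pe.C",
    "S.Pe.C.inter"      = "S.Pe.C",
    "S.Pe.C.inf"        = "S.Pe.C",
    "F.C.L.r.retroC.tr" = "F.I.P.Po.C.inf")

## canonical labels that exist only as merge targets, with display names
.defaultExtraCanonicals <- c("S.Pe.C" = "Pre-central sulcus")

## abbreviations are stored without trailing periods; source tables print
## them inconsistently ("S.T.s." vs "S.T.s")
.normLabel <- function(x) sub("\\.+$", "", trimws(x))

#' Load the sulcus nomenclature into a LabelRegistry
#'
#' Reads a delimited nomenclature table (columns \code{abbreviation},
#' \code{full_name}, \code{group}, optionally \code{index}) and installs the
#' merge rules. The packaged default is the 42-entry endocast nomenclature;
#' its default merges collapse \code{S.C.sylvian} into \code{S.C}, the five
#' pre-central variants into \code{S.Pe.C} and \code{F.C.L.r.retroC.tr}
#' into \code{F.I.P.Po.C.inf}, leaving 36 distinct canonical labels.
#'
#' Merge targets that are not themselves nomenclature rows (\code{S.Pe.C})
#' are auto-registered as canonical extras; a target that is neither an
#' entry nor a declared extra canonical is rejected.
#'
#' @param source path to a CSV nomenclature table; defaults to the packaged
#'   42-entry table.
#' @param mergeMap named character vector (source abbreviation -> canonical
#'   abbreviation) overriding the default merge rules.
#' @param extraCanonicals named character vector of canonical labels that
#'   may appear as merge targets without being table rows
#'   (abbreviation = full name).
#' @return a [LabelRegistry-class].
#' @examples
#' reg <- loadNomenclature()
#' length(reg)                    # 42 nomenclature entries
#' length(canonicalLabels(reg))   # 36 after merging
#' @export
loadNomenclature <- function(source = system.file("extdata",
                                 "sulcus_nomenclature.csv",
                                 package = "endoSISS"),
                             mergeMap = .defaultMergeMap,
                             extraCanonicals = .defaultExtraCanonicals) {
    tab <- utils::read.csv(source, stringsAsFactors = FALSE)
    need <- c("abbreviation", "full_name", "group")
    if (!all(need %in% names(tab)))
        stop("nomenclature table must have columns ",
             paste(need, collapse = ", "))
    if (nrow(tab) == 0L)
        stop("nomenclature table is empty")
    if (!"index" %in% names(tab))
        tab$index <- seq_len(nrow(tab))
    tab$abbreviation <- .normLabel(tab$abbreviation)
    dup <- unique(tab$abbreviation[duplicated(tab$abbreviation)])
    if (length(dup))
        stop("duplicate abbreviation in nomenclature: ",
             paste(dup, collapse = ", "))
    entries <- data.frame(index = as.integer(tab$index),
                          abbreviation = tab$abbreviation,
                          full_name = tab$full_name,
                          group = tab$group,
                          stringsAsFactors = FALSE)
    mergeMap <- stats::setNames(.normLabel(mergeMap),
                                .normLabel(names(mergeMap)))
    badSrc <- setdiff(names(mergeMap), entries$abbreviation)
    if (length(badSrc))
        stop("merge source not in nomenclature: ",
             paste(badSrc, collapse = ", "))
    needExtra <- setdiff(unname(mergeMap), entries$abbreviation)
    unknown <- setdiff(needExtra, .normLabel(names(extraCanonicals)))
    if (length(unknown))
        stop("unknown merge target: ", paste(unknown, collapse = ", "))
    extras <- data.frame(index = NA_integer_,
                         abbreviation = .normLabel(needExtra),
                         full_name = unname(extraCanonicals[needExtra]),
                         group = "canonical",
                         stringsAsFactors = FALSE)[seq_along(needExtra), ,
                                                   drop = FALSE]
    new("LabelRegistry", entries = entries, extras = extras,
        mergeMap = mergeMap)
}

#' Canonicalize sulcus labels
#'
#' Maps each label to its canonical abbreviation via the registry's merge
#' rules; labels without a merge rule are returned unchanged. The mapping is
#' idempotent. Trailing periods are stripped before lookup.
#'
#' @param label character vector of abbreviations.
#' @param registry a [LabelRegistry-class].
#' @return character vector of canonical abbreviations.
#' @examples
#' reg <- loadNomenclature()
#' canonicalize(c("S.C.sylvian", "S.Pe.C.inf", "S.C"), reg)
#' @export
canonicalize <- function(label, registry) {
    stopifnot(is(registry, "LabelRegistry"))
    label <- .normLabel(label)
    known <- allLabels(registry)
    bad <- setdiff(unique(label), known)
    if (length(bad))
        stop("unknown sulcus label: ", paste(bad, collapse = ", "))
    mm <- registry@mergeMap
    hit <- label %in% names(mm)
    label[hit] <- unname(mm[label[hit]])
    label
}

#' Register an occipital label drawn beyond the official list
#'
#' Occipital sulci were not part of the list given to raters, but raters
#' drew some under varying names; such labels are accepted as
#' \code{occipital_extra} entries that canonicalize to the single
#' \code{Occipital} reporting label.
#'
#' @param registry a [LabelRegistry-class].
#' @param abbreviation label used by the rater.
#' @param full_name optional display name.
#' @return the updated [LabelRegistry-class].
#' @examples
#' reg <- addOccipitalLabel(loadNomenclature(), "S.O.sup")
#' canonicalize("S.O.sup", reg)
#' @export
addOccipitalLabel <- function(registry, abbreviation,
                              full_name = abbreviation) {
    stopifnot(is(registry, "LabelRegistry"))
    abbreviation <- .normLabel(abbreviation)
    if (abbreviation %in% allLabels(registry))
        stop("label already registered: ", abbreviation)
    extras <- rbind(registry@extras,
                    data.frame(index = NA_integer_,
                               abbreviation = abbreviation,
                               full_name = full_name,
                               group = "occipital_extra",
                               stringsAsFactors = FALSE))
    mm <- c(registry@mergeMap,
            stats::setNames("Occipital", abbreviation))
    new("LabelRegistry", entries = registry@entries, extras = extras,
        mergeMap = mm)
}

## ---- label corrections ----------------------------------------------------

#' Build a label-correction table
#'
#' Corrections are declarative metadata: each row reassigns one drawing
#' (identified by rater, view and the label under which it was drawn) to one
#' or more true sulci, or discards it with the sentinel \code{"NONE"} when
#' the drawing matches no real sulcus. A drawing assigned to two sulci is
#' scored once against each.
#'
#' @param rater,view,drawn_label character vectors (recycled to a common
#'   length) identifying the drawings to correct.
#' @param corrected_labels character vector; each element is one
#'   abbreviation, several separated by \code{";"}, or \code{"NONE"}.
#' @param hemisphere optional character vector; \code{"*"} (default)
#'   matches both hemispheres of a bilateral view.
#' @return a data.frame with columns \code{rater}, \code{view},
#'   \code{hemisphere}, \code{drawn_label}, \code{corrected_labels}.
#' @seealso [applyCorrections()], [readCorrections()]
#' @examples
#' correctionTable("R3", "lateral_left", "S.C", "S.Pe.C")
#' @export
correctionTable <- function(rater, view, drawn_label, corrected_labels,
                            hemisphere = "*") {
    n <- max(length(rater), length(view), length(drawn_label),
             length(corrected_labels))
    data.frame(rater = rep_len(as.character(rater), n),
               view = rep_len(as.character(view), n),
               hemisphere = rep_len(as.character(hemisphere), n),
               drawn_label = rep_len(as.character(drawn_label), n),
               corrected_labels = rep_len(as.character(corrected_labels),
                                          n),
               stringsAsFactors = FALSE)
}

#' Read / write a correction file
#'
#' CSV with columns \code{rater}, \code{view}, \code{drawn_label},
#' \code{corrected_labels} (\code{";"}-separated list or \code{"NONE"}) and
#' optionally \code{hemisphere}.
#'
#' @param path file path.
#' @param corrections a correction data.frame (see [correctionTable()]).
#' @return `readCorrections` returns the correction data.frame;
#'   `writeCorrections` returns `path` invisibly.
#' @export
readCorrections <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("rater", "view", "drawn_label", "corrected_labels")
    if (!all(need %in% names(tab)))
        stop("correction file must have columns ",
             paste(need, collapse = ", "))
    if (!"hemisphere" %in% names(tab))
        tab$hemisphere <- "*"
    tab$rater <- as.character(tab$rater)
    tab[c("rater", "view", "hemisphere", "drawn_label",
          "corrected_labels")]
}

#' @rdname readCorrections
#' @export
writeCorrections <- function(corrections, path) {
    utils::write.csv(corrections, path, row.names = FALSE)
    invisible(path)
}

#' Apply label corrections to a set of drawings
#'
#' Replays expert label corrections over a list of rater masks: corrected
#' drawings are re-labelled (duplicated once per corrected label when a
#' drawing matches several sulci), sentinel-marked drawings are dropped, and
#' everything else passes through unchanged. Pixel content is never
#' altered — only labels and multiplicity.
#'
#' @param drawings list of [SulcusMask-class] rater drawings.
#' @param corrections correction data.frame ([correctionTable()] /
#'   [readCorrections()]); may have zero rows.
#' @param registry a [LabelRegistry-class] used to resolve labels.
#' @return list of [SulcusMask-class] with a logical attribute
#'   \code{"corrected"} flagging relabelled masks.
#' @examples
#' reg <- loadNomenclature()
#' m <- SulcusMask("lateral_left", "left", "S.C", "R3", c(20, 20),
#'                 cbind(5:10, 10))
#' out <- applyCorrections(list(m), correctionTable("R3", "lateral_left",
#'                                                  "S.C", "S.Pe.C"), reg)
#' sulcusLabel(out[[1]])
#' @export
applyCorrections <- function(drawings, corrections, registry) {
    stopifnot(is(registry, "LabelRegistry"))
    if (is.null(corrections) || nrow(corrections) == 0L) {
        attr(drawings, "corrected") <- rep(FALSE, length(drawings))
        return(drawings)
    }
    corrections$drawn_label <- canonicalize(corrections$drawn_label,
                                            registry)
    matched <- rep(FALSE, nrow(corrections))
    out <- list()
    flag <- logical()
    for (m in drawings) {
        lab <- canonicalize(sulcusLabel(m), registry)
        hit <- which(corrections$rater == raterId(m) &
                     corrections$view == viewId(m) &
                     (corrections$hemisphere == "*" |
                      corrections$hemisphere == hemisphere(m)) &
                     corrections$drawn_label == lab)
        if (!length(hit)) {
            out[[length(out) + 1L]] <- m
            flag <- c(flag, FALSE)
            next
        }
        matched[hit] <- TRUE
        targets <- unlist(strsplit(
            corrections$corrected_labels[hit], ";", fixed = TRUE))
        targets <- .normLabel(targets)
        if (!length(targets))
            stop("correction with empty corrected_labels for ",
                 raterId(m), "/", viewId(m), "/", lab)
        if (all(targets == .NO_SULCUS))
            next                 # drawing matches no real sulcus: drop
        targets <- canonicalize(setdiff(targets, .NO_SULCUS), registry)
        for (tg in unique(targets)) {
            out[[length(out) + 1L]] <-
                initialize(m, label = tg)
            flag <- c(flag, !identical(tg, lab))
        }
    }
    if (any(!matched)) {
        d <- corrections[!matched, , drop = FALSE]
        stop("corrections reference missing drawings: ",
             paste(sprintf("%s/%s/%s", d$rater, d$view, d$drawn_label),
                   collapse = "; "))
    }
    attr(out, "corrected") <- flag
    out
}
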