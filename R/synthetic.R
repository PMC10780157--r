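## ---- synthetic references and rater simulation ---------------------------

#' Describe a reference sulcus curve
#'
#' A reference sulcus is a smooth curve through a few control points,
#' rasterized at a given stroke width. Control points are expressed as
#' (independent, transverse) coordinates: for a `"horizontal"` curve the
#' independent axis is columns and the transverse coordinate is the row,
#' and vice versa for `"vertical"`. Control points must be strictly
#' increasing along the independent axis, so each curve is a function of
#' its independent coordinate — matching the streamline form the scoring
#' assumes.
#'
#' @param view one of [sulcusViews].
#' @param hemisphere `"left"` or `"right"`.
#' @param label sulcus abbreviation.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param control 2-column matrix of (independent, transverse) anchors.
#' @param width stroke width in pixels (>= 1).
#' @param confusable abbreviation of the neighbouring sulcus this one is
#'   typically mislabelled as, or `NA`.
#' @return a `referenceSpec` list.
#' @seealso [referenceSpecs()], [generateReferences()]
#' @export
referenceSpec <- function(view, hemisphere, label, axis, control,
                          width = 3L, confusable = NA_character_) {
    control <- as.matrix(control)
    stopifnot(view %in% sulcusViews,
              hemisphere %in% c("left", "right"),
              axis %in% c("horizontal", "vertical"),
              ncol(control) == 2L, nrow(control) >= 2L,
              width >= 1L)
    if (any(diff(control[, 1L]) <= 0))
        stop("control points must be strictly increasing along the ",
             "independent axis")
    structure(list(view = view, hemisphere = hemisphere, label = label,
                   axis = axis, control = control,
                   width = as.integer(width),
                   confusable = as.character(confusable)),
              class = "referenceSpec")
}

## mirror a spec across the vertical midline of the frame
.mirrorSpec <- function(spec, view, hemisphere, cols = 600L) {
    ctrl <- spec$control
    if (spec$axis == "vertical") {
        ctrl[, 2L] <- cols + 1L - ctrl[, 2L]          # transverse = col
    } else {
        ctrl[, 1L] <- cols + 1L - ctrl[, 1L]          # independent = col
        ctrl <- ctrl[rev(seq_len(nrow(ctrl))), , drop = FALSE]
    }
    referenceSpec(view, hemisphere, spec$label, spec$axis, ctrl,
                  spec$width, spec$confusable)
}

#' Default reference sulcus set
#'
#' A packaged set of 26 reference curves over the five views and ten
#' canonical labels, on a 600x600 frame, laid out to mimic the spatial
#' structure that drives rater confusions: every view contains at least one
#' adjacent confusable pair (central next to pre-central, inferior frontal
#' next to anterior inferior frontal, superior frontal next to intermediate
#' frontal, parieto-occipital next to occipital) at 40-70 px separation,
#' with reference stroke widths between 2 and 5 px.
#'
#' @return list of `referenceSpec` objects.
#' @export
referenceSpecs <- function() {
    rs <- referenceSpec
    latL <- list(
        rs("lateral_left", "left", "S.C", "vertical",
           rbind(c(140, 368), c(230, 355), c(320, 344), c(400, 358)),
           width = 3, confusable = "S.Pe.C"),
        rs("lateral_left", "left", "S.Pe.C", "vertical",
           rbind(c(140, 312), c(230, 299), c(320, 288), c(400, 302)),
           width = 3, confusable = "S.C"),
        rs("lateral_left", "left", "S.F.sup", "horizontal",
           rbind(c(60, 138), c(130, 121), c(200, 131), c(260, 144)),
           width = 2),
        rs("lateral_left", "left", "S.F.inf", "horizontal",
           rbind(c(60, 214), c(130, 200), c(200, 208), c(250, 222)),
           width = 4, confusable = "S.F.inf.ant"),
        rs("lateral_left", "left", "S.F.inf.ant", "horizontal",
           rbind(c(60, 272), c(130, 259), c(200, 266), c(240, 278)),
           width = 3, confusable = "S.F.inf"),
        rs("lateral_left", "left", "S.T.s", "horizontal",
           rbind(c(120, 475), c(240, 459), c(360, 468), c(480, 481)),
           width = 5))
    latR <- lapply(latL, .mirrorSpec, view = "lateral_right",
                   hemisphere = "right")
    antL <- list(
        rs("anterior", "left", "S.F.sup", "vertical",
           rbind(c(160, 222), c(250, 210), c(340, 205), c(420, 216)),
           width = 3, confusable = "S.F.inter"),
        rs("anterior", "left", "S.F.inter", "vertical",
           rbind(c(160, 282), c(250, 270), c(340, 265), c(420, 276)),
           width = 2, confusable = "S.F.sup"))
    antR <- lapply(antL, .mirrorSpec, view = "anterior",
                   hemisphere = "right")
    supL <- list(
        rs("superior", "left", "S.C", "horizontal",
           rbind(c(60, 310), c(140, 296), c(210, 288), c(270, 300)),
           width = 3, confusable = "S.Pe.C"),
        rs("superior", "left", "S.Pe.C", "horizontal",
           rbind(c(60, 255), c(140, 241), c(210, 233), c(270, 245)),
           width = 2, confusable = "S.C"),
        rs("superior", "left", "F.I.P", "horizontal",
           rbind(c(80, 430), c(160, 418), c(240, 428)), width = 4))
    supR <- lapply(supL, .mirrorSpec, view = "superior",
                   hemisphere = "right")
    posL <- list(
        rs("posterior", "left", "Occipital", "vertical",
           rbind(c(180, 235), c(260, 222), c(340, 215), c(420, 228)),
           width = 3, confusable = "F.P.O"),
        rs("posterior", "left", "F.P.O", "horizontal",
           rbind(c(150, 120), c(210, 108), c(270, 118)),
           width = 2, confusable = "Occipital"))
    posR <- lapply(posL, .mirrorSpec, view = "posterior",
                   hemisphere = "right")
    c(latL, latR, antL, antR, supL, supR, posL, posR)
}

## evaluate a spec's smooth curve at every integer independent coordinate
.specCurve <- function(spec) {
    ctrl <- spec$control
    ind <- seq(ctrl[1L, 1L], ctrl[nrow(ctrl), 1L])
    tra <- stats::spline(ctrl[, 1L], ctrl[, 2L], xout = ind,
                         method = "natural")$y
    list(ind = ind, tra = tra)
}

## rasterize a function-form curve: one pixel per independent coordinate,
## thickened transversely to the requested width
.rasterizeCurve <- function(ind, tra, axis, width, frame,
                            clip = TRUE) {
    ctr <- .roundHalfOut(tra)
    offs <- (0:(width - 1L)) - floor((width - 1L) / 2)
    ii <- rep(ind, each = length(offs))
    tt <- rep(ctr, each = length(offs)) + offs
    px <- if (axis == "horizontal") cbind(row = tt, col = ii)
          else cbind(row = ii, col = tt)
    inside <- px[, 1L] >= 1 & px[, 1L] <= frame[1L] &
              px[, 2L] >= 1 & px[, 2L] <= frame[2L]
    if (!clip && any(!inside))
        stop("curve leaves the ", frame[1L], "x", frame[2L], " frame")
    px[inside, , drop = FALSE]
}

#' Rasterize reference sulci from their specs
#'
#' Each spec's natural cubic spline is evaluated at every integer
#' coordinate of its independent axis, rounded to pixels and thickened to
#' the spec's width, producing one reference [SulcusMask-class] per spec
#' (rater `"reference"`). Generation is deterministic; with `jitter > 0`
#' control points are first perturbed by Gaussian noise (sd `jitter` px)
#' under `seed`, for randomized variants of the layout.
#'
#' @param specs list of [referenceSpec()] objects.
#' @param frame integer `c(rows, cols)` (default 600x600).
#' @param jitter control-point jitter sd in px (default 0: deterministic).
#' @param seed integer seed used only when `jitter > 0`.
#' @return list of [SulcusMask-class] with the specs attached as attribute
#'   `"specs"`. A curve leaving the frame is an error.
#' @examples
#' refs <- generateReferences(referenceSpecs())
#' length(refs)
#' @export
generateReferences <- function(specs, frame = c(600L, 600L),
                               jitter = 0, seed = 1L) {
    frame <- as.integer(frame)
    build <- function() lapply(specs, function(sp) {
        if (jitter > 0) {
            sp$control[, 2L] <- sp$control[, 2L] +
                stats::rnorm(nrow(sp$control), 0, jitter)
        }
        cv <- .specCurve(sp)
        px <- .rasterizeCurve(cv$ind, cv$tra, sp$axis, sp$width, frame,
                              clip = FALSE)
        SulcusMask(sp$view, sp$hemisphere, sp$label, "reference",
                   frame, px)
    })
    masks <- if (jitter > 0) .withSeed(seed, build()) else build()
    attr(masks, "specs") <- specs
    masks
}

#' Confusable-label map of a spec set
#'
#' @param specs list of [referenceSpec()] objects (e.g. the attribute
#'   attached by [generateReferences()]).
#' @return named character vector, label -> neighbouring confusable label.
#' @export
defaultConfusions <- function(specs) {
    lab <- vapply(specs, `[[`, character(1), "label")
    cf <- vapply(specs, `[[`, character(1), "confusable")
    keep <- !is.na(cf)
    out <- cf[keep]
    names(out) <- lab[keep]
    out[!duplicated(names(out))]
}

#' Configure one simulated rater
#'
#' The noise model is additive-geometric, with one interpretable knob per
#' error mode the scoring is meant to detect:
#' \describe{
#'   \item{displacement_px}{rigid positional shift: the whole stroke moves
#'     by exactly this many pixels along the normal to its chord, with a
#'     random sign — the systematic transverse misplacement seen for the
#'     central/pre-central region.}
#'   \item{smooth_deform_amp, smooth_deform_scale}{smooth random shape
#'     deformation: a spline through Gaussian knots (sd = amplitude, px)
#'     spaced `smooth_deform_scale` px along the stroke is added to the
#'     transverse coordinate.}
#'   \item{truncation_frac}{fraction of the stroke length removed from a
#'     random end — drawings rarely cover a sulcus end to end.}
#'   \item{rectilinear_bias}{blend toward the straight chord (1 = drawn as
#'     a straight line regardless of the true course).}
#'   \item{stroke_width_px}{drawn line width, 1-7 px across raters.}
#'   \item{p_omit}{probability of not drawing a sulcus at all.}
#'   \item{p_mislabel}{probability that a confusable pair of strokes gets
#'     its labels swapped.}
#' }
#'
#' @param rater rater identifier.
#' @param seed integer; fully determines the rater's output.
#' @param displacement_px,smooth_deform_amp,smooth_deform_scale,truncation_frac,stroke_width_px,p_omit,p_mislabel,rectilinear_bias
#'   noise knobs as described above.
#' @return a `raterSimConfig` list.
#' @seealso [simulateRater()], [cohortConfigs()]
#' @export
raterConfig <- function(rater, seed,
                        displacement_px = 8,
                        smooth_deform_amp = 6,
                        smooth_deform_scale = 60,
                        truncation_frac = 0.15,
                        stroke_width_px = 3L,
                        p_omit = 0.25,
                        p_mislabel = 0.1,
                        rectilinear_bias = 0.2) {
    stopifnot(displacement_px >= 0, smooth_deform_amp >= 0,
              smooth_deform_scale > 0,
              truncation_frac >= 0, truncation_frac <= 1,
              stroke_width_px >= 1,
              p_omit >= 0, p_omit <= 1,
              p_mislabel >= 0, p_mislabel <= 1,
              rectilinear_bias >= 0, rectilinear_bias <= 1)
    structure(list(rater = as.character(rater), seed = as.integer(seed),
                   displacement_px = displacement_px,
                   smooth_deform_amp = smooth_deform_amp,
                   smooth_deform_scale = smooth_deform_scale,
                   truncation_frac = truncation_frac,
                   stroke_width_px = as.integer(stroke_width_px),
                   p_omit = p_omit, p_mislabel = p_mislabel,
                   rectilinear_bias = rectilinear_bias),
              class = "raterSimConfig")
}

#' Default cohort of simulated raters
#'
#' Fourteen raters with per-rater seeds derived deterministically from one
#' cohort seed and stroke widths cycling over 1-7 px, all other knobs at
#' the [raterConfig()] defaults unless overridden.
#'
#' @param seed cohort seed.
#' @param nRaters cohort size (default 14).
#' @param ... overrides passed to every [raterConfig()].
#' @return list of `raterSimConfig`.
#' @export
cohortConfigs <- function(seed, nRaters = 14L, ...) {
    seeds <- .withSeed(seed, sample.int(1e9L, nRaters))
    widths <- rep_len(1:7, nRaters)
    fixed <- list(...)
    lapply(seq_len(nRaters), function(i) {
        args <- c(list(rater = paste0("R", i), seed = seeds[i]), fixed)
        if (is.null(fixed$stroke_width_px))
            args$stroke_width_px <- widths[i]
        do.call(raterConfig, args)
    })
}

#' Simulate one rater's drawings over a reference set
#'
#' For each reference sulcus, with probability `p_omit` nothing is drawn;
#' otherwise the reference's centroid streamline is truncated, blended
#' toward its chord, smoothly deformed, rigidly shifted, and re-rasterized
#' at the rater's stroke width (see [raterConfig()] for the knobs). With
#' probability `p_mislabel` the labels of a confusable pair of drawn
#' strokes are swapped within a view/hemisphere. The truth log records, per
#' reference, the true and drawn labels and whether it was omitted — the
#' ground truth from which a correction file is derived.
#'
#' With all knobs at zero and the stroke width equal to an odd reference
#' width, the drawings reproduce the references pixel for pixel.
#'
#' @param references list of reference [SulcusMask-class] (see
#'   [generateReferences()]).
#' @param config a [raterConfig()].
#' @param confusions named label -> label map for mislabelling; defaults to
#'   the map of the spec set attached to `references`.
#' @return list with `drawings` (list of [SulcusMask-class]) and `log`
#'   (data.frame: view, hemisphere, true_label, drawn_label, omitted).
#' @export
simulateRater <- function(references, config, confusions = NULL) {
    stopifnot(inherits(config, "raterSimConfig"))
    if (is.null(confusions)) {
        sp <- attr(references, "specs")
        confusions <- if (is.null(sp)) character() else
            defaultConfusions(sp)
    }
    .withSeed(config$seed, {
        drawings <- list()
        logs <- list()
        for (ref in references) {
            entry <- data.frame(view = viewId(ref),
                                hemisphere = hemisphere(ref),
                                true_label = sulcusLabel(ref),
                                drawn_label = NA_character_,
                                omitted = TRUE,
                                stringsAsFactors = FALSE)
            if (stats::runif(1) < config$p_omit) {
                logs[[length(logs) + 1L]] <- entry
                next
            }
            path <- extractCentroid(ref)
            pts <- pathPoints(path)
            horiz <- pathAxis(path) == "horizontal"
            ind <- as.numeric(if (horiz) pts[, 2L] else pts[, 1L])
            tra <- as.numeric(if (horiz) pts[, 1L] else pts[, 2L])
            n <- length(ind)
            ## truncate from a random end
            k <- min(floor(config$truncation_frac * n), n - 2L)
            if (k > 0) {
                keep <- if (stats::runif(1) < 0.5) (k + 1L):n
                        else 1L:(n - k)
                ind <- ind[keep]; tra <- tra[keep]
            }
            ## blend toward the straight chord
            b <- config$rectilinear_bias
            if (b > 0) {
                m <- length(ind)
                chord <- tra[1L] + (tra[m] - tra[1L]) *
                    (ind - ind[1L]) / (ind[m] - ind[1L])
                tra <- (1 - b) * tra + b * chord
            }
            ## smooth random deformation
            if (config$smooth_deform_amp > 0) {
                span <- diff(range(ind))
                nk <- max(3L, ceiling(span / config$smooth_deform_scale)
                          + 1L)
                knots <- seq(min(ind), max(ind), length.out = nk)
                vals <- stats::rnorm(nk, 0, config$smooth_deform_amp)
                tra <- tra + stats::spline(knots, vals, xout = ind)$y
            }
            ## rigid shift along the chord normal, random sign
            if (config$displacement_px > 0) {
                m <- length(ind)
                v <- c(ind[m] - ind[1L], tra[m] - tra[1L])
                nv <- c(-v[2L], v[1L]) / sqrt(sum(v^2))
                s <- if (stats::runif(1) < 0.5) -1 else 1
                ind <- ind + s * config$displacement_px * nv[1L]
                tra <- tra + s * config$displacement_px * nv[2L]
            }
            ## re-grid to one point per integer independent coordinate
            xi <- seq(ceiling(min(ind)), floor(max(ind)))
            if (length(xi) < 2L) {
                logs[[length(logs) + 1L]] <- entry
                next
            }
            yi <- stats::approx(ind, tra, xout = xi)$y
            px <- .rasterizeCurve(xi, yi,
                                  if (horiz) "horizontal" else "vertical",
                                  config$stroke_width_px, maskDim(ref))
            if (nrow(px) == 0L) {
                logs[[length(logs) + 1L]] <- entry
                next
            }
            entry$omitted <- FALSE
            entry$drawn_label <- sulcusLabel(ref)
            drawings[[length(drawings) + 1L]] <-
                SulcusMask(viewId(ref), hemisphere(ref), sulcusLabel(ref),
                           config$rater, maskDim(ref), px)
            logs[[length(logs) + 1L]] <- entry
        }
        log <- do.call(rbind, logs)
        ## mislabel confusable pairs: swap labels within view/hemisphere
        if (config$p_mislabel > 0 && length(confusions)) {
            pairs <- unique(t(apply(cbind(names(confusions),
                                          unname(confusions)), 1L, sort)))
            keys <- vapply(drawings, function(d)
                paste(viewId(d), hemisphere(d), sep = "|"), character(1))
            for (vh in unique(keys)) {
                for (p in seq_len(nrow(pairs))) {
                    i1 <- which(keys == vh & vapply(drawings, sulcusLabel,
                                character(1)) == pairs[p, 1L])
                    i2 <- which(keys == vh & vapply(drawings, sulcusLabel,
                                character(1)) == pairs[p, 2L])
                    if (!length(i1) && !length(i2)) next
                    if (stats::runif(1) >= config$p_mislabel) next
                    for (i in i1) drawings[[i]] <-
                        initialize(drawings[[i]], label = pairs[p, 2L])
                    for (i in i2) drawings[[i]] <-
                        initialize(drawings[[i]], label = pairs[p, 1L])
                    vw <- strsplit(vh, "|", fixed = TRUE)[[1L]]
                    sw <- log$view == vw[1L] & log$hemisphere == vw[2L] &
                        !log$omitted & log$true_label %in% pairs[p, ]
                    log$drawn_label[sw] <- vapply(log$true_label[sw],
                        function(tl) pairs[p, ][pairs[p, ] != tl][1L],
                        character(1))
                }
            }
        }
        log$rater <- config$rater
        list(drawings = drawings,
             log = log[c("rater", "view", "hemisphere", "true_label",
                         "drawn_label", "omitted")])
    })
}

#' Derive a correction table from a simulation truth log
#'
#' Every non-omitted drawing whose drawn label differs from its true label
#' yields one correction entry mapping the drawn label back to the true
#' one — the synthetic analogue of the expert a-posteriori correction.
#'
#' @param log truth log data.frame from [simulateRater()] (or several
#'   raters' logs row-bound).
#' @return a correction data.frame (see [correctionTable()]).
#' @export
correctionsFromLog <- function(log) {
    mis <- log[!log$omitted & log$drawn_label != log$true_label, ,
               drop = FALSE]
    correctionTable(mis$rater, mis$view, mis$drawn_label,
                    mis$true_label, hemisphere = mis$hemisphere)
}

## blank background image for a view a rater left empty
.writeBlankImage <- function(path, frame, background = "#FFFFFF") {
    img <- array(rep(.hex2rgb(background) / 255, each = prod(frame)),
                 dim = c(frame[1L], frame[2L], 3L))
    png::writePNG(img, path)
    invisible(path)
}

#' Write a full simulated cohort to disk
#'
#' Produces the on-disk layout the scoring pipeline consumes: one reference
#' label image per view (`reference_<view>.png`), one label image per rater
#' and view (`<rater>_<view>.png`, blank where the rater drew nothing), the
#' colour palette (`palette.csv`), a correction file (`corrections.csv`)
#' derived from the truth log (mislabelled drawings mapped back to their
#' true labels), and the truth log itself (`truth_log.csv`). Deterministic
#' given the configs' seeds.
#'
#' @param configs list of [raterConfig()] (e.g. [cohortConfigs()]).
#' @param references list of reference [SulcusMask-class].
#' @param outDir output directory (created if needed).
#' @param background image background colour.
#' @return invisibly, a list with the palette, the truth log and the
#'   correction table.
#' @export
emitCohort <- function(configs, references, outDir,
                       background = "#FFFFFF") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    frame <- maskDim(references[[1L]])
    labs <- vapply(references, sulcusLabel, character(1))
    hems <- vapply(references, hemisphere, character(1))
    palette <- makePalette(labs, hems)
    writePalette(palette, file.path(outDir, "palette.csv"))

    refViews <- vapply(references, viewId, character(1))
    for (v in unique(refViews))
        writeViewImage(references[refViews == v],
                       file.path(outDir, paste0("reference_", v, ".png")),
                       palette, background = background)

    logs <- list()
    for (cfg in configs) {
        sim <- simulateRater(references, cfg)
        logs[[length(logs) + 1L]] <- sim$log
        dViews <- vapply(sim$drawings, viewId, character(1))
        for (v in unique(refViews)) {
            path <- file.path(outDir,
                              paste0(cfg$rater, "_", v, ".png"))
            dv <- sim$drawings[dViews == v]
            if (length(dv))
                writeViewImage(dv, path, palette,
                               background = background)
            else
                .writeBlankImage(path, frame, background)
        }
    }
    log <- do.call(rbind, logs)
    utils::write.csv(log, file.path(outDir, "truth_log.csv"),
                     row.names = FALSE)
    corrections <- correctionsFromLog(log)
    writeCorrections(corrections, file.path(outDir, "corrections.csv"))
    invisible(list(palette = palette, log = log,
                   corrections = corrections))
}

#' Load a cohort directory written by [emitCohort()]
#'
#' @param dir cohort directory.
#' @param tolerance,strict colour matching options passed to
#'   [loadLabelImage()].
#' @return list with `references` and `drawings` (lists of
#'   [SulcusMask-class]), `palette`, and `corrections` (NULL when no
#'   correction file is present).
#' @export
loadCohort <- function(dir, tolerance = 30, strict = FALSE) {
    palPath <- file.path(dir, "palette.csv")
    if (!file.exists(palPath))
        stop("no palette.csv in ", dir)
    palette <- readPalette(palPath)
    refs <- list(); draws <- list()
    for (v in sulcusViews) {
        rp <- file.path(dir, paste0("reference_", v, ".png"))
        if (file.exists(rp))
            refs <- c(refs, loadLabelImage(rp, palette, v, "reference",
                                           tolerance = tolerance,
                                           strict = strict))
        pat <- paste0("_", v, "\\.png$")
        ff <- setdiff(list.files(dir, pattern = pat),
                      paste0("reference_", v, ".png"))
        for (f in ff) {
            rater <- sub(pat, "", f)
            draws <- c(draws, loadLabelImage(file.path(dir, f), palette,
                                             v, rater,
                                             tolerance = tolerance,
                                             strict = strict))
        }
    }
    corrPath <- file.path(dir, "corrections.csv")
    corrections <- if (file.exists(corrPath)) readCorrections(corrPath)
                   else NULL
    list(references = refs, drawings = draws, palette = palette,
         corrections = corrections)
}
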