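## ---- palettes -------------------------------------------------------------

#' Colour palettes keying strokes to sulci
#'
#' A palette maps each stroke colour in a label image to a (label,
#' hemisphere) pair. In the bilateral views (anterior, superior, posterior)
#' the two hemispheres use distinct colours; lateral views force their
#' hemisphere. `makePalette` assigns maximally separated RGB colours
#' (pairwise Euclidean distance >= 60, far from the white background) so
#' that anti-aliased edge pixels resolve unambiguously under the default
#' colour tolerance of 30.
#'
#' @param labels character vector of sulcus abbreviations.
#' @param hemispheres character vector recycled against `labels`.
#' @param path file path for `readPalette` / `writePalette`.
#' @param palette a palette data.frame.
#' @return a data.frame with columns \code{color} (hex \code{"#RRGGBB"}),
#'   \code{label}, \code{hemisphere}.
#' @examples
#' makePalette(c("S.C", "S.C", "S.Pe.C"), c("left", "right", "left"))
#' @export
makePalette <- function(labels, hemispheres) {
    combo <- unique(data.frame(label = labels, hemisphere = hemispheres,
                               stringsAsFactors = FALSE))
    lv <- c(0L, 60L, 120L, 180L, 240L)
    grid <- expand.grid(r = lv, g = lv, b = lv)
    dWhite <- sqrt((grid$r - 255)^2 + (grid$g - 255)^2 + (grid$b - 255)^2)
    grid <- grid[dWhite > 60, ]
    grid <- grid[order(grid$r + grid$g + grid$b, grid$r, grid$g), ]
    if (nrow(combo) > nrow(grid))
        stop("palette capacity exceeded: ", nrow(combo), " combinations")
    combo$color <- grDevices::rgb(grid$r[seq_len(nrow(combo))],
                                  grid$g[seq_len(nrow(combo))],
                                  grid$b[seq_len(nrow(combo))],
                                  maxColorValue = 255)
    combo[c("color", "label", "hemisphere")]
}

#' @rdname makePalette
#' @export
readPalette <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("color", "label", "hemisphere")
    if (!all(need %in% names(tab)))
        stop("palette file must have columns ",
             paste(need, collapse = ", "))
    if (anyDuplicated(toupper(tab$color)))
        stop("palette colours must be unique")
    tab[need]
}

#' @rdname makePalette
#' @export
writePalette <- function(palette, path) {
    utils::write.csv(palette, path, row.names = FALSE)
    invisible(path)
}

## hex -> length-3 integer RGB
.hex2rgb <- function(hex) as.integer(grDevices::col2rgb(hex))

## ---- label image I/O ------------------------------------------------------

#' Isolate the sulcus strokes of a label image into binary masks
#'
#' Reads a raster label image (PNG, RGB or RGBA; alpha ignored) and returns
#' one [SulcusMask-class] per (label, hemisphere) colour present, preserving
#' pixel positions and the frame size. A label drawn as several disconnected
#' strokes yields a single mask (pixel union). Pixels within `tolerance`
#' (Euclidean RGB distance) of a palette colour are assigned to it, which
#' absorbs anti-aliased stroke edges; pixels within `tolerance` of
#' `background` are dropped silently. Any other colour is an error in strict
#' mode and is dropped with a warning otherwise.
#'
#' @param path PNG file path.
#' @param palette palette data.frame (see [makePalette()]).
#' @param view one of [sulcusViews].
#' @param rater rater identifier for the produced masks.
#' @param tolerance colour-distance tolerance in RGB units (default 30).
#' @param strict error on unmapped colours instead of warning.
#' @param background background colour (default white).
#' @return list of [SulcusMask-class]; empty list for an all-background
#'   image.
#' @seealso [writeMask()], [writeViewImage()]
#' @export
loadLabelImage <- function(path, palette, view, rater,
                           tolerance = 30, strict = FALSE,
                           background = "#FFFFFF") {
    if (!file.exists(path))
        stop("cannot read image: ", path)
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L)                   # greyscale
        img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    img <- img[, , 1:3, drop = FALSE]             # drop alpha
    h <- dim(img)[1L]; w <- dim(img)[2L]
    rgbInt <- round(img * 255)
    key <- rgbInt[, , 1L] * 65536 + rgbInt[, , 2L] * 256 + rgbInt[, , 3L]
    uk <- unique(as.vector(key))
    ur <- uk %/% 65536; ug <- (uk %/% 256) %% 256; ub <- uk %% 256

    pal <- palette
    pr <- vapply(pal$color, function(cc) .hex2rgb(cc), integer(3))
    bg <- .hex2rgb(background)
    dBg <- sqrt((ur - bg[1L])^2 + (ug - bg[2L])^2 + (ub - bg[3L])^2)
    dPal <- sapply(seq_len(ncol(pr)), function(j)
        sqrt((ur - pr[1L, j])^2 + (ug - pr[2L, j])^2 + (ub - pr[3L, j])^2))
    dPal <- matrix(dPal, nrow = length(uk))
    best <- max.col(-dPal, ties.method = "first")
    bestD <- dPal[cbind(seq_along(uk), best)]

    assign <- ifelse(bestD <= tolerance, best, NA_integer_)
    isBg <- is.na(assign) & dBg <= tolerance
    unmapped <- is.na(assign) & !isBg
    if (any(unmapped)) {
        counts <- vapply(uk[unmapped], function(k) sum(key == k), integer(1))
        desc <- sprintf("#%02X%02X%02X (%d px)",
                        ur[unmapped], ug[unmapped], ub[unmapped], counts)
        if (strict)
            stop("unmapped colour(s) in ", basename(path), ": ",
                 paste(desc, collapse = ", "))
        warning("ignoring unmapped colour(s) in ", basename(path), ": ",
                paste(desc, collapse = ", "))
    }

    masks <- list()
    for (j in seq_len(nrow(pal))) {
        hits <- uk[!is.na(assign) & assign == j]
        if (!length(hits)) next
        sel <- which(matrix(key %in% hits, nrow = h), arr.ind = TRUE)
        if (!nrow(sel)) next
        k <- paste(pal$label[j], pal$hemisphere[j], sep = "|")
        if (is.null(masks[[k]]))
            masks[[k]] <- sel
        else
            masks[[k]] <- rbind(masks[[k]], sel)
    }
    out <- vector("list", length(masks))
    for (i in seq_along(masks)) {
        parts <- strsplit(names(masks)[i], "|", fixed = TRUE)[[1L]]
        out[[i]] <- SulcusMask(view = view, hemisphere = parts[2L],
                               label = parts[1L], rater = rater,
                               dim = c(h, w), pixels = masks[[i]])
    }
    out
}

#' Write a single mask to a PNG file
#'
#' Renders the mask's pixels in `color` on `background`, preserving the
#' frame, so that reloading the file through [loadLabelImage()] with a
#' one-entry palette reproduces the pixel set exactly.
#'
#' @param mask a [SulcusMask-class].
#' @param path output PNG path.
#' @param color stroke colour (hex).
#' @param background background colour (hex).
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path, color = "#000000",
                      background = "#FFFFFF") {
    stopifnot(is(mask, "SulcusMask"))
    validObject(mask)
    pal <- data.frame(color = color, label = sulcusLabel(mask),
                      hemisphere = hemisphere(mask),
                      stringsAsFactors = FALSE)
    writeViewImage(list(mask), path, pal, background = background)
}

#' Render a set of masks of one view into a label image
#'
#' Later masks overdraw earlier ones where strokes overlap, as with hand
#' drawing tools.
#'
#' @param masks list of [SulcusMask-class] sharing one view frame.
#' @param path output PNG path.
#' @param palette palette covering every (label, hemisphere) in `masks`.
#' @param background background colour.
#' @return `path`, invisibly.
#' @export
writeViewImage <- function(masks, path, palette, background = "#FFFFFF") {
    if (!length(masks))
        stop("no masks to write")
    dm <- maskDim(masks[[1L]])
    img <- array(rep(.hex2rgb(background) / 255, each = prod(dm)),
                 dim = c(dm[1L], dm[2L], 3L))
    for (m in masks) {
        if (!identical(maskDim(m), dm))
            stop("masks of one view image must share the frame size")
        j <- which(palette$label == sulcusLabel(m) &
                   palette$hemisphere == hemisphere(m))
        if (length(j) != 1L)
            stop("palette does not cover ", sulcusLabel(m), "/",
                 hemisphere(m))
        rgbv <- .hex2rgb(palette$color[j]) / 255
        px <- maskPixels(m)
        for (ch in 1:3)
            img[cbind(px, ch)] <- rgbv[ch]
    }
    ok <- tryCatch({png::writePNG(img, path); TRUE},
                   error = function(e) e)
    if (!isTRUE(ok))
        stop("cannot write image ", path, ": ", conditionMessage(ok))
    invisible(path)
}
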