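## internal helpers

## round half away from zero (base round() rounds half to even)
.roundHalfOut <- function(x) sign(x) * floor(abs(x) + 0.5)

## linear index of (row, col) pixels on a frame; used for set operations
.pixelKey <- function(pixels, dim) {
    (pixels[, 2L] - 1L) * dim[1L] + pixels[, 1L]
}

## run code with a local RNG state: seeds deterministically, restores the
## caller's .Random.seed afterwards
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

.checkSameFrame <- function(A, B) {
    if (!identical(maskDim(A), maskDim(B)))
        stop("masks are on different view frames (",
             paste(maskDim(A), collapse = "x"), " vs ",
             paste(maskDim(B), collapse = "x"),
             "); images of one cohort must share resolution")
    if (!identical(viewId(A), viewId(B)))
        stop("masks belong to different views: ", viewId(A), " vs ",
             viewId(B))
    invisible(TRUE)
}

## key identifying a scoring cell
.cellKey <- function(view, hemisphere, label) {
    paste(view, hemisphere, label, sep = "|")
}

.maskKey <- function(m) .cellKey(viewId(m), hemisphere(m), sulcusLabel(m))
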