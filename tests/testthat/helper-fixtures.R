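## fixture builders shared across test files; everything is generated in
## code at test time

mk <- function(px, dim = c(50L, 50L), view = "superior", hem = "left",
               label = "S.C", rater = "R1") {
    SulcusMask(view, hem, label, rater, dim, px)
}

## random non-empty pixel set on a dim frame
randPixels <- function(n, dim = c(50L, 50L)) {
    cbind(row = sample.int(dim[1L], n, replace = TRUE),
          col = sample.int(dim[2L], n, replace = TRUE))
}

## independent brute-force oracle for the directed mean minimum Euclidean
## distance: explicit nested loops over every streamline point and every
## reference pixel
bruteMmed <- function(points, refPixels) {
    mins <- numeric(nrow(points))
    for (i in seq_len(nrow(points))) {
        best <- Inf
        for (j in seq_len(nrow(refPixels))) {
            d <- sqrt((points[i, 1L] - refPixels[j, 1L])^2 +
                      (points[i, 2L] - refPixels[j, 2L])^2)
            if (d < best) best <- d
        }
        mins[i] <- best
    }
    mean(mins)
}

## a noiseless rater configuration; override knobs as needed
quietConfig <- function(rater = "R1", seed = 1L, ...) {
    args <- list(rater = rater, seed = seed, displacement_px = 0,
                 smooth_deform_amp = 0, truncation_frac = 0,
                 stroke_width_px = 1L, p_omit = 0, p_mislabel = 0,
                 rectilinear_bias = 0)
    over <- list(...)
    args[names(over)] <- over
    do.call(raterConfig, args)
}

## default reference layout rasterized at width 1 (exact-identity regime)
thinReferences <- function() {
    specs <- lapply(referenceSpecs(), function(s) { s$width <- 1L; s })
    generateReferences(specs)
}
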