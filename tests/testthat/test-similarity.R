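test_that("dice matches the set formula and its boundary values", {
    A <- mk(rbind(c(1, 1), c(1, 2)))
    B <- mk(rbind(c(1, 2), c(1, 3)))
    expect_equal(diceScore(A, B), 0.5)            # 2*1/(2+2)
    expect_equal(diceScore(A, A), 1)
    C <- mk(rbind(c(10, 10), c(10, 11)))
    expect_equal(diceScore(A, C), 0)
    ## symmetry
    expect_equal(diceScore(A, B), diceScore(B, A))
    ## errors: different frames, empty operand impossible by construction
    D <- mk(cbind(1, 1), dim = c(20L, 20L))
    expect_error(diceScore(A, D), "different view frames")
    E <- mk(cbind(1, 1), view = "anterior")
    expect_error(diceScore(A, E), "different views")
})

test_that("dice is 1 iff equal and 0 iff disjoint on random masks", {
    set.seed(21)
    for (i in 1:25) {
        A <- mk(randPixels(sample(3:60, 1)))
        B <- mk(randPixels(sample(3:60, 1)))
        d <- diceScore(A, B)
        expect_gte(d, 0); expect_lte(d, 1)
        ka <- paste(maskPixels(A)[, 1], maskPixels(A)[, 2])
        kb <- paste(maskPixels(B)[, 1], maskPixels(B)[, 2])
        expect_identical(d == 1, setequal(ka, kb))
        expect_identical(d == 0, length(intersect(ka, kb)) == 0L)
    }
})

test_that("centroid of a uniform bar is its central streamline", {
    bar <- mk(as.matrix(expand.grid(row = 5:7, col = 1:10)),
              dim = c(20L, 20L))
    p <- extractCentroid(bar)
    expect_identical(pathAxis(p), "horizontal")
    pts <- pathPoints(p)
    expect_identical(nrow(pts), 10L)
    expect_true(all(pts[, "row"] == 6L))
    expect_identical(pts[, "col"], 1:10)
})

test_that("centroid is the identity on single-pixel-wide strokes", {
    set.seed(31)
    cols <- 1:30
    rows <- round(15 + 6 * sin(cols / 5))
    thin <- mk(cbind(rows, cols), dim = c(40L, 40L))
    p <- extractCentroid(thin)
    expect_identical(pathPoints(p)[, "col"], cols)
    expect_identical(as.integer(pathPoints(p)[, "row"]), as.integer(rows))
})

test_that("centroid of a thick band tracks the per-column mean midline", {
    ## 3-px-wide gently diagonal band (longer than tall)
    cols <- rep(1:30, each = 3)
    rows <- rep(round((1:30) / 2) + 5L, each = 3) + 0:2
    band <- mk(cbind(rows, cols), dim = c(40L, 40L))
    p <- extractCentroid(band)
    pts <- pathPoints(p)
    expect_identical(nrow(pts), 30L)
    ## brute-force oracle: mean row per column, rounded
    for (i in seq_len(nrow(pts))) {
        cc <- pts[i, "col"]
        mu <- mean(rows[cols == cc])
        expect_lte(abs(pts[i, "row"] - mu), 1)
    }
    ## vertical strokes pick the row axis
    tall <- mk(cbind(1:20, rep(5L, 20)), dim = c(40L, 40L))
    expect_identical(pathAxis(extractCentroid(tall)), "vertical")
})

test_that("mmed matches hand-computed distances and is directed", {
    p1 <- new("CentroidPath", points = cbind(row = 1L, col = 1L),
              axis = "horizontal")
    B <- mk(cbind(4, 5))                            # 3-4-5 triangle
    expect_equal(mmed(p1, B), 5)
    p2 <- new("CentroidPath",
              points = cbind(row = c(1L, 1L), col = c(1L, 11L)),
              axis = "horizontal")
    B2 <- mk(cbind(1, 1))
    expect_equal(mmed(p2, B2), 5)                   # mean of {0, 10}
    ## a streamline inside the reference scores 0
    ref <- mk(as.matrix(expand.grid(row = 5:7, col = 1:10)))
    expect_equal(mmed(extractCentroid(ref), ref), 0)
})

test_that("mmed equals the brute-force nested-loop oracle", {
    set.seed(41)
    for (i in 1:30) {
        A <- mk(randPixels(sample(3:40, 1)))
        B <- mk(randPixels(sample(3:40, 1)))
        p <- extractCentroid(A)
        expect_equal(mmed(p, B), bruteMmed(pathPoints(p), maskPixels(B)),
                     tolerance = 1e-12)
    }
})

test_that("normalizeMmed is linear below threshold with a floor at it", {
    expect_equal(normalizeMmed(0), 1)
    expect_equal(normalizeMmed(5), 0.95)
    expect_equal(normalizeMmed(100), 0)
    expect_equal(normalizeMmed(150), 0)
    ## continuity at the threshold and monotone non-increase
    g <- seq(0, 200, by = 0.5)
    v <- normalizeMmed(g)
    expect_true(all(diff(v) <= 0))
    expect_lt(normalizeMmed(100 - 1e-9), 1e-8)
    ## alternative threshold and error branches
    expect_equal(normalizeMmed(25, threshold = 50), 0.5)
    expect_error(normalizeMmed(-1), "non-negative")
    expect_error(normalizeMmed(1, threshold = 0), "positive")
})

test_that("siss is the mean of its components on the unit scale", {
    expect_equal(sissScore(1, 1), 1)
    expect_equal(sissScore(0, 0), 0)
    expect_equal(sissScore(0.5, 0.95), 0.725)
    expect_error(sissScore(1.2, 0), "dice")
    expect_error(sissScore(0, -0.1), "mmedn")
})

test_that("scorePair combines the components consistently", {
    cols <- 3:25
    rows <- round(15 + 3 * sin(cols / 4))
    ref <- mk(cbind(rows, cols), dim = c(40L, 40L), rater = "reference")
    d <- mk(cbind(rows, cols), dim = c(40L, 40L))
    s <- scorePair(d, ref)
    expect_equal(s@dice, 1); expect_equal(s@mmed, 0)
    expect_equal(s@mmedn, 1); expect_equal(s@siss, 1)
    expect_false(s@saturated)

    ## far translation: no overlap, saturated, siss 0  (shift >= threshold)
    far <- mk(cbind(rows, cols), dim = c(400L, 400L))
    refBig <- mk(cbind(rows + 150L, cols), dim = c(400L, 400L),
                 rater = "reference")
    s2 <- scorePair(far, refBig)
    expect_equal(s2@dice, 0)
    expect_true(s2@saturated)
    expect_equal(s2@siss, 0)

    ## thin stroke 2 px from a wide reference everywhere
    dr <- mk(cbind(rep(10L, 20), 1:20), dim = c(40L, 40L))
    rf <- mk(as.matrix(expand.grid(row = 12:15, col = 1:20)),
             dim = c(40L, 40L), rater = "reference")
    s3 <- scorePair(dr, rf)
    expect_equal(s3@dice, 0)
    expect_equal(s3@mmedn, 0.98)
    expect_equal(s3@siss, 0.49)
})

test_that("moving a disjoint drawing further away never helps it", {
    cols <- 1:20
    rows <- rep(50L, 20)
    ref <- mk(cbind(rows, cols), dim = c(400L, 400L), rater = "reference")
    last <- NULL
    for (shift in c(5L, 20L, 60L, 150L)) {
        d <- mk(cbind(rows + shift, cols), dim = c(400L, 400L))
        s <- scorePair(d, ref)
        if (!is.null(last)) {
            expect_gte(s@mmed, last@mmed)
            expect_lte(s@siss, last@siss)
        }
        last <- s
    }
})
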