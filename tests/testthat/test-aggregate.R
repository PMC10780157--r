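## small helper: a score row with given siss
row1 <- function(rater, label, view = "superior", hem = "left", siss = 0.5,
                 dice = siss, mmedn = siss) {
    data.frame(rater = rater, view = view, hemisphere = hem, label = label,
               dice = dice, mmed = 0, mmedn = mmedn, siss = siss,
               saturated = FALSE, corrected = FALSE,
               stringsAsFactors = FALSE)
}

test_that("a perfect single-rater cohort scores siss 1 everywhere", {
    reg <- loadNomenclature()
    refs <- thinReferences()
    sim <- simulateRater(refs, quietConfig())
    res <- scoreCohort(sim$drawings, refs, reg)
    expect_identical(nrow(res$scores), length(refs))
    expect_true(all(res$scores$siss == 1))
    expect_identical(nrow(res$unmatched), 0L)
})

test_that("drawings without a reference go to the unmatched report only", {
    reg <- loadNomenclature()
    ref <- mk(cbind(rep(25L, 20), 11:30), dim = c(50L, 50L),
              label = "S.C", rater = "reference")
    good <- mk(cbind(rep(25L, 20), 11:30), dim = c(50L, 50L),
               label = "S.C", rater = "R1")
    stray <- mk(cbind(rep(40L, 10), 11:20), dim = c(50L, 50L),
                label = "F.P.O", rater = "R1")
    res <- scoreCohort(list(good, stray), list(ref), reg)
    expect_identical(res$scores$label, "S.C")
    expect_identical(res$unmatched$label, "F.P.O")
    ## labels are canonicalized before matching the reference
    asVariant <- mk(cbind(rep(25L, 20), 11:30), dim = c(50L, 50L),
                    label = "S.C.sylvian", rater = "R2")
    res2 <- scoreCohort(list(asVariant), list(ref), reg)
    expect_identical(res2$scores$label, "S.C")
})

test_that("mean table averages raters per cell and skips absent cells", {
    sc <- rbind(row1("R1", "S.C", siss = 0.4), row1("R2", "S.C", siss = 0.6))
    tb <- meanTable(sc)
    expect_equal(tableCells(tb)$mean_siss, 0.5)
    expect_identical(tableCells(tb)$n_raters, 2L)

    ## marginal over present views only: (0.3 + 0.5)/2, not /4
    sc2 <- rbind(row1("R1", "F.I.P", view = "superior", siss = 0.3),
                 row1("R1", "F.I.P", view = "posterior", siss = 0.5))
    mg <- tableMarginals(meanTable(sc2))
    expect_equal(mg$mean_siss, 0.4)
    expect_identical(mg$n_views, 2L)

    ## single rater: the table is that rater's scores
    sc3 <- row1("R1", "S.T.s", siss = 0.37)
    expect_equal(tableCells(meanTable(sc3))$mean_siss, 0.37)
    expect_error(meanTable(sc3[0, ]), "empty")
})

test_that("cell means stay within the hull of their contributing scores", {
    set.seed(51)
    sc <- do.call(rbind, lapply(1:40, function(i)
        row1(paste0("R", sample(6, 1)),
             sample(c("S.C", "F.I.P", "S.T.s"), 1),
             view = sample(c("superior", "posterior"), 1),
             siss = runif(1))))
    tb <- tableCells(meanTable(sc))
    for (i in seq_len(nrow(tb))) {
        sl <- sc[sc$label == tb$label[i] & sc$view == tb$view[i] &
                 sc$hemisphere == tb$hemisphere[i], ]
        expect_gte(tb$mean_siss[i], min(sl$siss) - 1e-12)
        expect_lte(tb$mean_siss[i], max(sl$siss) + 1e-12)
    }
})

test_that("identification rates are counts over the full cohort", {
    sc <- do.call(rbind, lapply(paste0("R", 1:7), row1, label = "S.C"))
    r <- identificationRate(sc, 14)
    expect_equal(r$rate, 0.5)
    expect_identical(r$n_raters, 7L)
    expect_equal(identificationRate(sc, 7)$rate, 1)
    expect_identical(nrow(identificationRate(sc[0, ], 14)), 0L)
    expect_error(identificationRate(sc, 0), "nTotalRaters")
})

test_that("wide table has the reporting layout with missing cells as NA", {
    sc <- rbind(row1("R1", "S.C", view = "superior", siss = 0.43),
                row1("R1", "S.C", view = "lateral_left", siss = 0.51),
                row1("R2", "F.I.P", view = "posterior", hem = "right",
                     siss = 0.3))
    w <- wideTable(meanTable(sc))
    expect_named(w, c("label", "anterior_left", "anterior_right",
                      "superior_left", "superior_right", "posterior_left",
                      "posterior_right", "lateral_left", "lateral_right",
                      "average_left", "average_right"))
    expect_equal(w$superior_left[w$label == "S.C"], 0.43)
    expect_equal(w$average_left[w$label == "S.C"], 0.47)
    expect_true(is.na(w$anterior_left[w$label == "S.C"]))
    expect_true(is.na(w$average_left[w$label == "F.I.P"]))

    dir <- withr::local_tempdir()
    p <- file.path(dir, "table.csv")
    writeAggregateTable(meanTable(sc), p)
    txt <- readLines(p)
    expect_true(any(grepl("-", txt, fixed = TRUE)))
})

test_that("zone classification applies the strict thresholds per best view", {
    mkScores <- function(label, siss, nRaters)
        do.call(rbind, lapply(paste0("R", seq_len(nRaters)), row1,
                              label = label, siss = siss))
    nTotal <- 10
    sc <- rbind(mkScores("S.C", 0.55, 4),       # 40% raters, mean 0.55
                mkScores("F.I.P", 0.45, 3),     # 30% raters, mean 0.45
                mkScores("S.T.s", 0.6, 1))      # 10% raters, mean 0.6
    tb <- meanTable(sc)
    z <- classifyZones(tb, identificationRate(sc, nTotal))
    zz <- setNames(z$zone, z$label)
    expect_identical(zz[["S.C"]], "green")
    expect_identical(zz[["F.I.P"]], "yellow")
    expect_identical(zz[["S.T.s"]], "red")
    ## partition: every classified label gets exactly one zone
    expect_true(all(z$zone %in% c("green", "yellow", "red")))
    expect_false(anyDuplicated(paste(z$label, z$hemisphere)) > 0)
    ## boundary: mean exactly 0.5 is yellow, not green
    zb <- classifyZones(meanTable(mkScores("S.C", 0.5, 4)),
                        identificationRate(mkScores("S.C", 0.5, 4),
                                           nTotal))
    expect_identical(zb$zone, "yellow")
})

test_that("relabelling toward the true reference raises the cell mean", {
    reg <- loadNomenclature()
    refA <- mk(cbind(rep(10L, 30), 11:40), dim = c(100L, 100L),
               label = "S.C", rater = "reference")
    refB <- mk(cbind(rep(60L, 30), 11:40), dim = c(100L, 100L),
               label = "S.Pe.C", rater = "reference")
    ## R1 draws S.C correctly; R2 draws near S.C but labels it S.Pe.C
    d1 <- mk(cbind(rep(11L, 30), 11:40), dim = c(100L, 100L),
             label = "S.C", rater = "R1")
    d2 <- mk(cbind(rep(12L, 30), 11:40), dim = c(100L, 100L),
             label = "S.Pe.C", rater = "R2")
    refs <- list(refA, refB)
    raw <- scoreCohort(list(d1, d2), refs, reg)$scores
    corr <- scoreCohort(list(d1, d2), refs, reg,
                        corrections = correctionTable(
                            "R2", "superior", "S.Pe.C", "S.C"))$scores
    cellMean <- function(s, lab) mean(s$siss[s$label == lab])
    ## the mislabelled cell scores poorly raw and empties after correction
    expect_lt(cellMean(raw, "S.Pe.C"), 0.3)
    expect_false("S.Pe.C" %in% corr$label)
    ## the re-labelled drawing scores far better against its true sulcus
    expect_gt(cellMean(corr, "S.C"), cellMean(raw, "S.Pe.C"))
    expect_gt(mean(corr$siss), mean(raw$siss))
})

test_that("score tables round-trip through CSV and reject malformed input", {
    dir <- withr::local_tempdir()
    sc <- rbind(row1("R1", "S.C", siss = 0.25),
                row1("R2", "F.I.P", siss = 0.75))
    p <- file.path(dir, "scores.csv")
    writeScores(sc, p)
    back <- readScores(p)
    expect_equal(back$siss, sc$siss)
    writeLines("a,b\n1,2", p)
    expect_error(readScores(p), "malformed")
})
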