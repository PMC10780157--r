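test_that("reference generation is deterministic and width-monotone", {
    specs <- referenceSpecs()
    refs1 <- generateReferences(specs)
    refs2 <- generateReferences(specs)
    expect_identical(lapply(refs1, maskPixels), lapply(refs2, maskPixels))
    expect_gte(length(unique(vapply(refs1, sulcusLabel, character(1)))),
               10L)
    expect_setequal(unique(vapply(refs1, viewId, character(1))),
                    sulcusViews)

    ## wider rasterization is a superset of the thin one
    sp <- specs[[1]]
    thin <- sp; thin$width <- 1L
    wide <- sp; wide$width <- 3L
    m1 <- generateReferences(list(thin))[[1]]
    m3 <- generateReferences(list(wide))[[1]]
    k1 <- paste(maskPixels(m1)[, 1], maskPixels(m1)[, 2])
    k3 <- paste(maskPixels(m3)[, 1], maskPixels(m3)[, 2])
    expect_true(all(k1 %in% k3))
    ## at least one pixel per spanned independent coordinate
    expect_gte(nPixels(m1), diff(range(sp$control[, 1])))

    ## a curve leaving the frame is rejected
    off <- referenceSpec("superior", "left", "S.C", "horizontal",
                         rbind(c(1, 5), c(50, -40)), width = 1)
    expect_error(generateReferences(list(off)), "leaves")
})

test_that("a noiseless rater reproduces the references pixel for pixel", {
    refs <- thinReferences()
    sim <- simulateRater(refs, quietConfig())
    expect_length(sim$drawings, length(refs))
    expect_false(any(sim$log$omitted))
    for (i in seq_along(refs))
        expect_identical(maskPixels(sim$drawings[[i]]),
                         maskPixels(refs[[i]]))
})

test_that("simulation is seed-deterministic and honours p_omit", {
    refs <- thinReferences()
    cfg <- raterConfig("R1", seed = 99)
    s1 <- simulateRater(refs, cfg)
    s2 <- simulateRater(refs, cfg)
    expect_identical(lapply(s1$drawings, maskPixels),
                     lapply(s2$drawings, maskPixels))
    expect_identical(s1$log, s2$log)

    none <- simulateRater(refs, quietConfig(p_omit = 1))
    expect_length(none$drawings, 0L)
    expect_true(all(none$log$omitted))
})

test_that("mean SISS degrades monotonically with each noise knob", {
    reg <- loadNomenclature()
    refs <- thinReferences()
    cohortMean <- function(...) {
        m <- vapply(1:8, function(i) {
            sim <- simulateRater(refs, quietConfig(seed = i, ...))
            sc <- scoreCohort(sim$drawings, refs, reg)$scores
            mean(sc$siss)
        }, numeric(1))
        mean(m)
    }
    ## smooth deformation amplitude
    byAmp <- vapply(c(0, 8, 25), function(a)
        cohortMean(smooth_deform_amp = a), numeric(1))
    expect_true(all(diff(byAmp) < 0))
    expect_equal(byAmp[1], 1)
    ## truncation removes covered length, lowering dice
    byTrunc <- vapply(c(0, 0.3, 0.6), function(f)
        cohortMean(truncation_frac = f), numeric(1))
    expect_true(all(diff(byTrunc) < 0))
    ## full rectilinear bias flattens curved sulci and hurts the score
    straight <- cohortMean(rectilinear_bias = 1)
    expect_lt(straight, 1)
})

test_that("label swaps are logged and corrections restore them", {
    reg <- loadNomenclature()
    refs <- generateReferences(referenceSpecs())
    mis <- list()
    for (i in 1:6)
        mis[[i]] <- simulateRater(refs, quietConfig(
            rater = paste0("R", i), seed = 100 + i,
            displacement_px = 3, stroke_width_px = 3, p_mislabel = 0.5))
    drawings <- do.call(c, lapply(mis, `[[`, "drawings"))
    log <- do.call(rbind, lapply(mis, `[[`, "log"))
    swapped <- !log$omitted & log$drawn_label != log$true_label
    expect_gt(sum(swapped), 0)
    ## the drawn labels on the masks match the log
    labs <- vapply(drawings, sulcusLabel, character(1))
    expect_identical(sort(labs), sort(log$drawn_label[!log$omitted]))

    corr <- correctionsFromLog(log)
    expect_identical(nrow(corr), sum(swapped))
    raw <- scoreCohort(drawings, refs, reg)$scores
    fixed <- scoreCohort(drawings, refs, reg, corrections = corr)$scores
    expect_gt(mean(fixed$siss), mean(raw$siss))
})

test_that("emitCohort writes a complete, reproducible fixture tree", {
    dir <- withr::local_tempdir()
    refs <- generateReferences(referenceSpecs())
    cfgs <- cohortConfigs(5, nRaters = 2, p_mislabel = 0.4)
    emitCohort(cfgs, refs, file.path(dir, "a"))
    emitCohort(cfgs, refs, file.path(dir, "b"))
    pngs <- list.files(file.path(dir, "a"), pattern = "\\.png$")
    expect_length(grep("^reference_", pngs), 5L)
    expect_length(grep("^R", pngs), 2L * 5L)
    for (f in c("palette.csv", "corrections.csv", "truth_log.csv"))
        expect_identical(readLines(file.path(dir, "a", f)),
                         readLines(file.path(dir, "b", f)))

    ## the tree loads back and scores: corrected >= raw in every cell
    reg <- loadNomenclature()
    cohort <- loadCohort(file.path(dir, "a"))
    expect_length(cohort$references, length(refs))
    raw <- scoreCohort(cohort$drawings, cohort$references, reg)$scores
    fixed <- scoreCohort(cohort$drawings, cohort$references, reg,
                         corrections = cohort$corrections)$scores
    expect_gte(mean(fixed$siss), mean(raw$siss))
})
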