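test_that("population summaries report mean, histogram and size", {
    s <- summarizePopulation(c(16, 16, 16))
    expect_equal(s$mean, 16)
    expect_identical(s$n, 3L)

    s2 <- summarizePopulation(c(1, 1, 19, 28))
    expect_equal(s2$mean, 12.25)
    expect_identical(as.integer(s2$histogram[c("1", "19", "28")]),
                     c(2L, 1L, 1L))
    expect_identical(sum(s2$histogram), s2$n)

    # permutation invariance and min/max bounds
    set.seed(1)
    x <- sample(1:30, 50, replace = TRUE)
    expect_equal(summarizePopulation(x)$mean,
                 summarizePopulation(sample(x))$mean)
    expect_gte(summarizePopulation(x)$mean, min(x))
    expect_lte(summarizePopulation(x)$mean, max(x))

    # empty input is flagged, not an error
    s0 <- summarizePopulation(integer(0))
    expect_identical(s0$n, 0L)
    expect_true("empty" %in% s0$flags)

    # seeded bootstrap CI brackets the mean deterministically
    set.seed(2)
    b1 <- summarizePopulation(x, bootstrap = 200)
    set.seed(2)
    b2 <- summarizePopulation(x, bootstrap = 200)
    expect_identical(b1[c("ciLow", "ciHigh")], b2[c("ciLow", "ciHigh")])
    expect_lte(b1$ciLow, b1$mean)
    expect_gte(b1$ciHigh, b1$mean)
})

test_that("divisions follow log2 of the OD ratio, summed over days", {
    expect_equal(divisionsFromOD(0.05, 0.8), 4)
    expect_equal(divisionsFromOD(0.3, 0.3), 0)
    expect_equal(divisionsFromOD(c(0.05, 0.05), c(0.4, 0.4)), 6)
    expect_equal(divisionsFromOD(data.frame(start = 0.05, end = 0.8)), 4)
    expect_error(divisionsFromOD(0, 0.5), "positive")
})

test_that("variation index is percent change per division", {
    expect_equal(variationIndex(16, 16, 5)$vi, 0)
    expect_equal(variationIndex(20, 18, 5)$vi, 2)

    # direct recomputation on randomized inputs
    set.seed(3)
    cs <- runif(20, 1, 40); ce <- runif(20, 1, 40); dv <- runif(20, 1, 10)
    expect_equal(variationIndex(cs, ce, dv)$vi,
                 100 * (cs - ce) / cs / dv)

    # swapping start and end flips the sign and rescales by the ratio
    a <- variationIndex(20, 12, 4)$vi
    b <- variationIndex(12, 20, 4)$vi
    expect_equal(b, -a * 20 / 12)

    expect_error(variationIndex(0, 5, 2), "positive")
    expect_error(variationIndex(10, 5, 0), "positive")
})

test_that("qPCR copy number is the ACT1-normalised calibrated ratio", {
    expect_equal(qpcrCopyNumber(1, 1, 16), 16)
    expect_equal(qpcrCopyNumber(0.5, 1, 16), 8)
    expect_error(qpcrCopyNumber(1, 0, 16), "positive")

    # calibration chosen from a sequencing-measured reference sample
    # returns that sample's copy number by construction
    nanoporeMean <- 15.7
    refRatio <- 0.82
    calib <- nanoporeMean / refRatio
    expect_equal(qpcrCopyNumber(refRatio, 1, calib), nanoporeMean)
})

test_that("marker-loss frequency follows dilution-corrected arithmetic", {
    r <- markerLossFrequency(foaAssay(50, 100), foaAssay(10, 100))
    expect_equal(r$frequency, 0.5)
    expect_equal(r$fold, 5)

    # zero resistant colonies
    r0 <- markerLossFrequency(foaAssay(0, 200), foaAssay(10, 100))
    expect_equal(r0$frequency, 0)
    expect_equal(r0$fold, 0)

    # the published-style contrast: 51.7% versus 0.1%
    r2 <- markerLossFrequency(foaAssay(517, 1000), foaAssay(1, 1000))
    expect_equal(r2$frequency, 0.517)
    expect_equal(r2$controlFrequency, 0.001)
    expect_equal(r2$fold, 517)

    # dilution correction
    r3 <- markerLossFrequency(foaAssay(50, 100, resistantDilution = 10,
                                       totalDilution = 1000),
                              foaAssay(10, 100))
    expect_equal(r3$frequency, 50 * 10 / (100 * 1000))

    # zero control frequency: flagged, not an error
    r4 <- markerLossFrequency(foaAssay(5, 100), foaAssay(0, 100))
    expect_true(is.na(r4$fold))
    expect_true("zero_control" %in% r4$flags)
})

test_that("pipeline means on a mixed population match the truth table", {
    unit <- tsUnit(300, seed = 41)
    fp <- tsFlanks(250, 42, 43)
    specs <- list(arraySpec(unit, 3, fp), arraySpec(unit, 8, fp))
    pop <- simulatePopulation(specs, nReads = 40, weights = c(2, 1),
                              model = errorModel(0, 0, 0),
                              lengthDist = NULL, seed = 44)
    counted <- countReads(pop$reads, unit)
    expect_identical(counted$count, pop$truth$copyNumber)
    expect_equal(summarizePopulation(counted)$mean,
                 mean(pop$truth$copyNumber))
})
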