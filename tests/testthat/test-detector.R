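mkSmoothed <- function(v, m) {
    methods::new("SmoothedProfile", values = as.numeric(v), L = 1L,
                 n = length(v), m = as.integer(m))
}

test_that("dense-region search finds blocks, bridges gaps and breaks ties left", {
    par50 <- detectorParams(alpha = 0.5, gapTolerance = 0)

    v <- c(rep(0, 20), rep(1, 15), rep(0, 25))
    r <- findRepeatRegion(mkSmoothed(v, 5), par50)
    expect_true(r@found)
    expect_identical(c(r@start, r@end), c(20L, 35L))

    # two blocks, gap beyond tolerance: the longer one wins
    v2 <- c(rep(1, 30), rep(0, 50), rep(1, 20))
    r2 <- findRepeatRegion(mkSmoothed(v2, 5), par50)
    expect_identical(c(r2@start, r2@end), c(0L, 30L))

    # equal lengths: leftmost wins
    v3 <- c(rep(1, 20), rep(0, 50), rep(1, 20))
    r3 <- findRepeatRegion(mkSmoothed(v3, 5), par50)
    expect_identical(c(r3@start, r3@end), c(0L, 20L))

    # a gap within tolerance is bridged
    v4 <- c(rep(1, 20), rep(0, 10), rep(1, 20))
    r4 <- findRepeatRegion(mkSmoothed(v4, 5),
                           detectorParams(alpha = 0.5, gapTolerance = 10))
    expect_identical(c(r4@start, r4@end), c(0L, 50L))

    # all-zero profile: distinguished not-found result, no exception
    r0 <- findRepeatRegion(mkSmoothed(rep(0, 40), 5), par50)
    expect_false(r0@found)
    expect_identical(regionWidth(r0), 0L)
})

test_that("a clean spectral line is counted at its frequency", {
    i <- 0:999
    v <- 1 + cos(2 * pi * 5 * i / 1000)
    sm <- mkSmoothed(v, 200)
    reg <- findRepeatRegion(sm)
    expect_identical(c(reg@start, reg@end), c(0L, 1000L))
    cc <- countRepeatsDFT(sm, reg, m = 200)
    expect_identical(copyCount(cc), 5L)
    expect_identical(cc@method, "dft")
})

test_that("a flat profile falls back to region length over unit length", {
    sm <- mkSmoothed(rep(5, 1000), 200)
    reg <- findRepeatRegion(sm)
    cc <- countRepeatsDFT(sm, reg, m = 200)
    expect_identical(copyCount(cc), 5L)
    expect_identical(cc@method, "coverage")
    expect_true("flat_spectrum" %in% cc@flags)
})

test_that("counting is invariant under positive scaling of the profile", {
    i <- 0:999
    base <- 1 + cos(2 * pi * 7 * i / 1000)
    for (s in c(0.001, 1, 42, 1e6)) {
        sm <- mkSmoothed(s * base, 140)
        cc <- countRepeatsDFT(sm, findRepeatRegion(sm), m = 140)
        expect_identical(copyCount(cc), 7L, label = paste("scale", s))
    }
})

test_that("short regions and empty regions use their special rules", {
    # region shorter than 1.5 units: single copy, no spectral search
    v <- c(rep(0, 50), rep(3, 120), rep(0, 50))
    sm <- mkSmoothed(v, 100)
    cc <- countRepeatsDFT(sm, findRepeatRegion(sm), m = 100)
    expect_identical(copyCount(cc), 1L)
    expect_identical(cc@method, "single")

    # unfound region: count 0, flagged
    r0 <- findRepeatRegion(mkSmoothed(rep(0, 300), 100))
    cc0 <- countRepeatsDFT(mkSmoothed(rep(0, 300), 100), r0, m = 100)
    expect_identical(copyCount(cc0), 0L)
    expect_true("no_repeat" %in% cc0@flags)
})

test_that("region endpoints land within one unit of the true array", {
    unit <- tsUnit(500, seed = 61)
    fp <- flankPair(randomDNA(1000, seed = 62), randomDNA(1000, seed = 63))
    mol <- buildArrayMolecule(arraySpec(unit, 16, fp))
    prof <- matchRunProfile(mol$sequence, unit)
    sm <- smoothProfile(prof)
    reg <- findRepeatRegion(sm)
    expect_true(reg@found)
    expect_lt(abs(reg@start - mol$truth$arrayStart), 500)
    expect_lt(abs(reg@end - mol$truth$arrayEnd), 500)
})

test_that("a seeded 7-copy read at 5% total error is counted as 7", {
    unit <- tsUnit(1000, seed = 71)
    fp <- flankPair(randomDNA(500, seed = 72), randomDNA(500, seed = 73))
    mol <- buildArrayMolecule(arraySpec(unit, 7, fp))
    set.seed(74)
    rd <- mutateSequence(mol$sequence, scaledErrorModel(0.05))
    expect_identical(copyCount(countRead(rd, unit)), 7L)
})

test_that("copy-consistent unit divergence imprints a countable line", {
    # every copy deviates identically from the reference, so the profile
    # is genuinely periodic and the spectral branch fires
    unit <- tsUnit(2000, seed = 81)
    fp <- flankPair(randomDNA(1000, seed = 82), randomDNA(1000, seed = 83))
    set.seed(84)
    mol <- buildArrayMolecule(arraySpec(unit, 9, fp, unitDivergence = 0.05))
    cc <- countRead(mol$sequence, unit)
    expect_identical(copyCount(cc), 9L)
    expect_identical(cc@method, "dft")
})

test_that("count accuracy does not improve as error rates rise", {
    unit <- tsUnit(1000, seed = 91)
    fp <- flankPair(randomDNA(500, seed = 92), randomDNA(500, seed = 93))
    mol <- buildArrayMolecule(arraySpec(unit, 7, fp))
    set.seed(94)
    acc <- vapply(c(0, 0.08, 0.16), function(tot) {
        model <- scaledErrorModel(tot)
        mean(vapply(1:10, function(i) {
            sim <- simulateRead(mol$sequence, mol$truth, model)
            copyCount(countRead(sim$sequence, unit)) == 7L
        }, logical(1)))
    }, numeric(1))
    expect_identical(acc[1], 1)          # exact at zero error
    expect_true(all(diff(acc) <= 0))     # non-increasing in error rate
})

test_that("countReads returns one tidy row per read", {
    unit <- tsUnit(200, seed = 95)
    fp <- tsFlanks(150, 96, 97)
    mol <- buildArrayMolecule(arraySpec(unit, 4, fp))
    reads <- Biostrings::DNAStringSet(c(r1 = mol$sequence,
                                        r2 = randomDNA(800, seed = 98)))
    df <- countReads(reads, unit)
    expect_identical(df$readId, c("r1", "r2"))
    expect_identical(df$count[1], 4L)
    expect_identical(df$count[2], 0L)
    expect_match(df$flags[2], "no_repeat")
})
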