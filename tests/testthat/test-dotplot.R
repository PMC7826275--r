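test_that("k-mer matching agrees with a brute-force scan", {
    # identity case: one exact self-match on the forward strand
    s <- "ACGGTTACAGGT"
    mm <- kmerMatches(s, s, k = nchar(s))
    expect_identical(nrow(mm), 1L)
    expect_identical(c(mm$readPos, mm$refPos, mm$strand), c("0", "0", "+"))

    # unrelated sequences share no k-mer
    expect_identical(nrow(kmerMatches(randomDNA(200, seed = 1),
                                      randomDNA(200, seed = 2), k = 13)),
                     0L)

    # random pair against the quadratic oracle, both strands
    read <- randomDNA(300, seed = 3)
    ref <- paste0(substr(read, 100, 160),
                  revcompChr(substr(read, 200, 260)))
    got <- kmerMatches(read, ref, k = 8)
    want <- bruteKmerMatches(read, ref, 8)
    rownames(got) <- rownames(want) <- NULL
    got <- got[order(got$readPos, got$refPos, got$strand), ]
    rownames(got) <- NULL
    expect_identical(got, want)
    expect_error(kmerMatches(read, ref, k = 5), ">= 8")
})

test_that("diagonal chaining turns repeat copies into one segment each", {
    unit <- randomDNA(100, seed = 11)
    fp <- tsFlanks(60, 12, 13)
    u <- tsUnit(100, seed = 11)

    mol <- buildArrayMolecule(arraySpec(u, 3, fp))
    segs <- diagonalSegments(kmerMatches(mol$sequence, unit, k = 13),
                             k = 13, maxDiagonalDrift = 10,
                             maxGap = 20, minSeeds = 5)
    expect_identical(nrow(segs), 3L)
    expect_true(all(segs$refStart == 0L & segs$refEnd == 100L))
    expect_true(all(segs$strand == "+"))

    # a partial-unit deletion at a unit edge leaves one shorter segment
    md <- buildArrayMolecule(arraySpec(u, 3, fp,
                                       deletions = list(c(1, 0, 40))))
    segs2 <- diagonalSegments(kmerMatches(md$sequence, unit, k = 13),
                              k = 13, maxDiagonalDrift = 10,
                              maxGap = 20, minSeeds = 5)
    cnt <- countUnitsFromSegments(segs2, m = 100, fullFraction = 0.8)
    expect_identical(cnt$fullUnits, 2L)
    expect_identical(cnt$partialUnits, 1L)

    # empty in, empty out
    none <- kmerMatches(randomDNA(50, seed = 14), unit, k = 13)
    expect_identical(nrow(diagonalSegments(none)), 0L)
})

test_that("full/partial classification is a pure threshold rule", {
    segs <- data.frame(readStart = c(0L, 200L), readEnd = c(95L, 240L),
                       refStart = c(0L, 10L), refEnd = c(95L, 50L),
                       strand = "+", matchCount = c(20L, 6L),
                       stringsAsFactors = FALSE)
    cnt <- countUnitsFromSegments(segs, m = 100, fullFraction = 0.8)
    expect_identical(cnt$fullUnits, 1L)   # 0.95 of the unit
    expect_identical(cnt$partialUnits, 1L) # 0.40 of the unit
})

test_that("dotplot count matches construction and is strand invariant", {
    u <- tsUnit(200, seed = 21)
    fp <- tsFlanks(150, 22, 23)
    mol <- buildArrayMolecule(arraySpec(u, 16, fp))
    dc <- dotplotCount(mol$sequence, u)
    expect_identical(dc$fullUnits, 16L)
    expect_identical(dc$partialUnits, 0L)

    rc <- dotplotCount(revcompChr(mol$sequence), u)
    expect_identical(rc$fullUnits, 16L)
    expect_identical(rc$orientation, "-")
})

test_that("cassette insertions are located at their unit boundary", {
    u <- tsUnit(200, seed = 31)
    fp <- tsFlanks(150, 32, 33)
    cass <- randomDNA(150, seed = 34)
    mol <- buildArrayMolecule(arraySpec(u, 6, fp, cassette = cass,
                                        cassetteBoundary = 3L))
    dc <- dotplotCount(mol$sequence, u, cassette = cass)
    expect_identical(dc$fullUnits, 6L)
    expect_identical(dc$cassetteBoundary, 3L)

    # same molecule read from the other strand
    dcr <- dotplotCount(revcompChr(mol$sequence), u, cassette = cass)
    expect_identical(dcr$cassetteBoundary, 3L)

    # cassette absent from the read
    dna <- dotplotCount(buildArrayMolecule(arraySpec(u, 6, fp))$sequence,
                        u, cassette = cass)
    expect_true(is.na(dna$cassetteBoundary))
    expect_true("cassette_not_found" %in% dna$flags)
})

test_that("cassette boundary is recovered from noisy spanning reads", {
    u <- tsUnit(500, seed = 41)
    fp <- flankPair(randomDNA(500, seed = 42), randomDNA(500, seed = 43))
    cass <- randomDNA(400, seed = 44)
    mol <- buildArrayMolecule(arraySpec(u, 10, fp, cassette = cass,
                                        cassetteBoundary = 5L))
    set.seed(45)
    ok <- vapply(1:20, function(i) {
        sim <- simulateRead(mol$sequence, mol$truth, errorModel())
        dc <- dotplotCount(sim$sequence, u, cassette = cass)
        identical(dc$cassetteBoundary, 5L)
    }, logical(1))
    expect_gte(mean(ok), 0.9)
})
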