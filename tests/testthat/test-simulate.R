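test_that("molecule assembly follows the closed-form layout", {
    unit <- tsUnit(100, seed = 1)
    fp <- tsFlanks(50, 2, 3)
    up <- as.character(fp@upstream)
    down <- as.character(fp@downstream)

    # zero copies: flanks only
    m0 <- buildArrayMolecule(arraySpec(unit, 0, fp))
    expect_identical(m0$sequence, paste0(up, down))

    # 3 copies of a 100-base unit between 50-base flanks: 400 bases
    m3 <- buildArrayMolecule(arraySpec(unit, 3, fp))
    expect_identical(nchar(m3$sequence), 400L)
    expect_identical(m3$truth$copyNumber, 3L)

    # 16 copies with a cassette at boundary 8: closed-form length and
    # the cassette present exactly once
    cass <- randomDNA(120, seed = 4)
    m16 <- buildArrayMolecule(arraySpec(unit, 16, fp, cassette = cass,
                                        cassetteBoundary = 8L))
    expect_identical(nchar(m16$sequence), 50L + 16L * 100L + 120L + 50L)
    hits <- gregexpr(cass, m16$sequence, fixed = TRUE)[[1L]]
    expect_identical(as.integer(hits), 50L + 8L * 100L + 1L)
    expect_identical(m16$truth$cassetteBoundary, 8L)

    # interstitial deletion shortens by the stated amount
    md <- buildArrayMolecule(arraySpec(unit, 3, fp,
                                       deletions = list(c(1, 20, 70))))
    expect_identical(nchar(md$sequence), 400L - 50L)
    expect_identical(md$truth$deletionCount, 1L)

    # deletion referencing a unit beyond the array is rejected
    expect_error(buildArrayMolecule(
        arraySpec(unit, 3, fp, deletions = list(c(3, 0, 10)))))
})

test_that("simulateRead is the identity at zero error and honours strand", {
    unit <- tsUnit(80, seed = 5)
    fp <- tsFlanks(40, 6, 7)
    mol <- buildArrayMolecule(arraySpec(unit, 2, fp))
    e0 <- errorModel(0, 0, 0)

    r <- simulateRead(mol$sequence, mol$truth, e0, strand = "+")
    expect_identical(r$sequence, mol$sequence)
    expect_true(r$truth$isSpanning)

    rm <- simulateRead(mol$sequence, mol$truth, e0, strand = "-",
                       window = c(10L, 100L))
    expect_identical(rm$sequence,
                     revcompChr(substr(mol$sequence, 11L, 100L)))
    expect_false(rm$truth$isSpanning)

    expect_error(simulateRead(mol$sequence, mol$truth, e0,
                              window = c(-1L, 10L)))
})

test_that("substitution process is seeded and has the expected rate", {
    tmpl <- randomDNA(10000, seed = 8)
    model <- errorModel(subRate = 0.05, insRate = 0, delRate = 0)
    set.seed(123)
    a <- mutateSequence(tmpl, model)
    set.seed(123)
    b <- mutateSequence(tmpl, model)
    expect_identical(a, b)  # same seed, same draw
    nm <- sum(strsplit(a, "")[[1L]] != strsplit(tmpl, "")[[1L]])
    # 500 expected; 5 sigma of Binomial(10000, .05) is ~109
    expect_gt(nm, 500 - 110)
    expect_lt(nm, 500 + 110)
})

test_that("error process preserves expected read length", {
    tmpl <- randomDNA(20000, seed = 9)
    model <- errorModel(0.03, 0.02, 0.03)
    set.seed(11)
    lens <- vapply(1:5, function(i) nchar(mutateSequence(tmpl, model)),
                   numeric(1))
    expected <- 20000 * (1 + 0.02 - 0.03)
    expect_lt(abs(mean(lens) - expected), 5 * sqrt(20000 * 0.05))
})

test_that("population simulation is deterministic and truth-consistent", {
    unit <- tsUnit(60, seed = 21)
    fp <- tsFlanks(50, 22, 23)
    spec <- arraySpec(unit, 3, fp)

    p1 <- tempfile(); p2 <- tempfile()
    simulatePopulation(list(spec), nReads = 20, outPrefix = p1, seed = 7)
    simulatePopulation(list(spec), nReads = 20, outPrefix = p2, seed = 7)
    expect_identical(readLines(paste0(p1, ".fastq")),
                     readLines(paste0(p2, ".fastq")))
    expect_identical(readLines(paste0(p1, ".truth.tsv")),
                     readLines(paste0(p2, ".truth.tsv")))

    expect_error(simulatePopulation(list(spec), nReads = 0))

    # full-molecule windows at zero error: every read spans and the
    # spanning flag is re-derivable by exact flank search
    pop <- simulatePopulation(list(spec), nReads = 15,
                              model = errorModel(0, 0, 0),
                              lengthDist = NULL, seed = 31)
    expect_true(all(pop$truth$isSpanning))
    expect_true(all(pop$truth$copyNumber == 3L))
    up <- as.character(fp@upstream)
    for (i in seq_len(15)) {
        s <- as.character(pop$reads[[i]])
        expect_true(grepl(up, s, fixed = TRUE) ||
                    grepl(up, revcompChr(s), fixed = TRUE))
    }
})

test_that("longer arrays are underrepresented among spanning reads", {
    unit <- tsUnit(500, seed = 41)
    fp <- tsFlanks(500, 42, 43)
    specs <- list(arraySpec(unit, 2, fp), arraySpec(unit, 20, fp))
    pop <- simulatePopulation(specs, nReads = 300,
                              lengthDist = list(meanlog = log(5000),
                                                sdlog = 0.6),
                              seed = 77)
    tr <- pop$truth
    fracSpan <- tapply(tr$isSpanning, tr$copyNumber, mean)
    expect_lt(fracSpan[["20"]], fracSpan[["2"]])
})
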