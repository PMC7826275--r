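#' @include AllClasses.R
NULL

#' Random DNA sequence
#'
#' Bases drawn i.i.d. uniform over A/C/G/T.
#'
#' @param n sequence length.
#' @param seed optional integer; when given, the sequence is drawn from
#'   a temporary RNG state so the caller's stream is untouched.
#' @return a character string of length-`n`.
#' @export
randomDNA <- function(n, seed = NULL) {
    draw <- function() paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
    if (is.null(seed)) return(draw())
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    draw()
}

#' @describeIn randomDNA a random [RepeatUnit-class] of `n` bases.
#' @param id identifier for the unit.
#' @export
randomUnit <- function(n, id = "unit", seed = NULL) {
    repeatUnit(randomDNA(n, seed = seed), id = id)
}

#' Apply per-base substitution/insertion/deletion errors to a sequence
#'
#' Each template base independently suffers a substitution (to one of
#' the three other bases), a deletion, or an insertion of one uniform
#' random base after it, with the [ErrorModel-class] rates. Uses the
#' session RNG; call [set.seed()] for reproducibility.
#'
#' @param sequence character string (or [Biostrings::DNAString]).
#' @param model an [ErrorModel-class].
#' @return a character string.
#' @export
mutateSequence <- function(sequence, model = errorModel()) {
    stopifnot(is(model, "ErrorModel"))
    s <- .seq_chr(sequence)
    if (model@subRate + model@insRate + model@delRate == 0) return(s)
    b <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(b)
    if (n == 0L) return(s)
    u <- stats::runif(n)
    out <- b
    bases <- c("A", "C", "G", "T")
    subi <- which(u < model@subRate)
    deli <- which(u >= model@subRate & u < model@subRate + model@delRate)
    insi <- which(u >= model@subRate + model@delRate &
                  u < model@subRate + model@delRate + model@insRate)
    if (length(subi)) {
        ## substitute with one of the three other bases, uniformly
        shift <- sample.int(3L, length(subi), replace = TRUE)
        cur <- match(b[subi], bases)
        cur[is.na(cur)] <- sample.int(4L, sum(is.na(cur)), replace = TRUE)
        out[subi] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    if (length(insi))
        out[insi] <- paste0(out[insi],
                            sample(bases, length(insi), replace = TRUE))
    if (length(deli)) out[deli] <- ""
    paste(out, collapse = "")
}

#' Assemble a tandem-array molecule with ground truth
#'
#' Builds upstream flank + tandem unit copies (with the optional
#' cassette inserted at its unit boundary and interstitial deletions
#' applied) + downstream flank, and returns the sequence together with
#' a ground-truth record describing it.
#'
#' @param spec an [ArraySpec-class].
#' @param moleculeId identifier stored in the truth record.
#' @return a list with elements `sequence` (character) and `truth`, a
#'   list with fields `moleculeId`, `copyNumber`, `cassetteBoundary`
#'   (`NA` when absent), `deletionCount`, `upstreamLength`,
#'   `downstreamLength`, `arrayStart`, `arrayEnd` (0-based half-open
#'   interval of the array, cassette included, within the molecule) and
#'   `length`.
#' @examples
#' u <- randomUnit(100, seed = 1)
#' fp <- flankPair(randomDNA(50, seed = 2), randomDNA(50, seed = 3))
#' mol <- buildArrayMolecule(arraySpec(u, 3, fp))
#' mol$truth$length  # 50 + 3 * 100 + 50
#' @export
buildArrayMolecule <- function(spec, moleculeId = "mol") {
    stopifnot(is(spec, "ArraySpec"))
    validObject(spec)
    m <- unitLength(spec@unit)
    unitChr <- as.character(unitSequence(spec@unit))
    if (spec@unitDivergence > 0)
        unitChr <- mutateSequence(unitChr,
            errorModel(subRate = spec@unitDivergence, insRate = 0,
                       delRate = 0))
    copies <- rep(unitChr, spec@copyNumber)
    for (d in spec@deletions) {
        i <- d[1L] + 1L
        copies[i] <- paste0(substr(copies[i], 1L, d[2L]),
                            substr(copies[i], d[3L] + 1L, m))
    }
    if (!is.null(spec@cassette)) {
        b <- spec@cassetteBoundary
        body <- paste0(paste(copies[seq_len(b)], collapse = ""),
                       as.character(spec@cassette),
                       paste(copies[seq_len(spec@copyNumber) > b],
                             collapse = ""))
    } else {
        body <- paste(copies, collapse = "")
    }
    up <- as.character(spec@flanks@upstream)
    down <- as.character(spec@flanks@downstream)
    seq <- paste0(up, body, down)
    truth <- list(
        moleculeId = moleculeId,
        copyNumber = spec@copyNumber,
        cassetteBoundary = if (is.null(spec@cassette)) NA_integer_
                           else spec@cassetteBoundary,
        deletionCount = length(spec@deletions),
        upstreamLength = nchar(up),
        downstreamLength = nchar(down),
        arrayStart = nchar(up),
        arrayEnd = nchar(up) + nchar(body),
        length = nchar(seq))
    list(sequence = seq, truth = truth)
}

#' Simulate one read from a molecule
#'
#' Extracts `window` from the molecule, applies the error model, and
#' reverse-complements when the drawn (or given) strand is `"-"`. The
#' returned truth extends the molecule truth with the window, strand
#' and the spanning flag, which is true exactly when the window covers
#' both full flanks.
#'
#' @param molecule character sequence of the template molecule.
#' @param truth the molecule truth from [buildArrayMolecule()].
#' @param model an [ErrorModel-class].
#' @param window 0-based half-open interval `c(start, end)` within the
#'   molecule; `NULL` (default) reads the whole molecule.
#' @param strand `"+"`, `"-"`, or `NULL` to draw uniformly.
#' @param readId identifier for the read.
#' @return a list with `sequence` (character) and `truth` (list; adds
#'   `readId`, `strand`, `windowStart`, `windowEnd`, `isSpanning`).
#' @export
simulateRead <- function(molecule, truth, model = errorModel(),
                         window = NULL, strand = NULL, readId = "read") {
    molLen <- nchar(molecule)
    if (is.null(window)) window <- c(0L, molLen)
    if (window[1L] < 0 || window[2L] > molLen || window[1L] >= window[2L])
        stop("window must be a non-empty 0-based half-open interval ",
             "within the molecule")
    if (is.null(strand)) strand <- sample(c("+", "-"), 1L)
    s <- substr(molecule, window[1L] + 1L, window[2L])
    s <- mutateSequence(s, model)
    if (strand == "-")
        s <- as.character(reverseComplement(DNAString(s)))
    spanning <- window[1L] <= 0L &&
        window[2L] >= truth$length  # both full flanks covered
    tr <- truth
    tr$readId <- readId
    tr$strand <- strand
    tr$windowStart <- as.integer(window[1L])
    tr$windowEnd <- as.integer(window[2L])
    tr$isSpanning <- spanning
    list(sequence = s, truth = tr)
}

#' Simulate a read population from a mixture of array molecules
#'
#' Emulates sequencing a heterogeneous cell population: each read picks
#' a molecule in proportion to `weights`, draws a read length from a
#' log-normal (the shape of a ligation-prep nanopore run), places the
#' window uniformly, applies the error model, and draws the strand
#' uniformly. Reads whose drawn length reaches the molecule length
#' return the whole molecule and are therefore spanning.
#'
#' @param specs a list of [ArraySpec-class] objects (one per
#'   subpopulation).
#' @param nReads number of reads (> 0).
#' @param weights non-negative sampling weights, summing > 0 (default
#'   equal).
#' @param model an [ErrorModel-class].
#' @param lengthDist list with `meanlog` and `sdlog` for the log-normal
#'   read length (defaults `log(8000)` and `0.6`), or `NULL` to read
#'   every molecule end to end.
#' @param outPrefix when non-`NULL`, writes `<outPrefix>.fastq` and
#'   `<outPrefix>.truth.tsv`.
#' @param seed optional integer seed (sets the session RNG).
#' @return invisibly, a list with `reads` (a named
#'   [Biostrings::DNAStringSet]) and `truth` (a `data.frame`, one row
#'   per read).
#' @export
simulatePopulation <- function(specs, nReads, weights = NULL,
                               model = errorModel(),
                               lengthDist = list(meanlog = log(8000),
                                                 sdlog = 0.6),
                               outPrefix = NULL, seed = NULL) {
    if (nReads <= 0) stop("'nReads' must be positive")
    if (is(specs, "ArraySpec")) specs <- list(specs)
    if (is.null(weights)) weights <- rep(1, length(specs))
    if (length(weights) != length(specs) || any(weights < 0) ||
        sum(weights) <= 0)
        stop("'weights' must be non-negative, match 'specs' and sum > 0")
    if (!is.null(seed)) set.seed(seed)
    mols <- lapply(seq_along(specs), function(i)
        buildArrayMolecule(specs[[i]], moleculeId = paste0("mol", i)))
    pick <- sample.int(length(specs), nReads, replace = TRUE,
                       prob = weights / sum(weights))
    reads <- character(nReads)
    truths <- vector("list", nReads)
    for (r in seq_len(nReads)) {
        mol <- mols[[pick[r]]]
        molLen <- mol$truth$length
        len <- if (is.null(lengthDist)) molLen else
            max(200L, as.integer(round(stats::rlnorm(1,
                lengthDist$meanlog, lengthDist$sdlog))))
        len <- min(len, molLen)
        start <- if (len >= molLen) 0L else
            sample.int(molLen - len + 1L, 1L) - 1L
        sim <- simulateRead(mol$sequence, mol$truth, model,
                            window = c(start, start + len),
                            readId = sprintf("read%04d", r))
        reads[r] <- sim$sequence
        truths[[r]] <- sim$truth
    }
    truth <- do.call(rbind, lapply(truths, function(t)
        as.data.frame(t[c("readId", "moleculeId", "copyNumber",
                          "cassetteBoundary", "deletionCount", "strand",
                          "windowStart", "windowEnd", "isSpanning")],
                      stringsAsFactors = FALSE)))
    dss <- DNAStringSet(reads)
    names(dss) <- truth$readId
    if (!is.null(outPrefix)) {
        writeSeqs(dss, paste0(outPrefix, ".fastq"), format = "fastq")
        writeTable(truth, paste0(outPrefix, ".truth.tsv"))
    }
    invisible(list(reads = dss, truth = truth))
}
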