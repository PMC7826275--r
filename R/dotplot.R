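#' @include profile.R
NULL

#' Exact k-mer matches between a read and a reference
#'
#' All exact k-mer matches on both strands, as the raw material of a
#' dot plot: a match at `(readPos, refPos, "+")` means the read k-mer
#' starting at `readPos` equals the reference k-mer at `refPos`; on
#' strand `"-"` it equals its reverse complement. Positions are 0-based.
#' K-mers containing ambiguity codes match nothing.
#'
#' @param read,reference sequences (character, [Biostrings::DNAString],
#'   or length-1 sets).
#' @param k k-mer size, at least 8 (smaller seeds flood the plot with
#'   random matches).
#' @return a `data.frame` with columns `readPos`, `refPos`, `strand`.
#' @examples
#' kmerMatches("ACGTACGTTT", "ACGTACGT", k = 8)
#' @export
kmerMatches <- function(read, reference, k = 13L) {
    if (k < 8L) stop("'k' must be >= 8")
    s <- .seq_chr(read)
    f <- .seq_chr(reference)
    fwd <- .kmer_matches_cpp(s, f, as.integer(k))
    rcf <- as.character(reverseComplement(DNAString(f)))
    rev <- .kmer_matches_cpp(s, rcf, as.integer(k))
    out <- rbind(
        if (nrow(fwd)) data.frame(readPos = fwd$readPos,
                                  refPos = fwd$refPos, strand = "+",
                                  stringsAsFactors = FALSE),
        if (nrow(rev)) data.frame(readPos = rev$readPos,
                                  refPos = nchar(f) - k - rev$refPos,
                                  strand = "-", stringsAsFactors = FALSE))
    if (is.null(out))
        out <- data.frame(readPos = integer(0), refPos = integer(0),
                          strand = character(0), stringsAsFactors = FALSE)
    out[order(out$readPos, out$refPos), , drop = FALSE]
}

#' Chain k-mer matches into diagonal segments
#'
#' Groups matches lying on a near-constant diagonal — the dot-plot
#' signature of one repeat-unit copy — allowing the diagonal offset to
#' drift by up to `maxDiagonalDrift` bases (absorbing indels) and read
#' gaps of up to `maxGap` bases between consecutive seeds. Chains with
#' fewer than `minSeeds` matches are discarded as noise.
#'
#' @param matches `data.frame` from [kmerMatches()].
#' @param k the k-mer size the matches were computed with (used to turn
#'   start positions into intervals).
#' @param maxDiagonalDrift,maxGap,minSeeds chaining thresholds.
#' @return a `data.frame`, one row per segment, sorted by read position:
#'   `readStart`, `readEnd`, `refStart`, `refEnd` (0-based half-open),
#'   `strand`, `matchCount`.
#' @export
diagonalSegments <- function(matches, k = 13L, maxDiagonalDrift = 200,
                             maxGap = 400, minSeeds = 5L) {
    empty <- data.frame(readStart = integer(0), readEnd = integer(0),
                        refStart = integer(0), refEnd = integer(0),
                        strand = character(0), matchCount = integer(0),
                        stringsAsFactors = FALSE)
    if (nrow(matches) == 0L) return(empty)
    segs <- list()
    for (str in unique(matches$strand)) {
        mm <- matches[matches$strand == str, , drop = FALSE]
        off <- if (str == "+") mm$readPos - mm$refPos
               else mm$readPos + mm$refPos
        o <- order(off, mm$readPos)
        mm <- mm[o, , drop = FALSE]
        off <- off[o]
        ## split into diagonal clusters, then by read gaps
        newClust <- c(TRUE, diff(off) > maxDiagonalDrift)
        cl <- cumsum(newClust)
        for (g in split(seq_len(nrow(mm)), cl)) {
            sub <- mm[g, , drop = FALSE]
            sub <- sub[order(sub$readPos), , drop = FALSE]
            brk <- c(TRUE, diff(sub$readPos) > maxGap)
            for (h in split(seq_len(nrow(sub)), cumsum(brk))) {
                ch <- sub[h, , drop = FALSE]
                if (nrow(ch) < minSeeds) next
                segs[[length(segs) + 1L]] <- data.frame(
                    readStart = min(ch$readPos),
                    readEnd = max(ch$readPos) + k,
                    refStart = min(ch$refPos),
                    refEnd = max(ch$refPos) + k,
                    strand = str, matchCount = nrow(ch),
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(segs)) return(empty)
    out <- do.call(rbind, segs)
    out[order(out$readStart), , drop = FALSE]
}

#' Count full and partial repeat units from diagonal segments
#'
#' A segment whose reference interval covers at least `fullFraction` of
#' the unit counts as one full unit; shorter segments count as partial
#' units (interstitial deletions or array-edge truncations).
#'
#' @param segments `data.frame` from [diagonalSegments()].
#' @param m unit length.
#' @param fullFraction fraction of `m` a segment must cover to count as
#'   a full unit (default 0.8).
#' @return a list with `fullUnits` and `partialUnits`.
#' @export
countUnitsFromSegments <- function(segments, m, fullFraction = 0.8) {
    if (nrow(segments) == 0L)
        return(list(fullUnits = 0L, partialUnits = 0L))
    cov <- segments$refEnd - segments$refStart
    full <- cov >= fullFraction * m
    list(fullUnits = as.integer(sum(full)),
         partialUnits = as.integer(sum(!full)))
}

#' Dot-plot repeat count for one read
#'
#' The automated equivalent of counting diagonal lines in a dot plot of
#' a read against the repeat unit: k-mer matches are chained into
#' diagonal segments, each segment covering (nearly) the whole unit is
#' one repeat copy, and shorter segments are reported as partial units.
#' When a cassette sequence is supplied its insertion point is located
#' as the number of full units entirely on the array-upstream side of
#' the cassette's own diagonal segment.
#'
#' @param read a single read.
#' @param unit the repeat-unit reference ([RepeatUnit-class], character
#'   or [Biostrings::DNAString]).
#' @param cassette optional cassette sequence to locate.
#' @param k seed k-mer size (default 13).
#' @param maxDiagonalDrift,maxGap,minSeeds,fullFraction thresholds;
#'   `NA` drift/gap default to `0.1 * m` and `0.2 * m`.
#' @return a list: `fullUnits`, `partialUnits`, `cassetteBoundary`
#'   (`NA` when no cassette was given or found), `orientation`
#'   (`"+"`, `"-"` or `"*"`), `segments` (the unit segments), `flags`.
#' @examples
#' u <- randomUnit(100, seed = 1)
#' rd <- paste0(randomDNA(50, seed = 2),
#'              strrep(as.character(unitSequence(u)), 3),
#'              randomDNA(50, seed = 3))
#' dotplotCount(rd, u)$fullUnits  # 3
#' @export
dotplotCount <- function(read, unit, cassette = NULL, k = 13L,
                         maxDiagonalDrift = NA, maxGap = NA,
                         minSeeds = 5L, fullFraction = 0.8) {
    uChr <- .unit_chr(unit)
    m <- nchar(uChr)
    if (is.na(maxDiagonalDrift)) maxDiagonalDrift <- 0.1 * m
    if (is.na(maxGap)) maxGap <- 0.2 * m
    s <- .seq_chr(read)
    segs <- diagonalSegments(kmerMatches(s, uChr, k = k), k = k,
                             maxDiagonalDrift = maxDiagonalDrift,
                             maxGap = maxGap, minSeeds = minSeeds)
    counts <- countUnitsFromSegments(segs, m, fullFraction)
    flags <- character()
    orientation <- "*"
    if (nrow(segs)) {
        w <- tapply(segs$matchCount, segs$strand, sum)
        orientation <- names(w)[which.max(w)]
    }
    boundary <- NA_integer_
    if (!is.null(cassette)) {
        cChr <- .seq_chr(cassette)
        if (!nchar(cChr)) stop("'cassette' must be non-empty")
        csegs <- diagonalSegments(kmerMatches(s, cChr, k = k), k = k,
                                  maxDiagonalDrift =
                                      0.1 * nchar(cChr) + maxDiagonalDrift,
                                  maxGap = maxGap, minSeeds = minSeeds)
        if (nrow(csegs) == 0L) {
            flags <- c(flags, "cassette_not_found")
        } else {
            cs <- csegs[which.max(csegs$refEnd - csegs$refStart), ]
            fullSegs <- segs[(segs$refEnd - segs$refStart) >=
                                 fullFraction * m, , drop = FALSE]
            boundary <- if (orientation == "-")
                sum(fullSegs$readStart >= cs$readEnd)
            else sum(fullSegs$readEnd <= cs$readStart)
            boundary <- as.integer(boundary)
        }
    }
    list(fullUnits = counts$fullUnits, partialUnits = counts$partialUnits,
         cassetteBoundary = boundary, orientation = orientation,
         segments = segs, flags = flags)
}

#' @describeIn dotplotCount count a whole read set; returns a
#'   `data.frame` with `readId`, `fullUnits`, `partialUnits`,
#'   `cassetteBoundary`, `orientation`, `flags`.
#' @param reads a named [Biostrings::DNAStringSet] or character vector.
#' @param ... passed on to `dotplotCount()`.
#' @export
dotplotCounts <- function(reads, unit, cassette = NULL, ...) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    rows <- lapply(seq_along(reads), function(i) {
        dc <- dotplotCount(reads[[i]], unit, cassette = cassette, ...)
        data.frame(readId = ids[i], fullUnits = dc$fullUnits,
                   partialUnits = dc$partialUnits,
                   cassetteBoundary = dc$cassetteBoundary,
                   orientation = dc$orientation,
                   flags = paste(dc$flags, collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
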