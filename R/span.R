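#' @include dotplot.R
NULL

## local alignment of an oriented flank against a read window;
## returns identity, coverage and the 0-based half-open read interval
.align_flank <- function(readChr, flankChr, winStart, winEnd) {
    win <- substr(readChr, winStart + 1L, winEnd)
    mat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                        baseOnly = FALSE)
    al <- pairwiseAlignment(DNAString(flankChr), DNAString(win),
                            type = "local", substitutionMatrix = mat,
                            gapOpening = 0, gapExtension = 1)
    pr <- pattern(al)                      # aligned flank range
    sr <- subject(al)
    cols <- nchar(as.character(pr))        # alignment columns incl gaps
    if (cols == 0L) return(NULL)
    list(identity = nmatch(al) / cols,
         coverage = (end(pr) - start(pr) + 1L) / nchar(flankChr),
         readStart = winStart + start(sr) - 1L,
         readEnd = winStart + end(sr))
}

#' Find a flank sequence in a read by seed-and-extend
#'
#' Exact k-mer seeds between the read (both strands) and the flank are
#' chained along near-constant diagonals; each chained candidate region
#' is re-aligned locally (edit-distance-like scoring) and scored by
#' percent identity and by the fraction of the flank covered. Hits
#' below `minIdentity` or `minCoverage` are discarded.
#'
#' @param read a single read.
#' @param flank the flank sequence (character or
#'   [Biostrings::DNAString]).
#' @param k seed length (default 15).
#' @param minIdentity,minCoverage acceptance thresholds (defaults 0.75
#'   and 0.5, tuned for ~10\% read error).
#' @param label stored in the `flank` column of the result.
#' @return a `data.frame` sorted by read position, one row per hit:
#'   `readStart`, `readEnd` (0-based half-open), `strand`, `identity`,
#'   `coverage`, `flank`. Zero rows is a valid result.
#' @export
findFlankHits <- function(read, flank, k = 15L, minIdentity = 0.75,
                          minCoverage = 0.5, label = "flank") {
    s <- .seq_chr(read)
    f <- .seq_chr(flank)
    fl <- nchar(f)
    if (k > fl) stop("'k' must not exceed the flank length")
    empty <- data.frame(readStart = integer(0), readEnd = integer(0),
                        strand = character(0), identity = numeric(0),
                        coverage = numeric(0), flank = character(0),
                        stringsAsFactors = FALSE)
    mm <- kmerMatches(s, f, k = k)
    if (nrow(mm) == 0L) return(empty)
    segs <- diagonalSegments(mm, k = k, maxDiagonalDrift = 0.2 * fl,
                             maxGap = 0.3 * fl, minSeeds = 3L)
    if (nrow(segs) == 0L) return(empty)
    hits <- list()
    pad <- as.integer(0.1 * fl) + k
    for (i in seq_len(nrow(segs))) {
        sg <- segs[i, ]
        ## candidate window: chained read span extended to the full
        ## (orientation-aware) flank extent plus padding
        if (sg$strand == "+") {
            ws <- sg$readStart - sg$refStart - pad
            we <- sg$readEnd + (fl - sg$refEnd) + pad
            fo <- f
        } else {
            ws <- sg$readStart - (fl - sg$refEnd) - pad
            we <- sg$readEnd + sg$refStart + pad
            fo <- as.character(reverseComplement(DNAString(f)))
        }
        ws <- max(0L, as.integer(ws))
        we <- min(nchar(s), as.integer(we))
        if (we <= ws) next
        al <- .align_flank(s, fo, ws, we)
        if (is.null(al)) next
        if (al$identity < minIdentity || al$coverage < minCoverage) next
        hits[[length(hits) + 1L]] <- data.frame(
            readStart = al$readStart, readEnd = al$readEnd,
            strand = sg$strand, identity = al$identity,
            coverage = al$coverage, flank = label,
            stringsAsFactors = FALSE)
    }
    if (!length(hits)) return(empty)
    out <- do.call(rbind, hits)
    ## collapse near-duplicate hits (same strand, heavy overlap):
    ## keep the best-scoring, leftmost on ties
    out <- out[order(-out$identity * out$coverage, out$readStart), ,
               drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
        if (!keep[i]) next
        if (i < nrow(out)) for (j in (i + 1L):nrow(out)) {
            if (!keep[j] || out$strand[j] != out$strand[i]) next
            ov <- min(out$readEnd[i], out$readEnd[j]) -
                  max(out$readStart[i], out$readStart[j])
            if (ov > 0.5 * (out$readEnd[j] - out$readStart[j]))
                keep[j] <- FALSE
        }
    }
    out <- out[keep, , drop = FALSE]
    out[order(out$readStart), , drop = FALSE]
}

#' Classify whether a read spans the entire tandem array
#'
#' A read spans the array when it contains hits to both the upstream
#' and the downstream flank on the same strand, in array order:
#' upstream before downstream on `"+"`, the reverse on `"-"` (a
#' reverse-complemented read presents the downstream flank first). The
#' interval between the inner flank edges is reported as the array
#' interval. When consistent pairs exist in both orientations with
#' equal scores, the call is flagged undetermined.
#'
#' @param read a single read.
#' @param flanks a [FlankPair-class].
#' @param k,minIdentity,minCoverage passed to [findFlankHits()].
#' @param readId identifier for the result.
#' @return a list: `readId`, `spanning` (logical), `orientation`
#'   (`"+"`, `"-"` or `"undetermined"`), `arrayStart`, `arrayEnd`
#'   (0-based half-open, `NA` when not spanning; an empty interval is
#'   legitimate for a zero-copy array), `flags`.
#' @export
classifySpanning <- function(read, flanks, k = 15L, minIdentity = 0.75,
                             minCoverage = 0.5, readId = "") {
    stopifnot(is(flanks, "FlankPair"))
    s <- .seq_chr(read)
    up <- findFlankHits(s, flanks@upstream, k = k,
                        minIdentity = minIdentity,
                        minCoverage = minCoverage, label = "upstream")
    down <- findFlankHits(s, flanks@downstream, k = k,
                          minIdentity = minIdentity,
                          minCoverage = minCoverage, label = "downstream")
    best <- list()
    for (str in c("+", "-")) {
        uu <- up[up$strand == str, , drop = FALSE]
        dd <- down[down$strand == str, , drop = FALSE]
        if (!nrow(uu) || !nrow(dd)) next
        cand <- NULL
        for (i in seq_len(nrow(uu))) for (j in seq_len(nrow(dd))) {
            ok <- if (str == "+") uu$readEnd[i] <= dd$readStart[j]
                  else dd$readEnd[j] <= uu$readStart[i]
            if (!ok) next
            sc <- uu$identity[i] * uu$coverage[i] +
                  dd$identity[j] * dd$coverage[j]
            lo <- min(uu$readStart[i], dd$readStart[j])
            if (is.null(cand) || sc > cand$score ||
                (sc == cand$score && lo < cand$left))
                cand <- list(u = uu[i, ], d = dd[j, ], score = sc,
                             left = lo)
        }
        if (!is.null(cand)) best[[str]] <- cand
    }
    res <- list(readId = readId, spanning = FALSE,
                orientation = "undetermined",
                arrayStart = NA_integer_, arrayEnd = NA_integer_,
                flags = character())
    if (!length(best)) return(res)
    if (length(best) == 2L && best[["+"]]$score == best[["-"]]$score) {
        res$flags <- "conflicting_orientations"
        return(res)
    }
    str <- if (length(best) == 1L) names(best)
           else names(best)[which.max(c(best[["+"]]$score,
                                        best[["-"]]$score))]
    b <- best[[str]]
    res$spanning <- TRUE
    res$orientation <- str
    if (str == "+") {
        res$arrayStart <- as.integer(b$u$readEnd)
        res$arrayEnd <- as.integer(b$d$readStart)
    } else {
        res$arrayStart <- as.integer(b$d$readEnd)
        res$arrayEnd <- as.integer(b$u$readStart)
    }
    res
}

#' @describeIn classifySpanning classify a whole read set; returns a
#'   `data.frame` with columns `readId`, `spanning`, `orientation`,
#'   `arrayStart`, `arrayEnd`, `flags`.
#' @param reads a named [Biostrings::DNAStringSet] or character vector.
#' @export
selectSpanning <- function(reads, flanks, k = 15L, minIdentity = 0.75,
                           minCoverage = 0.5) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    rows <- lapply(seq_along(reads), function(i) {
        cl <- classifySpanning(reads[[i]], flanks, k = k,
                               minIdentity = minIdentity,
                               minCoverage = minCoverage,
                               readId = ids[i])
        data.frame(readId = cl$readId, spanning = cl$spanning,
                   orientation = cl$orientation,
                   arrayStart = cl$arrayStart, arrayEnd = cl$arrayEnd,
                   flags = paste(cl$flags, collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
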