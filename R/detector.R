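#' @include profile.R
NULL

## marked runs (TRUE blocks) of a logical vector as a 2-column matrix of
## 1-based [start, end] positions
.true_runs <- function(mk) {
    rl <- rle(mk)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    cbind(starts[keep], ends[keep])
}

#' Locate the dense profile region harbouring the repeat array
#'
#' Marks positions whose smoothed profile exceeds `alpha` times the
#' profile maximum, merges marked blocks separated by gaps of at most
#' `gapTolerance` bases (so that a cassette insertion inside the array
#' does not split the region), and returns the longest merged block;
#' ties are broken towards the leftmost block. An all-zero profile
#' yields the distinguished "not found" region rather than an error.
#'
#' @param smoothed a [SmoothedProfile-class].
#' @param params a [DetectorParams-class]; `alpha` and `gapTolerance`
#'   are used (`gapTolerance = NA` means one unit length).
#' @return a [RepeatRegion-class] (0-based half-open coordinates).
#' @export
findRepeatRegion <- function(smoothed, params = detectorParams()) {
    stopifnot(is(smoothed, "SmoothedProfile"), is(params, "DetectorParams"))
    v <- smoothed@values
    gap <- params@gapTolerance
    if (is.na(gap)) gap <- smoothed@m
    none <- new("RepeatRegion", start = 0L, end = 0L, found = FALSE)
    if (length(v) == 0L || max(v) <= 0) return(none)
    mk <- v > params@alpha * max(v)
    if (!any(mk)) return(none)
    blocks <- .true_runs(mk)
    merged <- blocks[1L, , drop = FALSE]
    if (nrow(blocks) > 1L) for (b in 2:nrow(blocks)) {
        if (blocks[b, 1L] - merged[nrow(merged), 2L] - 1L <= gap)
            merged[nrow(merged), 2L] <- blocks[b, 2L]
        else merged <- rbind(merged, blocks[b, , drop = FALSE])
    }
    lens <- merged[, 2L] - merged[, 1L] + 1L
    best <- merged[which.max(lens), ]     # which.max is leftmost on ties
    new("RepeatRegion", start = as.integer(best[1L] - 1L),
        end = as.integer(best[2L]), found = TRUE)
}

## Dense-coverage count: region length minus non-repeat insertions,
## divided by the unit length, rounded half away from zero. A gap is
## treated as an insertion (a cassette, say) only when it is both long
## (> insGap) and deep (mean smoothed profile < 0.25 * alpha * max):
## shallow dips just below the marking threshold are error dropouts
## within the array and must not shorten the effective length.
.coverage_count <- function(v, region, m, alpha, insGap) {
    idx <- (region@start + 1L):region@end
    vi <- v[idx]
    mk <- vi > alpha * max(v)
    gaps <- rle(mk)
    ends <- cumsum(gaps$lengths)
    starts <- ends - gaps$lengths + 1L
    deep <- 0L
    for (g in which(!gaps$values & gaps$lengths > insGap)) {
        if (mean(vi[starts[g]:ends[g]]) < 0.25 * alpha * max(v))
            deep <- deep + gaps$lengths[g]
    }
    eff <- length(idx) - deep
    as.integer(floor(eff / m + 0.5))
}

#' Count repeat units in a region by discrete Fourier transform
#'
#' Takes the smoothed profile restricted to the dense region, subtracts
#' its mean, applies a Hann window (suppressing the spectral leakage of
#' the region's rectangular envelope, which otherwise swamps the band),
#' and searches the magnitude spectrum for the repeat fundamental inside
#' the band `[bandLow * |R| / m, bandHigh * |R| / m]`.
#'
#' The in-band peak is accepted as a true periodic line only when it is
#' decisively prominent over the local spectral floor
#' (`peakProminence`-fold in power), sits above the envelope-leakage
#' bins (a fundamental below bin 4 is never trusted, since the region's
#' own rectangular shape concentrates power there), and its interpolated
#' frequency agrees with the dense-coverage estimate within 1: per-unit
#' periodicity in the profile comes from copy-consistent mismatches
#' against the reference (strain divergence, systematic basecalls), and
#' when the mismatch process is instead independent per copy the
#' spectrum contains no line, only noise whose in-band maximum would
#' otherwise masquerade as a count. When no line is accepted, the count
#' falls back to the effective dense-coverage length divided by the unit
#' length, with unmatched stretches longer than `insertionGap` excluded
#' as non-repeat insertions (a cassette, for instance). Regions shorter
#' than 1.5 units are reported as a single copy without spectral search,
#' since a one-period signal has no usable fundamental.
#'
#' @param smoothed a [SmoothedProfile-class].
#' @param region a [RepeatRegion-class] from [findRepeatRegion()].
#' @param m unit length in bases (defaults to the profile's own).
#' @param params a [DetectorParams-class].
#' @param readId identifier stored in the result.
#' @return a [CopyCount-class]. An unfound/empty region yields count 0
#'   flagged `"no_repeat"`.
#' @export
countRepeatsDFT <- function(smoothed, region, m = smoothed@m,
                            params = detectorParams(), readId = "") {
    stopifnot(is(smoothed, "SmoothedProfile"), is(region, "RepeatRegion"))
    band <- c(NA_integer_, NA_integer_)
    if (!region@found)
        return(new("CopyCount", count = 0L, peakMagnitude = 0,
                   band = band, method = "none", readId = readId,
                   flags = "no_repeat", region = region,
                   orientation = "*"))
    v <- smoothed@values
    len <- region@end - region@start
    if (len < 1.5 * m)
        return(new("CopyCount", count = 1L, peakMagnitude = 0,
                   band = band, method = "single", readId = readId,
                   flags = character(), region = region,
                   orientation = "*"))
    insGap <- params@insertionGap
    if (is.na(insGap)) insGap <- m / 10
    covCount <- .coverage_count(v, region, m, params@alpha, insGap)

    x <- v[(region@start + 1L):region@end]
    x <- x - mean(x)
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
    mg2 <- Mod(stats::fft(x * hann))[2:(len %/% 2 + 1L)]^2
    blo <- max(1L, as.integer(floor(params@bandLow * len / m)))
    bhi <- min(as.integer(ceiling(params@bandHigh * len / m)), length(mg2))
    band <- c(blo, bhi)
    if (blo > bhi || sum(mg2) == 0)
        return(new("CopyCount", count = covCount, peakMagnitude = 0,
                   band = band, method = "coverage", readId = readId,
                   flags = "flat_spectrum", region = region,
                   orientation = "*"))
    pk <- which.max(mg2[blo:bhi]) + blo - 1L
    floorIdx <- setdiff(blo:min(length(mg2), 4L * bhi), (pk - 2L):(pk + 2L))
    floorPow <- if (length(floorIdx)) stats::median(mg2[floorIdx]) else 0
    prominent <- if (floorPow > 0) mg2[pk] / floorPow >= params@peakProminence
                 else mg2[pk] > 0
    ## quadratic interpolation of the peak frequency in bins
    fstar <- pk
    if (pk > 1L && pk < length(mg2)) {
        a <- mg2[pk - 1L]; b <- mg2[pk]; cc <- mg2[pk + 1L]
        den <- a - 2 * b + cc
        if (den < 0) fstar <- pk + 0.5 * (a - cc) / den
    }
    lineCount <- as.integer(floor(fstar + 0.5))
    ## the line is used only when separated from the envelope leakage
    ## (bins <= 3, the spectral footprint of the region's own shape) and
    ## consistent with the dense-coverage estimate to within one unit
    if (prominent && lineCount >= 4L &&
        abs(lineCount - covCount) <= 1L &&
        lineCount >= blo && lineCount <= bhi)
        return(new("CopyCount", count = lineCount,
                   peakMagnitude = sqrt(mg2[pk]), band = band,
                   method = "dft", readId = readId, flags = character(),
                   region = region, orientation = "*"))
    new("CopyCount", count = covCount, peakMagnitude = sqrt(mg2[pk]),
        band = band, method = "coverage", readId = readId,
        flags = character(), region = region, orientation = "*")
}

.count_one_orientation <- function(s1, unitChr, params, readId) {
    prof <- matchRunProfile(s1, unitChr, X = params@X)
    sm <- smoothProfile(prof, L = params@L)
    region <- findRepeatRegion(sm, params)
    mass <- if (region@found)
        sum(sm@values[(region@start + 1L):region@end]) else 0
    list(count = countRepeatsDFT(sm, region, m = prof@m, params = params,
                                 readId = readId),
         mass = mass)
}

#' Count repeat units in one read with the Fourier detector
#'
#' Runs the full pipeline — match-run profile, smoothing, dense-region
#' search, spectral counting — against both orientations of the repeat
#' unit and reports the orientation with the larger in-region profile
#' mass, so reads sequenced from either strand give the same count.
#'
#' @param read a single read (character, [Biostrings::DNAString] or
#'   length-1 [Biostrings::DNAStringSet]).
#' @param unit the repeat-unit reference ([RepeatUnit-class], character
#'   or [Biostrings::DNAString]).
#' @param params a [DetectorParams-class].
#' @param readId identifier stored in the result (defaults to the
#'   read's name when available).
#' @return a [CopyCount-class]; count 0 flagged `"no_repeat"` when no
#'   dense region exists in either orientation.
#' @examples
#' unit <- repeatUnit(randomDNA(100, seed = 1))
#' read <- paste0(randomDNA(50, seed = 2),
#'                strrep(as.character(unitSequence(unit)), 5),
#'                randomDNA(50, seed = 3))
#' copyCount(countRead(read, unit, detectorParams(L = 5L)))
#' @export
countRead <- function(read, unit, params = detectorParams(),
                      readId = NULL) {
    if (is.null(readId)) {
        readId <- if (!is.null(names(read))) names(read)[1L] else ""
    }
    s1 <- .seq_chr(read)
    uf <- .unit_chr(unit)
    ur <- as.character(reverseComplement(DNAString(uf)))
    fwd <- .count_one_orientation(s1, uf, params, readId)
    rev <- .count_one_orientation(s1, ur, params, readId)
    if (fwd$mass == 0 && rev$mass == 0) {
        res <- fwd$count
        res@flags <- unique(c(res@flags, "no_repeat"))
        return(res)
    }
    pick <- if (fwd$mass >= rev$mass) fwd else rev
    res <- pick$count
    res@orientation <- if (fwd$mass >= rev$mass) "+" else "-"
    res
}

#' Count repeat units across a set of reads
#'
#' Vectorised driver for [countRead()].
#'
#' @param reads a named [Biostrings::DNAStringSet] or character vector.
#' @param unit,params as in [countRead()].
#' @return a `data.frame` with one row per read: `readId`, `count`,
#'   `regionStart`, `regionEnd` (0-based half-open; `NA` when no region),
#'   `orientation`, `method`, `peakMagnitude`, `flags`.
#' @export
countReads <- function(reads, unit, params = detectorParams()) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    rows <- lapply(seq_along(reads), function(i) {
        cc <- countRead(reads[[i]], unit, params, readId = ids[i])
        data.frame(readId = ids[i], count = cc@count,
                   regionStart = if (cc@region@found) cc@region@start
                                 else NA_integer_,
                   regionEnd = if (cc@region@found) cc@region@end
                               else NA_integer_,
                   orientation = cc@orientation, method = cc@method,
                   peakMagnitude = cc@peakMagnitude,
                   flags = paste(cc@flags, collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
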