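#' @include tandemscope-package.R
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

## ---------------------------------------------------------------------------
## Reference sequences
## ---------------------------------------------------------------------------

#' RepeatUnit: a known repeat-unit reference sequence
#'
#' Holds the short, known reference sequence of one repeat unit
#' (for example the ~2.0-kb CUP1 unit). The sequence must be strictly
#' over the unambiguous DNA alphabet A/C/G/T: the match-run profile
#' compares literal nucleotides only, so ambiguity codes are rejected
#' here (while being tolerated, as never-matching positions, in reads).
#'
#' @slot id single character identifier.
#' @slot sequence a [Biostrings::DNAString] over A/C/G/T.
#'
#' @seealso [repeatUnit()], [unitLength()]
#' @exportClass RepeatUnit
setClass("RepeatUnit",
    representation(id = "character", sequence = "DNAString"))

setValidity("RepeatUnit", function(object) {
    msg <- character()
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@sequence) < 1L)
        msg <- c(msg, "'sequence' must be non-empty")
    af <- alphabetFrequency(object@sequence)
    if (sum(af[c("A", "C", "G", "T")]) != length(object@sequence))
        msg <- c(msg, "'sequence' may contain only A, C, G or T")
    if (length(msg)) msg else TRUE
})

#' Construct a RepeatUnit
#'
#' @param sequence a [Biostrings::DNAString], or a single character string,
#'   over A/C/G/T. Lower case is accepted and folded to upper case; U is
#'   mapped to T.
#' @param id identifier for the unit (default `"unit"`).
#' @return a [RepeatUnit-class] object.
#' @examples
#' u <- repeatUnit("ACGTACGT", id = "toy")
#' unitLength(u)
#' @export
repeatUnit <- function(sequence, id = "unit") {
    if (is.character(sequence))
        sequence <- DNAString(chartr("Uu", "Tt", toupper(sequence)))
    new("RepeatUnit", id = as.character(id), sequence = sequence)
}

#' @describeIn repeatUnit number of bases in the unit (the profile period m).
#' @param x a `RepeatUnit`.
#' @export
unitLength <- function(x) {
    stopifnot(is(x, "RepeatUnit"))
    length(x@sequence)
}

#' @describeIn repeatUnit the unit sequence as a [Biostrings::DNAString].
#' @export
unitSequence <- function(x) {
    stopifnot(is(x, "RepeatUnit"))
    x@sequence
}

setMethod("show", "RepeatUnit", function(object) {
    cat("RepeatUnit '", object@id, "': ", length(object@sequence),
        " bp\n", sep = "")
})

#' FlankPair: unique sequences bracketing a tandem array
#'
#' The ~1-kb unique sequences immediately upstream and downstream of the
#' array, used to recognise reads that span the whole array. Neither
#' flank may contain the repeat unit, so containment of both flanks in a
#' read implies the array between them is complete.
#'
#' @slot upstream,downstream [Biostrings::DNAString] objects, non-empty.
#' @seealso [flankPair()]
#' @exportClass FlankPair
setClass("FlankPair",
    representation(upstream = "DNAString", downstream = "DNAString"))

setValidity("FlankPair", function(object) {
    if (length(object@upstream) < 1L || length(object@downstream) < 1L)
        return("both flanks must be non-empty")
    TRUE
})

#' Construct a FlankPair
#'
#' @param upstream,downstream DNA sequences (character or
#'   [Biostrings::DNAString]) flanking the array.
#' @param unit optional [RepeatUnit-class]; when given, each flank is
#'   checked not to contain the unit as an exact substring.
#' @return a [FlankPair-class] object.
#' @export
flankPair <- function(upstream, downstream, unit = NULL) {
    if (is.character(upstream)) upstream <- DNAString(toupper(upstream))
    if (is.character(downstream)) downstream <- DNAString(toupper(downstream))
    fp <- new("FlankPair", upstream = upstream, downstream = downstream)
    if (!is.null(unit)) {
        u <- as.character(unitSequence(unit))
        if (grepl(u, as.character(upstream), fixed = TRUE) ||
            grepl(u, as.character(downstream), fixed = TRUE))
            stop("a flank contains the repeat unit as an exact substring")
    }
    fp
}

setMethod("show", "FlankPair", function(object) {
    cat("FlankPair: upstream ", length(object@upstream), " bp, downstream ",
        length(object@downstream), " bp\n", sep = "")
})

## ---------------------------------------------------------------------------
## Simulation types
## ---------------------------------------------------------------------------

#' ErrorModel: per-base read error rates
#'
#' Substitution, insertion and deletion probabilities applied
#' independently per template base, caricaturing an R9.4.1-era nanopore
#' error profile. Insertions add one uniform random base after the
#' template base; no homopolymer-aware structure is modelled.
#'
#' @slot subRate,insRate,delRate numeric probabilities in [0, 1] whose
#'   sum must be < 1.
#' @seealso [errorModel()]
#' @exportClass ErrorModel
setClass("ErrorModel",
    representation(subRate = "numeric", insRate = "numeric",
                   delRate = "numeric"))

setValidity("ErrorModel", function(object) {
    r <- c(object@subRate, object@insRate, object@delRate)
    if (length(r) != 3L || any(is.na(r)) || any(r < 0) || any(r > 1))
        return("rates must be single probabilities in [0, 1]")
    if (sum(r) >= 1)
        return("subRate + insRate + delRate must be < 1")
    TRUE
})

#' Construct an ErrorModel
#'
#' Defaults caricature an R9.4.1 nanopore read
#' (3\% substitutions, 2\% insertions, 3\% deletions; 8\% total).
#'
#' @param subRate,insRate,delRate per-base probabilities.
#' @return an [ErrorModel-class] object.
#' @examples
#' errorModel()            # nanopore-like default
#' errorModel(0, 0, 0)     # error-free
#' @export
errorModel <- function(subRate = 0.03, insRate = 0.02, delRate = 0.03) {
    new("ErrorModel", subRate = subRate, insRate = insRate,
        delRate = delRate)
}

setMethod("show", "ErrorModel", function(object) {
    cat(sprintf("ErrorModel: sub %.3f, ins %.3f, del %.3f (total %.3f)\n",
        object@subRate, object@insRate, object@delRate,
        object@subRate + object@insRate + object@delRate))
})

#' ArraySpec: blueprint of one tandem-array molecule
#'
#' Describes a molecule as upstream flank + `copyNumber` tandem copies of
#' the unit + downstream flank, with an optional cassette inserted at a
#' unit boundary (boundary index b means after the b-th unit, 0-based in
#' [0, copyNumber]) and optional partial-unit (interstitial) deletions.
#'
#' `unitDivergence` mutates the array's own unit once, before
#' concatenation, so that every copy carries the same deviations from the
#' reference unit. This emulates divergence between the sequenced strain
#' (or its systematic basecalls) and the reference, which is what imprints
#' a genuine per-unit periodicity on the match-run profile.
#'
#' @slot unit a [RepeatUnit-class].
#' @slot copyNumber integer >= 0.
#' @slot flanks a [FlankPair-class].
#' @slot cassette optional [Biostrings::DNAString] inserted at
#'   `cassetteBoundary`.
#' @slot cassetteBoundary integer in [0, copyNumber].
#' @slot deletions list of `c(unitIndex, startOffset, endOffset)` triples,
#'   0-based offsets within a unit, `start < end`, removing
#'   `unit[start, end)` from copy `unitIndex` (0-based).
#' @slot unitDivergence per-base substitution probability applied once to
#'   the array unit.
#' @seealso [arraySpec()], [buildArrayMolecule()]
#' @exportClass ArraySpec
setClass("ArraySpec",
    representation(unit = "RepeatUnit", copyNumber = "integer",
                   flanks = "FlankPair", cassette = "DNAStringOrNULL",
                   cassetteBoundary = "integer", deletions = "list",
                   unitDivergence = "numeric"))

setValidity("ArraySpec", function(object) {
    msg <- character()
    k <- object@copyNumber
    m <- length(object@unit@sequence)
    if (length(k) != 1L || is.na(k) || k < 0L)
        msg <- c(msg, "'copyNumber' must be a single integer >= 0")
    if (!is.null(object@cassette)) {
        b <- object@cassetteBoundary
        if (length(b) != 1L || is.na(b) || b < 0L || b > k)
            msg <- c(msg, "'cassetteBoundary' must lie in [0, copyNumber]")
    }
    for (d in object@deletions) {
        if (length(d) != 3L || anyNA(d)) {
            msg <- c(msg, "each deletion must be c(unitIndex, start, end)")
            next
        }
        if (d[1L] < 0 || d[1L] >= k)
            msg <- c(msg, "deletion 'unitIndex' must be in [0, copyNumber)")
        if (d[2L] < 0 || d[3L] > m || d[2L] >= d[3L])
            msg <- c(msg, "deletion offsets must satisfy 0 <= start < end <= m")
    }
    if (object@unitDivergence < 0 || object@unitDivergence > 1)
        msg <- c(msg, "'unitDivergence' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct an ArraySpec
#'
#' @param unit a [RepeatUnit-class].
#' @param copyNumber number of tandem unit copies (>= 0).
#' @param flanks a [FlankPair-class].
#' @param cassette optional cassette sequence (character or
#'   [Biostrings::DNAString]) inserted at a unit boundary.
#' @param cassetteBoundary 0-based unit boundary in [0, copyNumber] at
#'   which the cassette is inserted (`floor(copyNumber / 2)` places it at
#'   the array centre).
#' @param deletions list of `c(unitIndex, startOffset, endOffset)`
#'   partial-unit deletions (0-based, half-open within the unit).
#' @param unitDivergence per-base substitution rate applied once to the
#'   array's unit so that all copies share the same deviations from the
#'   reference (default 0).
#' @return an [ArraySpec-class] object.
#' @export
arraySpec <- function(unit, copyNumber, flanks, cassette = NULL,
                      cassetteBoundary = NA_integer_, deletions = list(),
                      unitDivergence = 0) {
    if (is.character(cassette)) cassette <- DNAString(toupper(cassette))
    if (!is.null(cassette) && is.na(cassetteBoundary))
        cassetteBoundary <- as.integer(copyNumber %/% 2L)
    new("ArraySpec", unit = unit, copyNumber = as.integer(copyNumber),
        flanks = flanks, cassette = cassette,
        cassetteBoundary = as.integer(cassetteBoundary),
        deletions = deletions, unitDivergence = as.numeric(unitDivergence))
}

setMethod("show", "ArraySpec", function(object) {
    cat("ArraySpec: ", object@copyNumber, " x ",
        length(object@unit@sequence), " bp unit",
        if (!is.null(object@cassette))
            sprintf(", cassette %d bp at boundary %d",
                    length(object@cassette), object@cassetteBoundary) else "",
        if (length(object@deletions))
            sprintf(", %d interstitial deletion(s)",
                    length(object@deletions)) else "",
        "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Detector types
## ---------------------------------------------------------------------------

#' DetectorParams: tuning constants of the repeat counter
#'
#' @slot X run-length threshold: vertical match runs shorter than `X`
#'   are zeroed in the profile. A 12-base exact run between unrelated
#'   sequences arises with probability ~4^-12 per cell, so the default 12
#'   suppresses background while tolerating nanopore error spacing.
#' @slot L smoothing half-window of the moving average; `NA` means
#'   `max(1, round(m / 20))` where `m` is the unit length.
#' @slot alpha dense-region threshold as a fraction of the profile
#'   maximum.
#' @slot gapTolerance largest internal gap (bases) bridged when growing
#'   the dense region; `NA` means `m`.
#' @slot bandLow,bandHigh multipliers of `|R| / m` bounding the spectral
#'   search band.
#' @slot peakProminence smallest ratio of the peak spectral power to the
#'   local in-band median power at which the peak is believed to be a
#'   true periodic line rather than a noise or leakage maximum.
#' @slot insertionGap unmatched stretches inside the region longer than
#'   this (bases; `NA` means `m / 10`) are treated as non-repeat
#'   insertions and excluded from the effective array length.
#' @seealso [detectorParams()], [countRead()]
#' @exportClass DetectorParams
setClass("DetectorParams",
    representation(X = "integer", L = "integer", alpha = "numeric",
                   gapTolerance = "numeric", bandLow = "numeric",
                   bandHigh = "numeric", peakProminence = "numeric",
                   insertionGap = "numeric"))

setValidity("DetectorParams", function(object) {
    msg <- character()
    if (object@X < 1L) msg <- c(msg, "'X' must be >= 1")
    if (!is.na(object@L) && object@L < 1L) msg <- c(msg, "'L' must be >= 1")
    if (object@alpha <= 0 || object@alpha >= 1)
        msg <- c(msg, "'alpha' must be in (0, 1)")
    if (object@bandLow >= 1 || object@bandHigh <= 1)
        msg <- c(msg, "'bandLow' must be < 1 < 'bandHigh'")
    if (object@peakProminence <= 1)
        msg <- c(msg, "'peakProminence' must be > 1")
    if (length(msg)) msg else TRUE
})

#' Construct detector parameters
#'
#' @param X run-length threshold (default 12).
#' @param L smoothing half-window; `NA` (default) means
#'   `max(1, round(m / 20))`, i.e. 100 for a 2-kb unit.
#' @param alpha dense-region threshold, fraction of the profile maximum
#'   (default 0.1).
#' @param gapTolerance gap bridged inside the dense region; `NA`
#'   (default) means one unit length.
#' @param bandLow,bandHigh spectral search band as multipliers of
#'   `|R| / m` (defaults 0.5 and 1.5).
#' @param peakProminence spectral line acceptance threshold
#'   (peak power over local median in-band power; default 50).
#' @param insertionGap non-repeat insertion gap threshold; `NA`
#'   (default) means `m / 10`.
#' @return a [DetectorParams-class] object.
#' @examples
#' detectorParams()
#' detectorParams(X = 15, alpha = 0.2)
#' @export
detectorParams <- function(X = 12L, L = NA_integer_, alpha = 0.1,
                           gapTolerance = NA_real_, bandLow = 0.5,
                           bandHigh = 1.5, peakProminence = 50,
                           insertionGap = NA_real_) {
    new("DetectorParams", X = as.integer(X), L = as.integer(L),
        alpha = alpha, gapTolerance = as.numeric(gapTolerance),
        bandLow = bandLow, bandHigh = bandHigh,
        peakProminence = peakProminence,
        insertionGap = as.numeric(insertionGap))
}

setMethod("show", "DetectorParams", function(object) {
    cat(sprintf(paste0("DetectorParams: X=%d, L=%s, alpha=%.2f, ",
                       "gapTolerance=%s, band=[%.2f, %.2f]\n"),
        object@X, ifelse(is.na(object@L), "m/20", object@L), object@alpha,
        ifelse(is.na(object@gapTolerance), "m",
               format(object@gapTolerance)),
        object@bandLow, object@bandHigh))
})

#' MatchRunProfile: thresholded match-run profile of a read
#'
#' The per-position vector `c` obtained by comparing a read against all
#' cyclic phase shifts of the periodic repeat-unit reference, replacing
#' vertical match runs by their lengths, zeroing runs shorter than `X`,
#' and summing across the read-length's worth of shifted columns.
#'
#' @slot profile numeric vector of length `n` (row sums; non-negative).
#' @slot n read length.
#' @slot m unit length.
#' @slot X run threshold used.
#' @seealso [matchRunProfile()], [literalMatrixProfile()]
#' @exportClass MatchRunProfile
setClass("MatchRunProfile",
    representation(profile = "numeric", n = "integer", m = "integer",
                   X = "integer"))

setValidity("MatchRunProfile", function(object) {
    if (length(object@profile) != object@n)
        return("'profile' length must equal n")
    if (any(object@profile < 0))
        return("'profile' entries must be non-negative")
    TRUE
})

#' @describeIn matchRunProfile extract the numeric profile vector.
#' @param x a `MatchRunProfile` or `SmoothedProfile`.
#' @export
profileVector <- function(x) {
    if (is(x, "MatchRunProfile")) return(x@profile)
    if (is(x, "SmoothedProfile")) return(x@values)
    stop("no profile vector in object of class ", class(x))
}

setMethod("show", "MatchRunProfile", function(object) {
    cat(sprintf(
        "MatchRunProfile: n=%d, m=%d, X=%d, %.1f%% positions > 0\n",
        object@n, object@m, object@X,
        100 * mean(object@profile > 0)))
})

#' SmoothedProfile: moving-average smoothed match-run profile
#'
#' @slot values numeric vector of length `n`: inside `[L, n-1-L]` the
#'   mean of the 2L+1 surrounding profile values, the raw profile at the
#'   edges.
#' @slot L half-window used.
#' @slot n,m as in [MatchRunProfile-class].
#' @seealso [smoothProfile()]
#' @exportClass SmoothedProfile
setClass("SmoothedProfile",
    representation(values = "numeric", L = "integer", n = "integer",
                   m = "integer"))

setMethod("show", "SmoothedProfile", function(object) {
    cat(sprintf("SmoothedProfile: n=%d, m=%d, L=%d\n",
        object@n, object@m, object@L))
})

#' RepeatRegion: dense interval of the profile harbouring the array
#'
#' 0-based half-open interval `[start, end)` into the profile. `found`
#' is `FALSE` for the distinguished "no repeat found" result (all-zero
#' or empty marking), in which case `start == end == 0`.
#'
#' @slot start,end integer interval bounds.
#' @slot found logical.
#' @seealso [findRepeatRegion()]
#' @exportClass RepeatRegion
setClass("RepeatRegion",
    representation(start = "integer", end = "integer", found = "logical"))

setValidity("RepeatRegion", function(object) {
    if (object@found && object@start >= object@end)
        return("a found region must satisfy start < end")
    TRUE
})

#' @describeIn findRepeatRegion width of the region in bases (0 when not
#'   found).
#' @param region a [RepeatRegion-class].
#' @export
regionWidth <- function(region) {
    stopifnot(is(region, "RepeatRegion"))
    if (!region@found) 0L else region@end - region@start
}

setMethod("show", "RepeatRegion", function(object) {
    if (object@found)
        cat(sprintf("RepeatRegion: [%d, %d) (%d bp)\n",
            object@start, object@end, object@end - object@start))
    else cat("RepeatRegion: none found\n")
})

#' CopyCount: a per-read repeat unit count with its evidence
#'
#' @slot count non-negative integer unit count.
#' @slot peakMagnitude spectral magnitude at the reported peak (0 when
#'   the spectrum was uninformative).
#' @slot band integer two-vector, the spectral band searched.
#' @slot method `"dft"` when the count came from an accepted spectral
#'   line, `"coverage"` when it came from the dense-coverage length,
#'   `"single"` for the short-region single-copy rule, `"dotplot"` for
#'   diagonal counting, `"none"` when no repeat was found.
#' @slot readId read identifier.
#' @slot flags character vector of condition flags (e.g. `"no_repeat"`).
#' @slot region the [RepeatRegion-class] used.
#' @slot orientation `"+"`, `"-"` or `"*"` (undetermined).
#' @seealso [countRead()]
#' @exportClass CopyCount
setClass("CopyCount",
    representation(count = "integer", peakMagnitude = "numeric",
                   band = "integer", method = "character",
                   readId = "character", flags = "character",
                   region = "RepeatRegion", orientation = "character"))

setMethod("show", "CopyCount", function(object) {
    cat(sprintf("CopyCount: %d unit(s) [%s, strand %s%s]\n",
        object@count, object@method, object@orientation,
        if (length(object@flags))
            paste0(", flags: ", paste(object@flags, collapse = ","))
        else ""))
})

#' @describeIn countRead the integer unit count in a
#'   [CopyCount-class].
#' @param x a `CopyCount`.
#' @export
copyCount <- function(x) {
    stopifnot(is(x, "CopyCount"))
    x@count
}
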