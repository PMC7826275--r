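#' @include AllClasses.R
NULL

## coerce read-like / unit-like input to a plain uppercase character string
.seq_chr <- function(x) {
    if (is(x, "RepeatUnit")) x <- x@sequence
    if (is(x, "DNAString") || is(x, "DNAStringSet") || is(x, "BString") ||
        is(x, "BStringSet")) {
        x <- as.character(x)
        if (length(x) != 1L)
            stop("expected a single sequence, got ", length(x))
        return(x)
    }
    if (is.character(x) && length(x) == 1L)
        return(chartr("Uu", "Tt", toupper(x)))
    stop("cannot interpret object of class ", class(x)[1L],
         " as a single DNA sequence")
}

.unit_chr <- function(unit) {
    u <- .seq_chr(unit)
    if (!grepl("^[ACGT]+$", u))
        stop("the repeat unit must contain only A, C, G or T")
    u
}

#' Match-run profile of a read against a periodic repeat unit
#'
#' Computes the per-position profile `c` at the heart of the Fourier
#' repeat counter. Conceptually, an `n x n` matrix is built whose column
#' `j` holds the repeat unit shifted down by `j` and wrapped periodically
#' (`a[i, j] = r[(i - j) mod m]`); cells equal to the read base become 1
#' and all others 0; within each column, consecutive runs of 1s are
#' replaced by the run length; values below `X` are zeroed; and `c[i]` is
#' the row sum. Because columns repeat with period `m`, the efficient
#' implementation evaluates each distinct phase once and weights it by
#' its column multiplicity, which makes it exactly — not just
#' proportionally — equal to the literal construction.
#'
#' Runs of at least `X` exact matches are very unlikely between unrelated
#' sequences (probability about `4^-X` per cell) but common between a
#' read and the repeat unit it derives from, even at nanopore error
#' rates, so the profile is near zero outside the array and large inside
#' it.
#'
#' @param read a single read: character string, [Biostrings::DNAString],
#'   or length-1 [Biostrings::DNAStringSet]. Ambiguity codes (e.g. N)
#'   never match.
#' @param unit the repeat-unit reference: a [RepeatUnit-class], character
#'   string or [Biostrings::DNAString] over A/C/G/T.
#' @param X run-length threshold (>= 1).
#' @return a [MatchRunProfile-class].
#' @seealso [literalMatrixProfile()] for the direct matrix construction
#'   (small inputs only), [smoothProfile()], [countRead()].
#' @examples
#' p <- matchRunProfile(strrep("ACGTT", 8), "ACGTT", X = 5)
#' profileVector(p)[1:10]
#' @export
matchRunProfile <- function(read, unit, X = 12L) {
    s1 <- .seq_chr(read)
    s2 <- .unit_chr(unit)
    X <- as.integer(X)
    prof <- .match_run_profile_cpp(s1, s2, X)
    new("MatchRunProfile", profile = prof, n = nchar(s1),
        m = nchar(s2), X = X)
}

#' Literal matrix construction of the match-run profile
#'
#' Materialises the full `n x n` matrix of wrapped, shifted unit copies
#' and carries out the binarisation, vertical run-length relabelling,
#' thresholding and row summation step by step. This is the reference
#' oracle for [matchRunProfile()]: slower and memory-hungry, but a
#' direct transcription of the definition. Inputs are limited to reads
#' of 2,000 bases.
#'
#' @inheritParams matchRunProfile
#' @return a [MatchRunProfile-class] identical to the one returned by
#'   [matchRunProfile()] on the same input.
#' @export
literalMatrixProfile <- function(read, unit, X = 12L) {
    s1 <- .seq_chr(read)
    s2 <- .unit_chr(unit)
    n <- nchar(s1)
    m <- nchar(s2)
    X <- as.integer(X)
    if (n > 2000L)
        stop("literalMatrixProfile materialises an n x n matrix and is ",
             "limited to n <= 2000; use matchRunProfile() instead")
    if (n == 0L)
        return(new("MatchRunProfile", profile = numeric(0), n = 0L,
                   m = m, X = X))
    s <- strsplit(s1, "", fixed = TRUE)[[1L]]
    r <- strsplit(s2, "", fixed = TRUE)[[1L]]
    i <- matrix(0:(n - 1L), nrow = n, ncol = n)
    j <- matrix(0:(n - 1L), nrow = n, ncol = n, byrow = TRUE)
    M <- matrix(r[((i - j) %% m) + 1L], nrow = n)      # shifted wrapped unit
    M2 <- (M == s) * 1L                                # binarise vs read base
    M3 <- apply(M2, 2L, function(col) {                # vertical run lengths
        rl <- rle(col)
        rep.int(rl$lengths * rl$values, rl$lengths)
    })
    M3 <- matrix(M3, nrow = n)
    M4 <- M3 * (M3 >= X)                               # threshold at X
    new("MatchRunProfile", profile = as.numeric(rowSums(M4)),
        n = n, m = m, X = X)
}

#' Smooth a match-run profile with a centred moving average
#'
#' Produces the smoothed vector used by the region finder and the
#' Fourier counter: inside `[L, n - 1 - L]` each entry is the mean of
#' the `2L + 1` surrounding raw values; the first and last `L` entries
#' copy the raw profile through unchanged.
#'
#' @param profile a [MatchRunProfile-class].
#' @param L half-window; `NA` (default) uses `max(1, round(m / 20))`,
#'   wide enough to bridge error-induced dropouts yet much narrower than
#'   one unit, so per-unit structure survives.
#' @return a [SmoothedProfile-class].
#' @export
smoothProfile <- function(profile, L = NA_integer_) {
    stopifnot(is(profile, "MatchRunProfile"))
    if (is.na(L)) L <- max(1L, as.integer(round(profile@m / 20)))
    L <- as.integer(L)
    n <- profile@n
    if (2L * L + 1L > n)
        stop("smoothing window 2L+1 = ", 2L * L + 1L,
             " exceeds profile length ", n)
    cc <- profile@profile
    v <- as.numeric(stats::filter(cc, rep(1 / (2 * L + 1), 2L * L + 1L),
                                  sides = 2))
    edge <- is.na(v)
    v[edge] <- cc[edge]
    new("SmoothedProfile", values = v, L = L, n = n, m = profile@m)
}
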