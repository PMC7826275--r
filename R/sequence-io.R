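#' @include AllClasses.R
NULL

.guess_format <- function(path) {
    f <- sub("\\.(gz|bgz)$", "", basename(path))
    if (grepl("\\.(fastq|fq)$", f, ignore.case = TRUE)) "fastq" else "fasta"
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around \pkg{Biostrings} parsers that returns reads the
#' way the rest of the package expects them: a [Biostrings::DNAStringSet]
#' with upper-case sequences, U mapped to T, names taken from the record
#' headers, and (for FASTQ) the quality strings kept in
#' `mcols(x)$quality`. Gzip-compressed files are accepted transparently.
#'
#' @param path input file.
#' @param format `"auto"` (default; decided from the file extension),
#'   `"fasta"` or `"fastq"`.
#' @return a [Biostrings::DNAStringSet]; zero-length, with a warning,
#'   for an empty file.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeSeqs(Biostrings::DNAStringSet(c(a = "ACGT", b = "GGCC")), tf)
#' readSeqs(tf)
#' @export
readSeqs <- function(path, format = c("auto", "fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") format <- .guess_format(path)
    raw <- readBStringSet(path, format = format,
                          with.qualities = (format == "fastq"))
    if (length(raw) == 0L) {
        warning("no sequences in ", path)
        return(DNAStringSet())
    }
    seqs <- chartr("Uu", "Tt", toupper(as.character(raw)))
    out <- DNAStringSet(seqs)
    names(out) <- sub("\\s.*$", "", names(raw))
    if (format == "fastq") {
        qual <- as.character(mcols(raw)$qualities)
        if (any(nchar(qual) != nchar(seqs)))
            stop("FASTQ quality string length differs from sequence ",
                 "length for record ",
                 names(out)[which(nchar(qual) != nchar(seqs))[1L]])
        mcols(out)$quality <- qual
    }
    out
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a [Biostrings::DNAStringSet] (named). For FASTQ output,
#'   per-read quality strings are taken from `mcols(x)$quality` when
#'   present, otherwise a constant Phred quality of `defaultQuality` is
#'   written.
#' @param path output file; a `.gz` suffix triggers compression.
#' @param format `"auto"` (from the extension), `"fasta"` or `"fastq"`.
#' @param defaultQuality single Phred score used when no qualities are
#'   attached (default 20).
#' @return the path, invisibly.
#' @export
writeSeqs <- function(x, path, format = c("auto", "fasta", "fastq"),
                      defaultQuality = 20L) {
    format <- match.arg(format)
    if (format == "auto") format <- .guess_format(path)
    compress <- grepl("\\.gz$", path)
    if (format == "fasta") {
        writeXStringSet(x, path, format = "fasta", compress = compress)
    } else {
        qual <- mcols(x)$quality
        if (is.null(qual))
            qual <- vapply(width(x), function(w)
                paste(rep(rawToChar(as.raw(defaultQuality + 33L)), w),
                      collapse = ""), character(1))
        qx <- QualityScaledDNAStringSet(x, PhredQuality(qual))
        writeXStringSet(qx, path, format = "fastq", compress = compress,
                        qualities = quality(qx))
    }
    invisible(path)
}

#' Write a list of keyed records as a TSV table
#'
#' All rows must share one key set; the column order of the first row is
#' used for the whole file, so output is deterministic. Fields
#' containing a tab, newline or carriage return are rejected rather than
#' silently escaped (the dialect is plain unquoted TSV).
#'
#' @param rows a `data.frame`, or a list of named lists/vectors with
#'   identical key sets.
#' @param path output file.
#' @return the path, invisibly. An empty row list yields a header-only
#'   file when `rows` is a zero-row data.frame, or an empty file for an
#'   empty list (no keys are known).
#' @export
writeTable <- function(rows, path) {
    if (is.data.frame(rows)) {
        df <- rows
    } else {
        if (length(rows) == 0L) {
            file.create(path)
            return(invisible(path))
        }
        keys <- names(rows[[1L]])
        if (is.null(keys) || any(!nzchar(keys)))
            stop("rows must have named fields")
        for (i in seq_along(rows)) {
            ki <- names(rows[[i]])
            if (!identical(sort(ki), sort(keys)))
                stop("row ", i, " has keys {",
                     paste(ki, collapse = ","),
                     "} but the first row has {",
                     paste(keys, collapse = ","), "}")
        }
        df <- do.call(rbind, lapply(rows, function(r)
            as.data.frame(as.list(r[keys]), stringsAsFactors = FALSE)))
    }
    chr <- vapply(df, is.character, logical(1))
    for (cn in names(chr)[chr]) {
        bad <- grepl("[\t\n\r]", df[[cn]])
        if (any(bad))
            stop("field '", cn, "' of row ", which(bad)[1L],
                 " contains a tab or newline; the TSV dialect is ",
                 "unquoted and cannot represent it")
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a TSV table written by [writeTable()]
#'
#' @param path input file.
#' @return a `data.frame`.
#' @export
readTable <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
}
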