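# shared fixture builders: everything is generated in code, seeded

tsUnit <- function(m = 100, seed = 1, id = "unit")
    randomUnit(m, id = id, seed = seed)

tsFlanks <- function(len = 60, seedUp = 2, seedDown = 3, unit = NULL)
    flankPair(randomDNA(len, seed = seedUp),
              randomDNA(len, seed = seedDown), unit = unit)

revcompChr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# an error model with the default 3:2:3 sub:ins:del mix scaled to a
# given total per-base error rate
scaledErrorModel <- function(total) {
    if (total == 0) return(errorModel(0, 0, 0))
    errorModel(subRate = total * 3 / 8, insRate = total * 2 / 8,
               delRate = total * 3 / 8)
}

# brute-force all-pairs k-mer scan (quadratic oracle for kmerMatches)
bruteKmerMatches <- function(read, ref, k) {
    rk <- substring(read, seq_len(nchar(read) - k + 1),
                    seq_len(nchar(read) - k + 1) + k - 1)
    fk <- substring(ref, seq_len(nchar(ref) - k + 1),
                    seq_len(nchar(ref) - k + 1) + k - 1)
    rcf <- revcompChr(ref)
    fkrc <- substring(rcf, seq_len(nchar(rcf) - k + 1),
                      seq_len(nchar(rcf) - k + 1) + k - 1)
    out <- list()
    for (i in seq_along(rk)) {
        for (j in which(fk == rk[i]))
            out[[length(out) + 1L]] <- data.frame(
                readPos = i - 1L, refPos = j - 1L, strand = "+",
                stringsAsFactors = FALSE)
        for (j in which(fkrc == rk[i]))
            out[[length(out) + 1L]] <- data.frame(
                readPos = i - 1L, refPos = nchar(ref) - k - (j - 1L),
                strand = "-", stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(readPos = integer(0), refPos = integer(0),
                          strand = character(0), stringsAsFactors = FALSE))
    df <- do.call(rbind, out)
    df[order(df$readPos, df$refPos, df$strand), , drop = FALSE]
}
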