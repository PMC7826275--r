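#' @include AllClasses.R
NULL

#' Summarise per-read copy numbers across a population
#'
#' Aggregates spanning-read unit counts into the population view: the
#' arithmetic mean copy number, a histogram of counts, and optionally a
#' seeded percentile bootstrap confidence interval for the mean. The
#' caller is expected to pass counts from spanning reads only.
#'
#' @param counts an integer/numeric vector of per-read unit counts, a
#'   list of [CopyCount-class] objects, or the `data.frame` returned by
#'   [countReads()] (its `count` column is used).
#' @param bootstrap number of bootstrap resamples for a CI of the mean
#'   (0, the default, for none).
#' @param conf confidence level for the bootstrap interval.
#' @return a list: `n`, `mean`, `histogram` (a table of counts per copy
#'   number, summing to `n`), and when requested `ciLow`/`ciHigh`.
#'   Empty input gives `n = 0`, `mean = NaN` and a `"empty"` flag.
#' @examples
#' summarizePopulation(c(16, 16, 16))$mean          # 16
#' summarizePopulation(c(1, 1, 19, 28))$histogram
#' @export
summarizePopulation <- function(counts, bootstrap = 0L, conf = 0.95) {
    if (is.data.frame(counts)) counts <- counts$count
    if (is.list(counts))
        counts <- vapply(counts, function(x)
            if (is(x, "CopyCount")) x@count else as.integer(x),
            integer(1))
    counts <- as.integer(counts)
    out <- list(n = length(counts), mean = mean(counts),
                histogram = table(counts), flags = character())
    if (length(counts) == 0L) {
        out$flags <- "empty"
        return(out)
    }
    if (bootstrap > 0L) {
        bm <- vapply(seq_len(bootstrap), function(i)
            mean(sample(counts, replace = TRUE)), numeric(1))
        qs <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                              names = FALSE)
        out$ciLow <- qs[1L]
        out$ciHigh <- qs[2L]
    }
    out
}

#' Cell divisions from daily optical density measurements
#'
#' With daily dilution culture, the number of divisions in one day is
#' `log2(odEnd / odStart)` (each doubling of absorbance is one
#' division); the total over the interval is the sum over days.
#'
#' @param odStart OD600 right after each day's dilution.
#' @param odEnd OD600 at the end of the same day. Both may also be
#'   supplied as a two-column `data.frame` in `odStart`.
#' @return total number of divisions.
#' @examples
#' divisionsFromOD(0.05, 0.8)           # 4 divisions
#' divisionsFromOD(c(0.05, 0.05), c(0.4, 0.4))  # 6
#' @export
divisionsFromOD <- function(odStart, odEnd = NULL) {
    if (is.data.frame(odStart) || is.matrix(odStart)) {
        odEnd <- odStart[[2L]]
        odStart <- odStart[[1L]]
    }
    if (length(odStart) != length(odEnd))
        stop("'odStart' and 'odEnd' must have equal length")
    if (any(odStart <= 0) || any(odEnd <= 0))
        stop("OD values must be positive")
    sum(log2(odEnd / odStart))
}

#' Variation index: percent copy-number change per cell division
#'
#' `vi = 100 * (cStart - cEnd) / cStart / divisions`. The sign
#' convention makes array contraction positive, so strains that lose
#' repeat copies faster have a larger index.
#'
#' @param cStart,cEnd copy numbers at the start and end of the
#'   interval (`cStart > 0`).
#' @param divisions number of cell divisions over the interval (> 0),
#'   e.g. from [divisionsFromOD()].
#' @return a `data.frame` with columns `cStart`, `cEnd`, `divisions`,
#'   `vi` (percent per division). Vectorised over its arguments.
#' @examples
#' variationIndex(20, 18, 5)$vi  # 2
#' @export
variationIndex <- function(cStart, cEnd, divisions) {
    if (any(cStart <= 0)) stop("'cStart' must be positive")
    if (any(divisions <= 0)) stop("'divisions' must be positive")
    data.frame(cStart = cStart, cEnd = cEnd, divisions = divisions,
               vi = 100 * (cStart - cEnd) / cStart / divisions)
}

#' Copy number from qPCR quantities calibrated against sequencing
#'
#' Relative target quantity is normalised to the single-copy reference
#' gene (ACT1) and scaled by a calibration factor chosen so that a
#' reference sample reproduces its sequencing-determined copy number.
#'
#' @param targetQuantity relative quantity of the repeat target.
#' @param act1Quantity relative quantity of the ACT1 reference (> 0).
#' @param calibration copies per unit of the target/ACT1 ratio.
#' @return estimated copy number (vectorised).
#' @examples
#' qpcrCopyNumber(1, 1, 16)    # 16
#' qpcrCopyNumber(0.5, 1, 16)  # 8
#' @export
qpcrCopyNumber <- function(targetQuantity, act1Quantity, calibration) {
    if (any(act1Quantity <= 0))
        stop("'act1Quantity' must be positive")
    if (any(targetQuantity < 0) || any(calibration <= 0))
        stop("quantities must be non-negative and calibration positive")
    targetQuantity / act1Quantity * calibration
}

#' Marker-loss colony-count assay
#'
#' Bundles the plate counts of a 5-FOA-type marker-loss experiment:
#' colonies on the selective plate and on the permissive plate, each
#' with the dilution factor of the plated suspension (expressed so that
#' `cfu * dilution` is proportional to cells per volume of the original
#' culture).
#'
#' @param resistantCfu,totalCfu colony counts (>= 0; `totalCfu` > 0).
#' @param resistantDilution,totalDilution dilution factors (> 0).
#' @return a list of class `"foaAssay"`.
#' @export
foaAssay <- function(resistantCfu, totalCfu, resistantDilution = 1,
                     totalDilution = 1) {
    if (totalCfu <= 0) stop("'totalCfu' must be positive")
    if (resistantCfu < 0) stop("'resistantCfu' must be >= 0")
    if (resistantDilution <= 0 || totalDilution <= 0)
        stop("dilutions must be positive")
    structure(list(resistantCfu = resistantCfu, totalCfu = totalCfu,
                   resistantDilution = resistantDilution,
                   totalDilution = totalDilution), class = "foaAssay")
}

#' Frequency of marker loss relative to a control strain
#'
#' The frequency of resistant clones is the dilution-corrected ratio of
#' resistant to total colony-forming units; the fold change is the
#' ratio of the test frequency to the control frequency.
#'
#' @param assay,control [foaAssay()] objects for the test and control
#'   strains.
#' @return a list: `frequency`, `controlFrequency`, `fold` (`NA` with a
#'   `"zero_control"` flag when the control frequency is zero and the
#'   test frequency is not), `flags`.
#' @examples
#' markerLossFrequency(foaAssay(50, 100), foaAssay(1, 1000))$fold
#' @export
markerLossFrequency <- function(assay, control) {
    stopifnot(inherits(assay, "foaAssay"), inherits(control, "foaAssay"))
    freq <- function(a)
        (a$resistantCfu * a$resistantDilution) /
        (a$totalCfu * a$totalDilution)
    fa <- freq(assay)
    fc <- freq(control)
    flags <- character()
    fold <- if (fc > 0) fa / fc
            else if (fa == 0) 0
            else { flags <- "zero_control"; NA_real_ }
    list(frequency = fa, controlFrequency = fc, fold = fold,
         flags = flags)
}
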