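---
title: "Counting tandem repeat units in long reads"
author: "tandemscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting tandem repeat units in long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Macrosatellite arrays — loci where a unit of a kilobase or more is
iterated head-to-tail tens of times, such as the ~2.0-kb *CUP1* repeat
of budding yeast — change their copy number by recombination between
units. Short reads cannot resolve an individual array, and qPCR only
reports a population average. A single long (nanopore) read that spans
the whole array, however, carries the complete structure of one
molecule: the number of unit copies, insertions such as a selection
cassette, and interstitial (partial-unit) deletions.

`tandemscope` measures repeat copy number per read and aggregates the
results into population statistics. It provides two independent
counters — a match-run-profile / Fourier detector and a k-mer dot-plot
diagonal counter — plus spanning-read selection, a read simulator with
ground truth, and the downstream instability statistics (variation
index, qPCR calibration, marker-loss frequency).

# The match-run profile

Let the read be $s_0 s_1 \ldots s_{n-1}$ and the repeat-unit reference
$r_0 r_1 \ldots r_{m-1}$, both over A/C/G/T (ambiguity codes in reads
never match; they are rejected in the unit). Conceptually an
$n \times n$ matrix is formed whose column $j$ is the unit shifted down
by $j$ and wrapped periodically,

$$a_{i,j} = r_{(i-j) \bmod m},$$

so every possible phase alignment between read and periodic unit is
represented. Cells with $a_{i,j} = s_i$ become 1, all others 0. Within
each column, a run of $k$ consecutive 1s is replaced by the value $k$;
values below a threshold $X$ are then zeroed; and the profile is the
row sum $c_i = \sum_j b_{i,j}$.

Columns $j$ and $j+m$ are identical, so the implementation (Rcpp)
evaluates each of the $m$ distinct phases once and weighs it by its
column multiplicity $\lfloor n/m\rfloor + [\,j \bmod m < n \bmod m\,]$.
This makes the fast path *exactly* equal to the literal matrix
construction, which the package also ships
(`literalMatrixProfile()`, reads up to 2 kb) as an oracle; the test
suite asserts equality on hundreds of random instances.

Why runs? A run of $X$ exact matches between unrelated sequences occurs
with probability about $4^{-X}$ per cell, while a read drawn from the
array matches its unit in runs whose typical length is the inverse
error rate (10–15 bases for nanopore data). The default $X = 12$
therefore suppresses background to essentially zero while keeping most
of the in-array signal. The profile is smoothed with a centred moving
average of half-window $L$ (`smoothProfile()`; edges copy the raw
profile through); the default $L = m/20$ (100 bases for a 2-kb unit)
bridges error dropouts yet is far narrower than one unit, so per-unit
structure survives.

```{r profile-demo}
library(tandemscope)
unit <- randomUnit(200, seed = 1)
fp <- flankPair(randomDNA(150, seed = 2), randomDNA(150, seed = 3), unit)
mol <- buildArrayMolecule(arraySpec(unit, 5, fp))
prof <- matchRunProfile(mol$sequence, unit, X = 12)
summary(profileVector(prof)[150:1150])  # large inside the array
```

# Locating the array and counting units

`findRepeatRegion()` marks positions whose smoothed profile exceeds
`alpha` times the profile maximum (default 0.1) and merges marked
blocks across gaps up to `gapTolerance` (default one unit length, so a
cassette insertion does not split the region); the longest merged block
wins, leftmost on ties. An all-zero profile yields a distinguished
"not found" value rather than an error.

`countRepeatsDFT()` then estimates the number of units in the region
$R$. Two estimates are formed:

* **Spectral line.** The smoothed profile over $R$, mean-subtracted and
  Hann-windowed, is Fourier transformed; the magnitude spectrum is
  searched in the band $[0.5\,|R|/m,\ 1.5\,|R|/m]$ (excluding DC). The
  Hann window matters: the region's rectangular envelope otherwise
  leaks enough low-frequency power to swamp the band. The in-band peak
  is accepted only when it is a decisive line — its power at least
  `peakProminence` (default 50) times the local in-band median — at a
  frequency above the envelope-leakage bins (a fundamental below bin 4
  is never trusted: even after windowing, the region's own shape
  concentrates residual power there, so short arrays are always counted
  by coverage), and whose quadratically interpolated frequency agrees
  with the coverage estimate below to within one unit
  (fundamental/harmonic confusions are the classic failure of
  peak-picking a periodic but non-sinusoidal signal).
* **Dense coverage.** The effective array length — the region length
  minus any gap that is both long (`insertionGap`, default $m/10$) and
  deep (mean smoothed profile below $0.25\,\alpha \cdot \max$) —
  divided by $m$ and rounded half away from zero. The long-and-deep
  rule distinguishes true non-repeat insertions (a cassette, with
  essentially zero profile) from shallow error dropouts hovering just
  below the marking threshold, which must not shorten the array.

When is there a real spectral line? Per-unit periodicity in the
profile comes from mismatches that recur at the same offset in *every*
copy: divergence between the sequenced strain and the reference unit,
or systematic (sequence-dependent) basecalling errors. Errors drawn
independently per base — as in this package's simulator — break runs
aperiodically and leave *no* period-$m$ line at all, only smooth noise
whose in-band maximum would masquerade as a count. The prominence gate
plus the coverage anchor therefore routes i.i.d.-noise reads to the
robust coverage estimate, while reads with genuine copy-consistent
structure are counted from the line. The generator's `unitDivergence`
option creates exactly this structure (the array's unit is mutated once
and then iterated), and the test suite uses it to exercise the spectral
branch end to end.

Two special cases: a region shorter than $1.5\,m$ is reported as a
single copy (a one-period signal has no usable fundamental, and real
populations do contain single-copy arrays), and a perfectly flat
spectrum falls back to region length over unit length.

`countRead()` runs the whole pipeline against both orientations of the
unit and reports the orientation with the larger in-region profile
mass, so counts are strand-invariant.

```{r count-demo}
cc <- countRead(mol$sequence, unit)
cc
```

# The dot-plot counter

`dotplotCount()` is the automated version of counting diagonal lines in
a dot plot of a read against the unit: exact k-mer matches (default
$k = 13$, both strands) are chained while the diagonal offset drifts at
most $0.1\,m$ (absorbing indels) and read gaps stay below $0.2\,m$;
chains with fewer than 5 seeds are dropped. A segment covering at
least 80% of the unit (`fullFraction`) is one full copy; shorter
segments are partial units — the signature of interstitial deletions.
A cassette is located by its own diagonal segment, and its boundary
index is the number of full units entirely on the array-upstream side.

The two counters are deliberately different in kind (spatial chaining
versus profile periodicity/coverage) and agree exactly on error-free
full-unit arrays; with a partial-unit deletion they may legitimately
differ by one, since the Fourier counter rounds the missing fraction
while the dot plot reports it as a partial segment.

# Spanning-read selection

Only reads containing both unique 1-kb flanks bracket a complete
array. `classifySpanning()` seeds each flank into the read with 15-mers,
chains seeds on near-constant diagonals, re-aligns each candidate
locally (match +1, mismatch −1, gap −1, via
`Biostrings::pairwiseAlignment`), and accepts hits with identity
≥ 0.75 covering ≥ 0.5 of the flank — thresholds chosen for ~10%
read error and exposed as arguments. A read spans when both flanks hit
on the same strand in array order (a reverse-complemented read presents
the downstream flank first); the interval between the inner flank edges
is the array interval, legitimately empty for a zero-copy array.

Note one boundary property of the truth definition: the simulator marks
a read spanning only when its window covers both flanks *completely*,
while the classifier accepts a flank at 50% coverage. Reads whose end
falls inside the outer half of a flank can therefore be called spanning
against a false truth flag. Under realistic read-length mixtures such
ends are rare (a few hundred bases of ambiguous space against
tens of kilobases of molecule), which is why classification still
agrees with truth on far more than 95% of simulated reads.

# The simulator

`buildArrayMolecule()` assembles flank + $k$ unit copies (cassette at a
unit boundary, partial-unit deletions applied) + flank, and returns a
ground-truth record. `simulateRead()` applies per-base substitutions,
single-base insertions and deletions (defaults 3%/2%/3%, caricaturing
an R9.4.1-era nanopore read) and draws the strand uniformly.
`simulatePopulation()` mixes molecules by weight, draws read lengths
from a log-normal (default meanlog $\log 8000$, sdlog 0.6, the shape of
a ligation-prep run; neither value is a claim about any particular
dataset) and places windows uniformly, so longer arrays — requiring
longer reads to span — are underrepresented among spanning reads, the
same bias the real protocol has.

What the simulator does *not* emulate: signal-level (squiggle) noise,
homopolymer-biased or otherwise sequence-dependent errors,
chimeric/split reads, extrachromosomal circles, aneuploidy. Passing
tests therefore show robustness to error *rate*, not to every error
*structure* of real data; the `unitDivergence` option recovers one
important real-data structure (copy-consistent mismatches), and the
detector's design explicitly does not rely on structures the simulator
lacks. Reproducibility follows the R convention: a `seed` argument on
the population/sequence generators, the session RNG elsewhere.

# Population statistics

* `summarizePopulation()`: mean and histogram of spanning-read counts,
  optional seeded percentile bootstrap CI of the mean (B configurable;
  a convenience, not an inference framework).
* `divisionsFromOD()`: divisions per day $= \log_2(\mathrm{OD}_{end} /
  \mathrm{OD}_{start})$, summed over days of a daily-dilution culture.
* `variationIndex()`: $\mathrm{VI} = 100\,(c_{start} - c_{end}) /
  c_{start} / \mathrm{divisions}$ — percent copy-number change per
  division. The sign convention makes contraction positive, so strains
  losing copies faster have larger VI; this matches how contracting
  strains are usually tabulated.
* `qpcrCopyNumber()`: target quantity normalised to the single-copy
  reference (ACT1) and scaled by a calibration chosen so a reference
  sample reproduces its sequencing-determined copy number.
* `markerLossFrequency()`: dilution-corrected resistant-colony
  frequency and its fold change over a control assay; a zero-frequency
  control yields a flagged `NA` fold rather than an error. Published
  fold changes computed from unrounded raw counts generally cannot be
  reconstructed from rounded percentages, so only the arithmetic is
  asserted, never a particular fold value.

# Numerical choices and conventions

* Coordinates are 0-based, half-open throughout the API; strand `"+"`
  is the as-read orientation. (Biostrings' 1-based coordinates are
  converted at the boundary.)
* Ties in region search and hit pairing break towards the leftmost
  candidate; rounding of count estimates is half away from zero. Both
  choices are for determinism.
* The profile is returned as doubles: on pathological low-complexity
  input row sums can exceed integer range.
* `literalMatrixProfile()` enforces $n \le 2000$; the fast path has no
  limit and costs $O(nm)$ time, about a second for a 60-kb read against
  a 2-kb unit per orientation.

# Problem sizes used by the test suite

The suite validates the counters at the study scale — copy numbers 1–30
of a 2-kb unit between 1-kb flanks, 20 seeded reads per copy number at
8% total error, 200 reads for spanning classification — and uses
smaller units (100–1000 bases) for module-level tests, chosen so the
whole suite completes in minutes on one CPU. The acceptance script
rebuilds the 16-unit cassette-bearing parental architecture from seeded
random sequences and recounts it from scratch.

# Known limitations

* Counts assume a single repeat family per read; nested or interleaved
  repeat families are out of scope.
* The Fourier counter reports integer unit counts; it does not call
  breakpoints at base resolution, and an interstitial deletion shows up
  only as a count difference or as dot-plot partial segments.
* The coverage estimate divides read-space length by the reference unit
  length; at indel-heavy error profiles the systematic read-space
  contraction (about $1 + p_{ins} - p_{del}$) eats into the rounding
  margin at very high copy numbers (beyond ~45 at the default rates).
* Flank selection needs genuinely unique flanks; flanks sharing k-mers
  with the unit are rejected at construction where detectable.
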