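---
title: "Discovering candidate EMAST loci and calling tumor instability"
author: "emastscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering candidate EMAST loci and calling tumor instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(emastscan)
  library(GenomicRanges)
})
```

## The problem

EMAST — Elevated Microsatellite Alterations at Selected Tetranucleotide
repeats — is a form of microsatellite instability observed in colorectal
and several other cancers: at particular tetranucleotide loci (AAAG/CTTT
being the most commonly assayed unit) the number of repeat units in tumor
DNA differs from the matched normal tissue of the same individual.  Only
*selected* tetranucleotide loci behave this way, and the selection is not
explained by repeat length alone; the 25 nucleotides flanking a tract
appear to carry sequence features that distinguish instability-prone loci
from equally long stable ones.

Building an EMAST marker panel in a new species therefore requires three
computational steps, which this package implements end to end:

1. **Tandem-repeat scanning** — enumerate every maximal perfect run of the
   query unit in the genome, with its 25-nt flanks
   (`scanGenome()`, `extractFlanks()`).
2. **Flanking-motif modelling** — learn 11-nt motifs from the 5' and 3'
   flanks of a panel of *known* unstable loci, and keep only repeat loci
   whose two flanks both carry the motifs
   (`trainMotifModel()`, `filterByMotifs()`).
3. **Similarity ranking and selection** — score each surviving locus by
   global-alignment percent similarity against the known panel, rank by
   combined motif score percentile, and select loci at least 85% similar
   and at least 13 units long (`annotateSimilarity()`,
   `rankCandidates()`, `selectCandidates()`).

Once a panel has been assayed (repeat-unit counts per marker, per animal,
in normal and tumor tissue), the **caller** reproduces the human-study
decision rules: a tumor shows EMAST at a marker when its count differs
from the matched normal; a marker is unstable in normal tissue when any
normal count differs from the published reference count; a tumor is
EMAST-positive when at least one panel marker is unstable
(`callEmast()`, `callNormalInstability()`, `classifyTumors()`,
`summarizePanel()`).

## The repeat scanner

`findTandemRepeats()` reports every maximal run of the unit with at least
`minUnits` complete copies.  The design choices, each of which changes
the locus set, are explicit:

* **Perfect repeats only.** One mismatching base ends a run; assay
  panels report integer unit counts, and tolerance parameters would make
  "the repeat length" ambiguous.
* **Complete units only.** A trailing `C` after `CTTTCTTT` is not half a
  unit; the tract boundary stops at the last full copy.  (The caller's
  `repeatCountDelta()` does look at partial-unit overhangs — a tract
  -length difference that is not a multiple of the unit length is
  flagged as a non-unit indel rather than silently rounded.)
* **One rotation, one strand.** `CTTT` and `TTTC` describe the same
  biological tract starting at different offsets; scanning all rotations
  at once would report duplicated, phase-shifted loci.  The scanner
  matches the unit verbatim; `scanReverse = TRUE` additionally scans the
  reverse complement and reports those loci in forward coordinates with
  strand `-` (an `AAAG` tract on the forward strand *is* a `CTTT` tract
  on the other strand).
* **`N` never matches.** Assembly gaps split runs.
* **Defaults.** `minUnits = 10` for discovery scans (known unstable loci
  are ≥ 10 units long) and units of length 3 or 4 whose minimal period
  equals their length (`AAAA` and `ATAT` are rejected — they are mono-
  and dinucleotide repeats in disguise).

Coordinates are 0-based half-open in BED output and in the `start0`/
`end0` TSV columns, 1-based inclusive inside R (`GRanges`) and in the
`start1`/`end1` columns, so either convention can be read off directly.

For minus-strand loci the extracted flanks are reverse-complemented and
swapped so that `upstream_flank` is always 5' of the tract *on the
strand that carries the unit* — the motif model is stranded, and a
flank only makes sense in the orientation the motif was trained on.

## The motif model

### PWMs and scoring

A motif is a position weight matrix: per-column base probabilities
$p_{bj}$ over a 0-order background $q_b$.  `buildPWM()` uses

$$p_{bj} = \frac{c_{bj} + \lambda q_b}{n + \lambda}$$

with pseudocount $\lambda = 0.25$ by default — Laplace smoothing scaled
by the background, so a C/T-rich background does not hand rare bases
outsized corrections.  Windows score by summed log-odds
$\sum_j \log_2 (p_{b_j j}/q_{b_j})$ in bits; an `N` contributes zero at
its column.  The background is estimated from the training flanks
themselves rather than genome-wide: the flanks of unstable loci are
repetitive and C/T-rich, and a genome-wide background would inflate
every score.

### ZOOPS EM discovery

`discoverMotif()` re-implements the role a motif-discovery suite plays
in this workflow as a ZOOPS (zero-or-one occurrence per sequence)
finite-mixture EM: each training flank contains at most one motif
occurrence, at a uniform position, with prior probability $\gamma$.
ZOOPS rather than OOPS because real panels behave like "found in 6 out
of 7 flanking sequences" — one sequence may simply lack the motif.

* **Starts.** EM runs from the `nStarts` enumerated flank windows with
  the highest *coverage* (summed best per-sequence identity), ties
  broken lexicographically, so discovery is deterministic given its
  inputs.
* **Objective.** With pseudocounts the M-step maximises the
  Dirichlet-penalised (MAP) log-likelihood, so that penalised objective
  is what the implementation traces and what is asserted to be
  non-decreasing at every iteration.  Convergence at change
  $< 10^{-6}$ or 200 iterations.
* **Start selection.** Among converged starts the reported motif is the
  most *significant* one (smallest approximate E-value), not the
  highest-likelihood one.  The two disagree exactly in the known phase
  -ambiguity failure mode: a model shifted by one column trades an
  informative column for a noise column but can gain likelihood by
  absorbing a spurious seventh site; the information-content-based
  score penalises that trade.
* **Site acceptance.** A sequence is an accepted site when its
  posterior probability of containing an occurrence (the *sum* of its
  window posteriors) reaches 0.5; the best window gives the location.
  Summing matters in degenerate periodic flanks, where identical
  windows split the posterior mass.
* **Significance.** Writing $I$ for the model's information content
  over $n$ effective sites and $w$ for its width,
  $2 n \ln 2 \cdot I$ is compared against its asymptotic
  $\chi^2_{3w}$ null (normal approximation) and the one-sided tail
  probability is Bonferroni-scaled by the number of enumerated starting
  points.  This is a rough "is there any motif here at all" score: it
  is **not** comparable with E-values printed by MEME, whose objective
  and null analytics differ.  Panels for which no significant motif
  exists (e.g. a panel of only four loci of another unit category)
  should and do fail model training rather than return a fabricated
  model.

Model training (`trainMotifModel()`) runs discovery separately on the
5' and 3' flank sets, within a single repeat-unit category (mixing CTTT
and ATCT loci is an error — different unit categories have different
flank biology).  The acceptance threshold of each matrix defaults to the
minimum log-odds score among its accepted training sites: a new flank
"carries the motif" if it scores at least as well as the weakest
training example, which reproduces 6-of-7-style site acceptance at scan
time without any further tuning.  Over 20 seeded replicates of the
planted-motif condition (7 flanks of 25 nt, 6 carrying the 11-mer with
one point mutation each) the planted consensus is recovered within
Hamming distance 1 in ≥ 90% of replicates; the residual failures are
one-column phase shifts, which the data genuinely support when the
planted mutations cluster in a terminal motif column — a known,
documented limitation.

## The candidate pipeline

`filterByMotifs()` keeps exactly the loci whose 5' flank best score
meets the 5' threshold *and* whose 3' flank meets the 3' threshold;
`combined_score` is the sum of the two best scores.  Loci with flanks
truncated by a contig edge cannot be checked on both sides and are
dropped by default.  Raising either threshold can only shrink the
output (a property the tests assert).

"Percent similarity" to the known panel is defined precisely, since
reproducibility demands one convention: global Needleman–Wunsch
alignment of `upstream flank + tract + downstream flank` against each
panel member's region, match +1, mismatch −1, gap −2, no end-gap
forgiveness; similarity is 100 × identical columns / alignment length.
Alignment, not Hamming distance, because regions differ in repeat
length.  Among score-optimal alignments the implementation selects the
one maximising identical columns and then minimising alignment length
(lexicographically), which makes the reported value a well-defined,
symmetric function of the sequence pair; any remaining traceback ties
prefer diagonal, then up, then left.  The kernel is ~60 lines of C++
(Rcpp); an independent plain-R dynamic program serves as its oracle in
the tests.

Ranking uses percentile = 100·rank/n with average ranks on ties; a
candidate is top-decile when its percentile strictly exceeds 90 (with
distinct scores that is the top tenth of the set).  Selection keeps
candidates ≥ 85% similar and ≥ 13 units long — the thresholds used to
carry discovered loci forward to wet-lab verification — and names them
`C<chromosome>R<units>`, with `.1`, `.2` suffixes on collisions.

## The caller

`RepeatCountExperiment` (a `SummarizedExperiment` subclass) holds the
marker × sample count matrices for normal, tumor and optionally
parental-strain tissue, plus each marker's published reference count and
whether it was algorithm-identified (controls are carried but never
enter panel-level counts).  Missing measurements are explicit `NA` and
are skipped, never imputed.

* `callEmast()`: a sample shows EMAST at a marker when both counts are
  present and differ.  Samples missing either count are never called.
* `callNormalInstability()`: by default a marker is unstable in normal
  tissue when any normal count differs from the published reference
  count.  The alternative reading — normal counts differing *between
  animals* — is exposed as `compare = "across_mice"`; the two
  definitions agree on the packaged worked example, and the default is
  the one that reproduces its published annotations including the
  marker where a single animal deviates.
* `classifyTumors()`: EMAST-positive at ≥ `minUnstableMarkers` unstable
  panel markers (default 1, the commonly used human-study rule; human
  panels vary between one and two out of at least five).
* `summarizePanel()` aggregates: markers with normal instability, with
  EMAST, their overlap, markers with any instability, EMAST-positive
  samples, and control tallies.

On the packaged table (7 panel markers × 7 mice, 2 controls, 1
parental-assayed marker) the summary is 5/7 markers with normal-tissue
instability, 5/7 with EMAST, 4 overlapping, 6/7 with any instability,
0/2 controls unstable, 0/7 parental samples deviating — and 6 of 7
tumors EMAST-positive under the ≥ 1-marker rule.  The source report
states five EMAST-positive tumors while its own per-cell annotations
mark six; the package implements the stated rule and reports what the
data imply, and no correctness claim is attached to the tumor-level
count.

```{r table1}
rce <- readCountTable(system.file("extdata", "table1.tsv",
                                  package = "emastscan"))
summarizePanel(rce)
```

## Synthetic data: what it does and does not show

All validation runs on synthetic inputs with recorded ground truth,
generated by pure functions of their seeds:

* `generateGenome()` — i.i.d. background bases with planted repeat
  tracts; motif-bearing plants receive the exact consensus 11-mers at
  random offsets within their 25-nt flanks.  Planted tracts are forced
  maximal, placements respect a separation rule (≥ flank + motif width
  apart, flank-width from contig edges), and the generator re-scans its
  own output to verify the planted loci are exactly what a scan
  recovers.
* `generateFlankSet()` — the motif-training condition: `n` flanks,
  motif planted in `round(occurrence × n)` of them with a set number of
  point mutations per site (defaults 7 flanks, 6-of-7 occurrence,
  mirroring real panels).
* `generateCountTable()` — published counts drawn from 14–18 (the range
  real tetranucleotide panels occupy), normal counts deviating with
  probability `pNormalInstability`, tumor counts deviating from their
  matched normal with probability `pEmast`, shifts from {−2, −1, +1,
  +2}.  Shifts are non-zero, so planted events coincide exactly with
  observable tumor≠normal cells.

The shipped fixture genome (two 12-kb contigs, 20 planted CTTT tracts,
8 motif-bearing with ≥ 13 units) and its known-locus panel (mutated
copies of the motif-bearing loci, emulating orthologs in a related
genome at ~92–97% regional similarity) are committed under
`inst/extdata/` and regenerate bit-identically from
`tools/make-fixtures.R`; a test asserts exactly that.

What passing on these fixtures shows: the scanner, filter, ranker and
caller implement their stated rules exactly, and discovery recovers
planted signal under realistic noise.  What it does not show: behaviour
on real genomes — i.i.d. background has no repeat families, GC
isochores, or near-miss motifs, so genome-scale candidate counts and
filter reduction rates on real chromosomes cannot be extrapolated from
the fixture, and regenerating them requires full genome FASTA input at
the user's own scale.  Problem sizes used by the test-suite and the
acceptance script (100 oracle sequences of 1–8 kb, 20 discovery
replicates, 7 × 500 count tables) were chosen to exercise every rule
at comfortable desk scale.

## Numerical and degenerate-input choices

* PWM columns sum to 1 within 1e-9 (validity-checked); with
  pseudocount 0 a zero probability is legal and scores `-Inf`, which
  orders correctly below every finite score.
* `scanFlank()` on a flank shorter than the motif width returns no
  match (`NULL`), and such loci simply fail the filter.
* Tied best windows take the smallest offset; tied similarity takes the
  first panel member in input order; tied scores take average ranks.
* The EM seed is an explicit required argument end to end (CLI
  `--seed` is mandatory for `discover`); two runs with equal inputs and
  seeds are byte-identical, and all generator randomness flows through
  one seeded RNG per call with no global state left behind.

## Limitations

* Discovery within one repeat-unit category at a time, one rotation per
  call; users wanting all rotations of a unit pass them explicitly.
* The E-value approximation supports ranking and a sanity threshold,
  not cross-tool comparison.
* Chromatograph interpretation is out of scope: the caller consumes
  integer unit counts as given and represents ambiguous measurements as
  missing.
* Phase ambiguity in motif discovery (above) caps planted-consensus
  recovery near 90–95% when mutations land in terminal motif columns.
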