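# emastscan

Discovery of candidate EMAST microsatellite loci in animal genomes, and
calling of tumor instability from paired normal/tumor repeat counts.

EMAST (**E**levated **M**icrosatellite **A**lterations at **S**elected
**T**etranucleotide repeats) is a form of microsatellite instability seen
in colorectal and other cancers: at particular tetranucleotide loci —
most commonly AAAG/CTTT repeats — the repeat-unit count in tumor DNA
differs from matched normal tissue of the same individual. Only
*selected* loci behave this way, and the 25-nt flanking sequences of
known unstable loci carry distinguishing motifs. `emastscan` is for
researchers who want to build an EMAST marker panel in a species that
does not yet have one (e.g. a mouse cancer model), and to score assay
results once the panel is measured.

## The method

Given a genome FASTA, a repeat unit $u$ (e.g. `CTTT`) and a panel of
known unstable loci with their 25-nt flanks, the discovery chain is:

1. **Scan** — every maximal perfect tandem repeat
   $u^k,\ k \ge 10$, one rotation, with optional reverse-complement
   scanning (`scanGenome`), plus 25-nt flanks (`extractFlanks`).
2. **Motif filter** — 11-nt PWMs for the 5' and 3' flanks are learned
   from the known panel with a ZOOPS (zero-or-one occurrence per
   sequence) EM algorithm (`trainMotifModel`). A locus survives iff both
   of its flanks score at least the model thresholds
   $\max_w \sum_j \log_2\frac{p_{w_j j}}{q_{w_j}} \ge \tau$
   (`filterByMotifs`).
3. **Similarity & selection** — each survivor's region (flank + tract +
   flank) is globally aligned (match +1, mismatch −1, gap −2) against
   every panel member; similarity = 100 × identical columns / alignment
   length. Candidates are percentile-ranked by combined PWM score and
   selected at ≥ 85% similarity and ≥ 13 units
   (`annotateSimilarity`, `rankCandidates`, `selectCandidates`).

The caller reproduces the human-study rules on a marker × sample count
table: tumor ≠ matched normal ⇒ EMAST event; any normal ≠ published
reference count ⇒ normal-tissue instability; ≥ 1 unstable panel marker ⇒
EMAST-positive tumor (`callEmast`, `callNormalInstability`,
`classifyTumors`, `summarizePanel`).

Seeded generators (`generateGenome`, `generateFlankSet`,
`generateCountTable`) produce genomes with planted repeats/motifs and
count tables with planted instability, with full ground truth, so every
stage is testable without downloads.

## Worked example

Using the packaged synthetic fixture (two 12-kb contigs, 20 planted
CTTT tracts, 8 of them flanked by motifs; the known-locus panel mimics
orthologs of the motif-bearing loci):

```r
library(emastscan)
genome <- readGenome(system.file("extdata", "synthetic_genome.fa",
                                 package = "emastscan"))
panel  <- readKnownLoci(system.file("extdata", "synthetic_known_loci.tsv",
                                    package = "emastscan"))
model  <- trainMotifModel(panel, seed = 9)
model
#> MotifModel (unit category: CTTT )
#>   5' motif: GCGCATATGCG  threshold 14.71 bits  E ~ 9.71e-76
#>   3' motif: TTGACGTCAAG  threshold 14.97 bits  E ~ 1.1e-72

sel <- runCandidatePipeline(genome, model, panel)
length(sel)          # 8 candidates out of 20 scanned loci
names(sel)[1:3]
#> [1] "C1R13" "C1R17" "C1R19"
round(range(sel$best_similarity_pct), 1)
#> [1] 92.2 97.0
```

The selected panel carries, per locus, the two motif matches and scores,
the combined score and its percentile, and the best percent similarity
with the responsible panel locus; `writeCandidates()` saves it as an
annotated TSV (0-based *and* 1-based coordinates) or BED6.

Scoring an assayed panel — here the packaged table of seven markers and
two control markers typed in seven mice (normal and tumor colon tissue,
plus parental-strain samples for one marker):

```r
rce <- readCountTable(system.file("extdata", "table1.tsv",
                                  package = "emastscan"))
summarizePanel(rce)
#> EMAST panel summary — 7 panel marker(s), 2 control(s)
#>   markers with normal-tissue instability: 5/7
#>   markers with EMAST in >=1 tumor:        5/7
#>   overlap of the two:                     4/7
#>   markers with any instability:           6/7
#>   EMAST-positive tumors: 1, 2, 4, 5, 6, 7
#>   controls with any instability:          0/2
```

Five of seven panel markers show EMAST in at least one tumor, five show
instability already in (macroscopically) normal tissue from the diseased
animals, six show some form of instability — while neither control
marker nor any parental-strain sample shows any, i.e. the discovery
chain selects loci that are unstable specifically in diseased tissue.

A command-line wrapper with subcommands `scan`, `discover`, `pipeline`
and `call` is installed at
`system.file("cli", "emastscan", package = "emastscan")`; all defaults
(unit `CTTT`, ≥ 10 units, 25-nt flanks, 11-nt motifs, ≥ 85% similarity,
≥ 13 units for selection) match the discovery parameters above, and
`--help` is available per subcommand.

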