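#!/usr/bin/env Rscript
## Regenerates the shipped fixtures under inst/extdata/ from the
## package's own seeded generators.  Run from the repository root after
## installing the package:  Rscript tools/make-fixtures.R
## table1.tsv is a literal transcription of a published count table and
## is NOT regenerated here.
##
## Design: 20 CTTT tracts are planted on two 12-kb contigs; the 8
## motif-bearing ones (exact 11-nt consensi embedded in their 25-nt
## flanks) all have >= 13 units.  The synthetic known-locus panel is
## built from the 8 motif-bearing loci by mutating each flank at 2 positions
## and shifting the repeat length by +/-1 unit — emulating orthologous
## loci in a related genome, so panel similarity is high (> 85%) for
## the planted candidates, as it is for real cross-species matches,
## while motif-free loci (random flanks) stay far below it.

suppressPackageStartupMessages({
  library(emastscan)
  library(GenomicRanges)
})

MOTIF_5P <- "GCGCATATGCG"
MOTIF_3P <- "TTGACGTCAAG"
BASES <- c("A", "C", "G", "T")

set.seed(74)
nu_motif <- c(13, 14, 15, 16, 17, 18, 19, 21)       # motif-bearing
nu_plain <- c(10, 11, 12, 13, 14, 15, 16, 17, 18, 20, 22, 25)
plants <- data.frame(
  unit = "CTTT",
  n_units = c(nu_motif, nu_plain),
  with_motifs = rep(c(TRUE, FALSE), c(8, 12)),
  contig = rep(c("chr1", "chr2"), 10),
  position = NA_integer_,
  stringsAsFactors = FALSE
)
gen <- generateGenome(c(chr1 = 12000L, chr2 = 12000L), plants,
                      motif5p = MOTIF_5P, motif3p = MOTIF_3P,
                      flankLen = 25L, seed = 2018L)
writeGenome(gen$genome, "inst/extdata/synthetic_genome.fa")

truth <- gen$truth
names(truth) <- locusNames(truth)
writeCandidates(truth, "inst/extdata/synthetic_truth.bed",
                format = "bed")
tr <- data.frame(
  locus_id = names(truth),
  contig = as.character(seqnames(truth)),
  start0 = start(truth) - 1L,
  end0 = end(truth),
  unit = truth$unit,
  n_units = truth$n_units,
  with_motifs = truth$with_motifs,
  motif5p_offset = truth$motif5p_offset,
  motif3p_offset = truth$motif3p_offset,
  stringsAsFactors = FALSE
)
write.table(tr, "inst/extdata/synthetic_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## --- synthetic known-locus panel from the motif-bearing loci --------
mutate <- function(s, k) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  at <- sample.int(length(ch), k)
  for (j in at) ch[j] <- sample(setdiff(BASES, ch[j]), 1L)
  paste(ch, collapse = "")
}
set.seed(75)
flanked <- extractFlanks(truth, gen$genome, flankLen = 25L)
src <- flanked[flanked$with_motifs]
panel <- data.frame(
  locus_id = sprintf("HK%02d", seq_along(src)),
  unit = "CTTT",
  n_units = src$n_units + sample(c(-1L, 0L, 1L), length(src), replace = TRUE),
  upstream_flank = vapply(src$upstream_flank, mutate, character(1L), k = 2L),
  downstream_flank = vapply(src$downstream_flank, mutate, character(1L), k = 2L),
  stringsAsFactors = FALSE
)
writeKnownLoci(panel, "inst/extdata/synthetic_known_loci.tsv")

cat("wrote", nrow(panel), "panel loci,", length(truth),
    "planted loci (", sum(truth$with_motifs), "motif-bearing )\n")
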