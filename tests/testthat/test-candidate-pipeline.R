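## shared fixture objects (built once per file)
genome <- readGenome(fixtureGenomePath())
panel <- readKnownLoci(fixturePanelPath())
truth <- read.delim(fixtureTruthPath())
model <- trainMotifModel(panel, motifWidth = 11, nStarts = 10, seed = 9)
flanked <- extractFlanks(scanGenome(genome, "CTTT", minUnits = 10),
                         genome, flankLen = 25)

test_that("motif filter passes exactly the planted motif-bearing loci", {
  cand <- filterByMotifs(flanked, model)
  expect_length(cand, sum(truth$with_motifs))
  expect_setequal(paste(seqnames(cand), start(cand) - 1),
                  paste(truth$contig[truth$with_motifs],
                        truth$start0[truth$with_motifs]))
})

test_that("vacuous thresholds pass all complete-flank loci; raising thresholds never grows the set", {
  open <- model
  open@threshold5p <- -1e6   # effectively no threshold (finite, so the
  open@threshold3p <- -1e6   # model object stays valid)
  all_ <- filterByMotifs(flanked, open)
  expect_length(all_, sum(flanked$complete_flanks))

  base <- filterByMotifs(flanked, model)
  for (bump in c(0.5, 2, 10)) {
    tight <- model
    tight@threshold5p <- model@threshold5p + bump
    tight@threshold3p <- model@threshold3p + bump
    sub <- filterByMotifs(flanked, tight)
    expect_lte(length(sub), length(base))
    expect_true(all(paste(seqnames(sub), start(sub)) %in%
                    paste(seqnames(base), start(base))))
  }
})

test_that("percent similarity: identity, single mismatch, DP oracle agreement", {
  set.seed(601)
  r <- randomSeq(90)
  expect_identical(percentSimilarity(r, r), 100)
  ## 100 columns, one mismatch, no gaps -> 99.0
  a <- randomSeq(100)
  b <- a
  substr(b, 37, 37) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 37, 37))[1]
  expect_identical(percentSimilarity(a, b), 99)
  ## DP oracle on 50 random pairs (varying lengths <= 40)
  for (i in 1:50) {
    x <- randomSeq(sample(5:40, 1))
    y <- randomSeq(sample(5:40, 1))
    got <- percentSimilarity(x, y, details = TRUE)
    want <- oracleNW(x, y)
    expect_equal(got$score, want$score)
    expect_equal(got$matches, want$matches)
    expect_equal(got$length, want$length)
    expect_equal(got$similarity, want$similarity)
  }
  expect_error(percentSimilarity("", "ACGT"), "non-empty")
})

test_that("percent similarity is symmetric in its arguments", {
  set.seed(602)
  for (i in 1:40) {
    x <- randomSeq(sample(10:60, 1))
    y <- randomSeq(sample(10:60, 1))
    expect_identical(percentSimilarity(x, y), percentSimilarity(y, x))
  }
})

test_that("similarity annotation takes the panel maximum with first-entry ties", {
  cand <- filterByMotifs(flanked, model)
  ann <- annotateSimilarity(cand, panel, genome)
  ## max over panel >= similarity to any single member (spot-check one)
  p1 <- as.data.frame(panel)[1, ]
  reg1 <- paste0(p1$upstream_flank, strrep(p1$unit, p1$n_units),
                 p1$downstream_flank)
  regs <- paste0(ann$upstream_flank,
                 substr(as.character(genome[[as.character(seqnames(ann)[1])]]),
                        start(ann)[1], end(ann)[1]),
                 ann$downstream_flank)
  expect_gte(ann$best_similarity_pct[1],
             percentSimilarity(regs[1], reg1))
  ## candidate equal to a panel member's region scores exactly 100
  g2 <- Biostrings::DNAStringSet(c(k = paste0(
    p1$upstream_flank, strrep("CTTT", p1$n_units), p1$downstream_flank)))
  l2 <- extractFlanks(scanGenome(g2, "CTTT", minUnits = 10), g2, 25)
  l2$complete_flanks <- TRUE  # flanks are the full remaining sequence
  a2 <- annotateSimilarity(l2, panel, g2)
  expect_identical(a2$best_similarity_pct, 100)
  expect_identical(a2$best_similarity_locus, "HK01")
  expect_error(annotateSimilarity(cand, panel[0, ], genome), "empty")
})

test_that("percentile ranking uses average ranks and flags the top decile", {
  gr <- GRanges(rep("c", 10), IRanges(seq(1, 901, 100), width = 40))
  gr$combined_score <- as.numeric(1:10)
  r <- rankCandidates(gr)
  expect_identical(sum(r$top_decile), 1L)
  expect_identical(r$score_percentile[10], 100)
  ## all-tied scores with n = 2: both at 75, none flagged
  g2 <- gr[1:2]
  g2$combined_score <- c(5, 5)
  r2 <- rankCandidates(g2)
  expect_identical(r2$score_percentile, c(75, 75))
  expect_false(any(r2$top_decile))
  ## permutation invariance of the percentile multiset
  set.seed(603)
  g3 <- gr
  g3$combined_score <- rnorm(10)
  p1 <- sort(rankCandidates(g3)$score_percentile)
  g4 <- g3[sample(10)]
  p2 <- sort(rankCandidates(g4)$score_percentile)
  expect_identical(p1, p2)
})

test_that("selection applies the similarity and repeat-length thresholds", {
  gr <- GRanges(rep("chr5", 3), IRanges(c(1, 101, 201), width = 52))
  gr$n_units <- c(13L, 13L, 12L)
  gr$best_similarity_pct <- c(84.9, 85, 95)
  sel <- selectCandidates(gr)
  expect_length(sel, 1L)           # 84.9 excluded, n=12 excluded
  expect_identical(start(sel), 101L)
  ## thresholds (0, 2) keep everything
  expect_length(selectCandidates(gr, 0, 2), 3L)
})

test_that("locus names follow the C<chrom>R<units> convention with collision suffixes", {
  gr <- GRanges(c("chr9", "chr18", "chr18"),
                IRanges(c(1, 1, 100), width = 68))
  gr$n_units <- c(17L, 14L, 14L)
  expect_identical(locusNames(gr), c("C9R17", "C18R14.1", "C18R14.2"))
})

test_that("full pipeline selects the planted candidates deterministically", {
  sel1 <- runCandidatePipeline(genome, model, panel)
  expect_length(sel1, sum(truth$with_motifs))
  expect_setequal(paste(seqnames(sel1), start(sel1) - 1),
                  paste(truth$contig[truth$with_motifs],
                        truth$start0[truth$with_motifs]))
  ## byte-identical TSV on repeated runs
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  writeCandidates(sel1, t1)
  writeCandidates(runCandidatePipeline(genome, model, panel), t2)
  expect_identical(readLines(t1), readLines(t2))
  ## an impossible similarity threshold empties the panel
  expect_length(runCandidatePipeline(genome, model, panel,
                                     minSimilarityPct = 101), 0L)
})
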