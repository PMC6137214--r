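test_that("repeat units are validated for alphabet, length and periodicity", {
  expect_identical(checkRepeatUnit("cttt"), "CTTT")
  expect_identical(checkRepeatUnit("ATC"), "ATC")
  expect_error(checkRepeatUnit("AAAA"), "periodic")
  expect_error(checkRepeatUnit("ATAT"), "periodic")
  expect_error(checkRepeatUnit("CT"), "length 3 or 4")
  expect_error(checkRepeatUnit("CTNN"), "alphabet")
})

test_that("findTandemRepeats reports maximal runs of complete units", {
  gr <- findTandemRepeats("AACTTTCTTTGG", "CTTT", minUnits = 2)
  expect_length(gr, 1L)
  expect_identical(start(gr), 3L)   # 0-based [2,10) = 1-based 3..10
  expect_identical(end(gr), 10L)
  expect_identical(gr$n_units, 2L)

  gr2 <- findTandemRepeats(strrep("CTTT", 10), "CTTT", minUnits = 10)
  expect_identical(c(start(gr2), end(gr2), gr2$n_units), c(1L, 40L, 10L))

  ## trailing partial unit is excluded; interruptions split runs
  gr3 <- findTandemRepeats("CTTTCTTTC", "CTTT", minUnits = 2)
  expect_identical(end(gr3), 8L)
  gr4 <- findTandemRepeats(paste0(strrep("CTTT", 3), "A", strrep("CTTT", 3)),
                           "CTTT", minUnits = 2)
  expect_length(gr4, 2L)
  ## N never matches
  gr5 <- findTandemRepeats(paste0(strrep("CTTT", 3), "N", strrep("CTTT", 3)),
                           "CTTT", minUnits = 3)
  expect_length(gr5, 2L)
  ## rotated phase is not reported
  expect_length(findTandemRepeats(strrep("TTTC", 10), "CTTT", minUnits = 10),
                0L)
})

test_that("scanner equals the exhaustive sliding-window oracle on random sequences", {
  set.seed(42)
  for (rep in 1:30) {
    unit <- sample(c("CTTT", "ATC", "AAAG", "ATCT"), 1)
    ## enriched alphabet so that spontaneous runs actually occur
    s <- paste0(randomSeq(3000, c(A = .2, C = .3, G = .1, T = .4)),
                strrep(unit, sample(2:12, 1)),
                randomSeq(2000, c(A = .2, C = .3, G = .1, T = .4)))
    minU <- sample(2:4, 1)
    got <- findTandemRepeats(s, unit, minUnits = minU)
    want <- oracleTandemRepeats(s, unit, minU)
    expect_identical(start(got), want$start)
    expect_identical(got$n_units, want$n_units)
    expect_identical(width(got), want$n_units * nchar(unit))
  }
})

test_that("reported loci are maximal and non-overlapping", {
  set.seed(43)
  s <- paste(replicate(30, paste0(randomSeq(50), strrep("CTTT",
             sample(2:8, 1)))), collapse = "")
  gr <- findTandemRepeats(s, "CTTT", minUnits = 2)
  expect_gt(length(gr), 5L)
  ## no overlap
  expect_true(all(start(gr)[-1] > end(gr)[-length(gr)]))
  ## cannot extend by one unit on either side
  for (i in seq_along(gr)) {
    a <- start(gr)[i]; b <- end(gr)[i]
    if (a - 4 >= 1)
      expect_false(substr(s, a - 4, a - 1) == "CTTT")
    if (b + 4 <= nchar(s))
      expect_false(substr(s, b + 1, b + 4) == "CTTT")
  }
})

test_that("reverse-strand scanning reports minus-strand loci in forward coordinates", {
  g <- Biostrings::DNAStringSet(c(c1 = paste0(randomSeq(60),
                                              strrep("AAAG", 12),
                                              randomSeq(60))))
  expect_length(scanGenome(g, "CTTT", minUnits = 10), 0L)
  rev <- scanGenome(g, "CTTT", minUnits = 10, scanReverse = TRUE)
  expect_length(rev, 1L)
  expect_identical(as.character(strand(rev)), "-")
  expect_identical(start(rev), 61L)
  expect_identical(end(rev), 61L + 48L - 1L)
  expect_identical(rev$n_units, 12L)
  ## two forward contigs each with one planted tract
  g2 <- Biostrings::DNAStringSet(c(a = paste0(randomSeq(30), strrep("CTTT", 12)),
                                   b = paste0(strrep("CTTT", 12), randomSeq(30))))
  fwd <- scanGenome(g2, "CTTT", minUnits = 10)
  expect_length(fwd, 2L)
  expect_true(all(strand(fwd) == "+"))
})

test_that("flank extraction equals independent string slicing and flags edges", {
  set.seed(44)
  g <- Biostrings::DNAStringSet(c(chr = paste0(randomSeq(40),
        strrep("CTTT", 11), randomSeq(40))))
  s <- as.character(g[[1]])
  loci <- scanGenome(g, "CTTT", minUnits = 10)
  fl <- extractFlanks(loci, g, flankLen = 25)
  a <- start(loci); b <- end(loci)
  expect_identical(fl$upstream_flank, substr(s, a - 25, a - 1))
  expect_identical(fl$downstream_flank, substr(s, b + 1, b + 25))
  expect_true(fl$complete_flanks)

  ## locus 10 nt from the contig start: truncated upstream flank kept
  g2 <- Biostrings::DNAStringSet(c(c = paste0(randomSeq(10),
         strrep("CTTT", 10), randomSeq(60))))
  l2 <- scanGenome(g2, "CTTT", minUnits = 10)
  f2 <- extractFlanks(l2, g2, flankLen = 25)
  expect_identical(nchar(f2$upstream_flank), 10L)
  expect_false(f2$complete_flanks)
})

test_that("minus-strand flanks are stranded with their locus", {
  set.seed(45)
  up <- randomSeq(25); dn <- randomSeq(25)
  ## CTTT tract on the minus strand = AAAG tract forward; the 5' flank of
  ## the minus-strand unit is the reverse complement of the forward
  ## downstream slice
  g <- Biostrings::DNAStringSet(c(c = paste0(up, strrep("AAAG", 12), dn)))
  loci <- scanGenome(g, "CTTT", minUnits = 10, scanReverse = TRUE)
  fl <- extractFlanks(loci, g, flankLen = 25)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_identical(fl$upstream_flank, rc(dn))
  expect_identical(fl$downstream_flank, rc(up))
})

test_that("repeat-length spectrum counts per contig with an overflow bin", {
  set.seed(46)
  g <- Biostrings::DNAStringSet(c(
    c1 = paste0(randomSeq(50), strrep("CTTT", 10), randomSeq(50),
                strrep("CTTT", 10), randomSeq(50), strrep("CTTT", 12),
                randomSeq(50)),
    c2 = paste0(randomSeq(50), strrep("CTTT", 30), randomSeq(50))))
  sp <- repeatLengthSpectrum(g, "CTTT", minUnits = 10, maxUnits = 25)
  get <- function(ct, bin) sp$count[sp$contig == ct & sp$bin == bin]
  expect_identical(get("c1", "10"), 2L)
  expect_identical(get("c1", "12"), 1L)
  expect_identical(get("c2", ">25"), 1L)
  ## conservation: spectrum total equals the scan locus count
  expect_identical(sum(sp$count),
                   length(scanGenome(g, "CTTT", minUnits = 10)))
  ## empty genome: all zeros
  sp0 <- repeatLengthSpectrum(
    Biostrings::DNAStringSet(c(z = randomSeq(500))), "CTTT", 10, 25)
  expect_true(all(sp0$count == 0L))
})

test_that("scanning is deterministic", {
  genome <- readGenome(fixtureGenomePath())
  a <- scanGenome(genome, "CTTT", minUnits = 10)
  b <- scanGenome(genome, "CTTT", minUnits = 10)
  expect_identical(a, b)
})
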