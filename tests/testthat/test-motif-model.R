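test_that("PWM construction follows the pseudocount formula", {
  ## pure counts, no pseudocount
  p <- buildPWM(c("AC", "AC"), pseudocount = 0,
                background = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(pwmProbs(p)[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwmProbs(p)[, 2], c(A = 0, C = 1, G = 0, T = 0))
  ## single site, pseudocount 1, uniform background:
  ## p(A) = (1 + 0.25)/2, others 0.25/2
  p1 <- buildPWM("A", pseudocount = 1,
                 background = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(unname(pwmProbs(p1)[, 1]),
               c(1.25 / 2, 0.125, 0.125, 0.125))
  ## columns always sum to 1
  set.seed(501)
  sites <- replicate(5, randomSeq(11))
  p2 <- buildPWM(sites, pseudocount = 0.25)
  expect_true(all(abs(colSums(pwmProbs(p2)) - 1) < 1e-12))
  expect_error(buildPWM(c("AC", "ACG")), "same length")
})

test_that("log-odds scoring matches a per-column lookup oracle", {
  ## uniform PWM over uniform background scores 0 on any window
  u <- buildPWM(c("ACGT", "CGTA", "GTAC", "TACG"), pseudocount = 0,
                background = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(logOddsScore(u, "AAAA"), 0)
  ## self-match beats reversed
  p <- buildPWM("ACGT", pseudocount = 0.1)
  expect_gt(logOddsScore(p, "ACGT"), logOddsScore(p, "TGCA"))
  ## oracle agreement on 100 random windows
  set.seed(502)
  pwm <- buildPWM(replicate(6, randomSeq(8)), pseudocount = 0.25)
  tab <- log2(pwmProbs(pwm) / pwmBackground(pwm))
  for (i in 1:100) {
    win <- randomSeq(8)
    ch <- strsplit(win, "")[[1]]
    expect_equal(logOddsScore(pwm, win),
                 sum(tab[cbind(match(ch, rownames(tab)), 1:8)]))
  }
  ## N columns contribute zero
  expect_equal(logOddsScore(pwm, "NNNNNNNN"), 0)
  expect_error(logOddsScore(pwm, "ACGT"), "width")
})

test_that("scanFlank returns the best window, first on ties, none when short", {
  set.seed(503)
  pwm <- buildPWM(c("GCGCATATGCG", "GCGCATATGCG", "GCGCATATGCG"),
                  pseudocount = 0.25,
                  background = c(A = .25, C = .25, G = .25, T = .25))
  ## planted consensus inside random flank is found at its offset
  for (i in 1:20) {
    off <- sample(0:14, 1)
    fl <- randomSeq(25)
    substr(fl, off + 1, off + 11) <- "GCGCATATGCG"
    m <- scanFlank(fl, pwm)
    expect_identical(m$offset, off)
    expect_identical(m$match, "GCGCATATGCG")
  }
  ## flank of exactly motif width
  expect_identical(scanFlank(randomSeq(11), pwm)$offset, 0L)
  ## shorter flank: no match
  expect_null(scanFlank(randomSeq(10), pwm))
  ## duplicated best window: smaller offset wins
  fl2 <- paste0("GCGCATATGCG", "AC", "GCGCATATGCG")
  expect_identical(scanFlank(fl2, pwm)$offset, 0L)
})

test_that("scanFlank equals exhaustive window enumeration", {
  set.seed(504)
  for (i in 1:60) {
    pwm <- buildPWM(replicate(4, randomSeq(7)), pseudocount = 0.25)
    fl <- randomSeq(sample(7:40, 1))
    got <- scanFlank(fl, pwm)
    want <- oracleScanFlank(fl, pwm)
    expect_identical(got$offset, want$offset)
    expect_equal(got$score, want$score)
  }
})

test_that("ZOOPS EM recovers a planted motif and its site list", {
  fl <- generateFlankSet(7, 25, FIX_MOTIF_5P, occurrence = 6 / 7,
                         mutationsPerSite = 1, seed = 11)
  fit <- discoverMotif(fl$flanks, motifWidth = 11, nStarts = 10, seed = 3)
  expect_lte(hamming(fit$consensus, FIX_MOTIF_5P), 1L)
  expect_gte(nrow(fit$sites), 6L)
  ## determinism: same seed, same PWM
  fit2 <- discoverMotif(fl$flanks, motifWidth = 11, nStarts = 10, seed = 3)
  expect_identical(pwmProbs(fit$pwm), pwmProbs(fit2$pwm))
  ## objective trace is non-decreasing
  expect_true(all(diff(fit$logLikTrace) >= -1e-8))
})

test_that("ZOOPS EM on identical flanks returns their top window with all sites", {
  fl <- rep("ACGTACGTACGTACGTACGT", 5)
  fit <- discoverMotif(fl, motifWidth = 8, nStarts = 5, seed = 1)
  expect_identical(nrow(fit$sites), 5L)
  ## consensus is one of the flank's windows
  expect_true(grepl(fit$consensus, fl[1], fixed = TRUE))
  expect_error(discoverMotif(c("ACGT"), motifWidth = 8), "at least 2")
  expect_error(discoverMotif(c("ACGT", "ACG"), motifWidth = 8),
               "at least 2")
})

test_that("model training enforces the unit-category rule and sets thresholds", {
  panel <- as.data.frame(readKnownLoci(fixturePanelPath()))
  model <- trainMotifModel(panel, motifWidth = 11, nStarts = 10, seed = 9)
  expect_lte(hamming(motifConsensus(pwm5p(model)), FIX_MOTIF_5P), 1L)
  expect_lte(hamming(motifConsensus(pwm3p(model)), FIX_MOTIF_3P), 1L)
  expect_true(all(is.finite(motifThresholds(model))))

  mixed <- panel
  mixed$unit[3] <- "ATCT"
  expect_error(trainMotifModel(mixed), "HK03")

  ## two identical loci: thresholds equal the self-consensus score
  twin <- panel[c(1, 1), ]
  twin$locus_id <- c("T1", "T2")
  m2 <- trainMotifModel(twin, motifWidth = 11, nStarts = 5, seed = 2)
  s5 <- scanFlank(twin$upstream_flank[1], pwm5p(m2))
  expect_equal(unname(motifThresholds(m2)["p5"]), s5$score)
})

test_that("MEME-format and JSON serialization round-trip the model", {
  panel <- readKnownLoci(fixturePanelPath())
  model <- trainMotifModel(panel, motifWidth = 11, nStarts = 10, seed = 9)

  meme <- withr::local_tempfile(fileext = ".txt")
  writeMemeMotifs(model, meme)
  txt <- readLines(meme)
  expect_identical(txt[1], "MEME version 4")
  motifs <- readMemeMotifs(meme)
  expect_named(motifs, c("flank_5p", "flank_3p"))
  expect_equal(pwmProbs(motifs$flank_5p), pwmProbs(pwm5p(model)),
               tolerance = 1e-5)

  js <- withr::local_tempfile(fileext = ".json")
  writeMotifModel(model, js)
  back <- readMotifModel(js)
  ## decimal-text round trip: equal to full double precision
  expect_equal(pwmProbs(back@pwm5p), pwmProbs(pwm5p(model)),
               tolerance = 1e-12)
  expect_equal(motifThresholds(back), motifThresholds(model),
               tolerance = 1e-12)
})
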