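rce <- readCountTable(table1Path())

test_that("the packaged count table loads with missing cells and controls intact", {
  expect_s4_class(rce, "RepeatCountExperiment")
  expect_identical(nrow(rce), 9L)
  expect_identical(ncol(rce), 7L)
  expect_identical(sum(!algorithmIdentified(rce)), 2L)
  ## one missing normal measurement (six values for seven mice)
  expect_identical(sum(is.na(normalCounts(rce)["C19R16", ])), 1L)
  ## parental assay only carries values for its one assayed marker
  par <- parentalCounts(rce)
  expect_false(is.null(par))
  expect_true(all(is.na(par[rownames(par) != "C10R18", ])))
  expect_true(all(par["C10R18", ] == 18L))
  ## write + read round-trip
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(rce, tmp)
  back <- readCountTable(tmp)
  expect_identical(normalCounts(back), normalCounts(rce))
  expect_identical(tumorCounts(back), tumorCounts(rce))
  expect_identical(publishedUnits(back), publishedUnits(rce))
})

test_that("repeat-count deltas come from tract differences in whole units", {
  ref <- paste0("GGAA", strrep("CTTT", 18), "GACC")
  expect_identical(repeatCountDelta(ref,
    paste0("GGAA", strrep("CTTT", 17), "GACC"), "CTTT"), -1L)
  expect_identical(repeatCountDelta(ref, ref, "CTTT"), 0L)
  ## a tract shortened by a non-multiple of four is a non-unit indel
  expect_error(repeatCountDelta(ref,
    paste0("GGAA", strrep("CTTT", 17), "C", "GACC"), "CTTT"),
    "non-unit indel")
  ## sequences must contain exactly one run
  expect_error(repeatCountDelta("ACGTACGT", ref, "CTTT"),
               "exactly one maximal run")
})

test_that("normal-tissue instability calls reproduce the published per-marker pattern", {
  ni <- callNormalInstability(rce)
  expect_identical(ni, c(
    C6R16 = TRUE, C8R17 = FALSE, C9R17 = TRUE, C10R18 = TRUE,
    C14R15 = TRUE, C14R16 = TRUE, C19R16 = FALSE,
    Ch18R14.1 = FALSE, Ch18R14.2 = FALSE))
  ## single deviating mouse is enough (one 16 among 17s)
  expect_true(ni[["C9R17"]])
  ## the across-mice alternative agrees on this table
  expect_identical(callNormalInstability(rce, compare = "across_mice"), ni)
})

test_that("per-mouse EMAST events match the published tumor-vs-normal differences", {
  em <- callEmast(rce)
  expect_identical(em$C6R16, c("2", "4", "6"))
  expect_identical(em$C8R17, c("5", "7"))
  expect_identical(em$C9R17, character(0))
  expect_identical(em$C10R18, c("1", "2"))
  expect_identical(em$C14R15, "6")
  expect_identical(em$C14R16, c("1", "2", "5", "6", "7"))
  expect_identical(em$C19R16, character(0))
  expect_identical(em$Ch18R14.1, character(0))
  ## marker with all tumor counts missing errors
  n <- matrix(17L, 1, 2, dimnames = list("m", c("1", "2")))
  t <- matrix(NA_integer_, 1, 2, dimnames = list("m", c("1", "2")))
  bad <- RepeatCountExperiment(n, t, publishedUnits = 17L)
  expect_error(callEmast(bad), "no sample with both")
})

test_that("tumor classification applies the minimum-unstable-markers rule", {
  expect_identical(classifyTumors(rce), c("1", "2", "4", "5", "6", "7"))
  ## sample 3 has no event anywhere, so it is never positive
  expect_false("3" %in% classifyTumors(rce))
  ## vacuous threshold marks every sample
  expect_identical(classifyTumors(rce, minUnstableMarkers = 0),
                   as.character(1:7))
  ## stricter threshold shrinks the set
  expect_true(all(classifyTumors(rce, minUnstableMarkers = 2) %in%
                  classifyTumors(rce)))
})

test_that("panel summary aggregates calls with controls kept separate", {
  s <- summarizePanel(rce)
  expect_identical(panelCounts(s), c(
    emast = 5L, normal_instability = 5L, overlap = 4L,
    any_instability = 6L))
  expect_identical(s@nControls, 2L)
  expect_identical(s@nControlsAnyInstability, 0L)
  ## invariants
  expect_lte(panelCounts(s)[["overlap"]],
             min(panelCounts(s)[["emast"]],
                 panelCounts(s)[["normal_instability"]]))
  expect_gte(panelCounts(s)[["any_instability"]],
             max(panelCounts(s)[["emast"]],
                 panelCounts(s)[["normal_instability"]]))
  ## permutation invariance under marker reordering
  s2 <- summarizePanel(rce[rev(seq_len(nrow(rce))), ])
  expect_identical(panelCounts(s2), panelCounts(s))
  expect_identical(emastPositiveMice(s2), emastPositiveMice(s))
})

test_that("an all-stable table yields an all-zero summary", {
  n <- matrix(15L, 3, 4, dimnames = list(paste0("m", 1:3),
                                         as.character(1:4)))
  all0 <- summarizePanel(RepeatCountExperiment(n, n,
            publishedUnits = rep(15L, 3)))
  expect_identical(unname(panelCounts(all0)), rep(0L, 4))
  expect_length(emastPositiveMice(all0), 0L)
})

test_that("summary invariants hold on random tables", {
  set.seed(701)
  for (i in 1:10) {
    g <- generateCountTable(nMarkers = 6, nMice = 8,
                            pNormalInstability = runif(1, 0, .5),
                            pEmast = runif(1, 0, .6),
                            seed = 7000 + i)
    s <- summarizePanel(g$experiment)
    pc <- panelCounts(s)
    expect_lte(pc[["overlap"]], min(pc[["emast"]],
                                    pc[["normal_instability"]]))
    expect_gte(pc[["any_instability"]], max(pc[["emast"]],
                                            pc[["normal_instability"]]))
    ## planted events equal observed calls exactly
    em <- callEmast(g$experiment)
    for (mk in rownames(g$truth$emastEvents))
      expect_identical(em[[mk]],
                       colnames(g$truth$emastEvents)[
                         g$truth$emastEvents[mk, ]])
  }
})

test_that("EMAST calls are invariant under mouse relabeling", {
  g <- generateCountTable(4, 6, 0.2, 0.4, seed = 99)
  x <- g$experiment
  perm <- c(3, 1, 2, 6, 5, 4)
  y <- x[, perm]
  emx <- callEmast(x)
  emy <- callEmast(y)
  for (mk in rownames(x))
    expect_setequal(emx[[mk]], emy[[mk]])
})
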