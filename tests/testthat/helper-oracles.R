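suppressPackageStartupMessages(library(GenomicRanges))

## Independent oracles used across the suite.  These deliberately take
## the dumbest correct route (test every offset, full DP in plain R)
## and share no code with the package internals they check.

## exhaustive tandem-repeat oracle: tests every offset for a verbatim
## unit match, chains the hits per phase class, and reports maximal
## runs of >= minUnits complete copies
oracleTandemRepeats <- function(seq, unit, minUnits) {
  s <- toupper(seq)
  k <- nchar(unit)
  L <- nchar(s)
  if (L < k * minUnits) return(data.frame(start = integer(),
                                          n_units = integer()))
  hit <- vapply(seq_len(L - k + 1L),
                function(i) substr(s, i, i + k - 1L) == unit, logical(1L))
  ## chain length starting at i: 1 + chain(i + k) if hit
  chain <- integer(L - k + 1L)
  for (i in rev(seq_len(L - k + 1L))) {
    if (hit[i])
      chain[i] <- 1L + if (i + k <= L - k + 1L) chain[i + k] else 0L
  }
  starts <- which(hit & chain >= minUnits)
  ## left-maximal: no unit copy ending right before the run
  starts <- starts[vapply(starts, function(i)
    i - k < 1L || !hit[i - k], logical(1L))]
  data.frame(start = starts, n_units = chain[starts])
}

## plain-R Needleman-Wunsch sharing the package's objective (score,
## then matches, then shortest alignment, lexicographically) but
## implemented independently with matrix loops
oracleNW <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  M <- matrix(0L, n + 1, m + 1)
  L <- matrix(0L, n + 1, m + 1)
  S[, 1] <- (0:n) * gap; L[, 1] <- 0:n
  S[1, ] <- (0:m) * gap; L[1, ] <- 0:m
  better <- function(s1, m1, l1, s2, m2, l2) {
    # is option 1 lexicographically better than option 2?
    s1 > s2 || (s1 == s2 && (m1 > m2 || (m1 == m2 && l1 < l2)))
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      id <- as.integer(x[i - 1] == y[j - 1])
      sb <- S[i - 1, j - 1] + ifelse(id == 1L, match, mismatch)
      mb <- M[i - 1, j - 1] + id
      lb <- L[i - 1, j - 1] + 1L
      for (o in list(c(S[i - 1, j] + gap, M[i - 1, j], L[i - 1, j] + 1L),
                     c(S[i, j - 1] + gap, M[i, j - 1], L[i, j - 1] + 1L))) {
        if (better(o[1], o[2], o[3], sb, mb, lb)) {
          sb <- o[1]; mb <- o[2]; lb <- o[3]
        }
      }
      S[i, j] <- sb; M[i, j] <- as.integer(mb); L[i, j] <- as.integer(lb)
    }
  }
  list(score = S[n + 1, m + 1], matches = M[n + 1, m + 1],
       length = L[n + 1, m + 1],
       similarity = 100 * M[n + 1, m + 1] / L[n + 1, m + 1])
}

## exhaustive window scan: score every window by direct per-column
## table lookup and return the best (first on ties)
oracleScanFlank <- function(flank, pwm) {
  p <- pwmProbs(pwm)
  bg <- pwmBackground(pwm)
  w <- ncol(p)
  ch <- strsplit(toupper(flank), "")[[1]]
  if (length(ch) < w) return(NULL)
  best <- NULL
  for (off in 0:(length(ch) - w)) {
    sc <- 0
    for (j in 1:w) {
      b <- ch[off + j]
      if (b %in% rownames(p))
        sc <- sc + unname(log2(p[b, j] / bg[b]))
    }
    if (is.null(best) || sc > best$score)
      best <- list(offset = off, score = sc)
  }
  best
}

randomSeq <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
        collapse = "")
}

hamming <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

table1Path <- function()
  system.file("extdata", "table1.tsv", package = "emastscan")

fixtureGenomePath <- function()
  system.file("extdata", "synthetic_genome.fa", package = "emastscan")

fixtureTruthPath <- function()
  system.file("extdata", "synthetic_truth.tsv", package = "emastscan")

fixturePanelPath <- function()
  system.file("extdata", "synthetic_known_loci.tsv", package = "emastscan")

## fixture motif consensi (kept in sync with tools/make-fixtures.R)
FIX_MOTIF_5P <- "GCGCATATGCG"
FIX_MOTIF_3P <- "TTGACGTCAAG"
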