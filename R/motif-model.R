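#' Build a position weight matrix from aligned sites
#'
#' Column probabilities are
#' \deqn{p_{bj} = \frac{c_{bj} + \lambda\,q_b}{n + \lambda}}
#' where \eqn{c_{bj}} counts base \eqn{b} at column \eqn{j} over the
#' \eqn{n} sites, \eqn{q_b} is the background frequency and \eqn{\lambda}
#' the pseudocount — a Laplace correction scaled by the background, so
#' that a C/T-rich background does not hand rare bases implausibly large
#' corrections.  With \code{pseudocount = 0} columns may contain exact
#' zeros and log-odds scores can be \code{-Inf}.
#'
#' @param sites character vector of equal-length A/C/G/T strings.
#' @param pseudocount single non-negative number (default 0.25).
#' @param background named base frequencies; default the base composition
#'   of \code{sites} themselves (with a tiny floor so no frequency is 0).
#' @return \code{\linkS4class{MotifPWM}}.
#' @examples
#' buildPWM(c("AC", "AC"), pseudocount = 0)
#' @export
buildPWM <- function(sites, pseudocount = 0.25, background = NULL) {
  if (length(sites) < 1L)
    stop("need at least one site", call. = FALSE)
  sites <- toupper(sites)
  w <- unique(nchar(sites))
  if (length(w) != 1L)
    stop("sites must all have the same length", call. = FALSE)
  if (!all(grepl("^[ACGT]+$", sites)))
    stop("sites must be over the alphabet {A,C,G,T}", call. = FALSE)
  if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount < 0)
    stop("'pseudocount' must be a single non-negative number",
         call. = FALSE)
  if (is.null(background))
    background <- .baseFreqs(sites)
  background <- .normBaseFreqs(background)
  chm <- do.call(rbind, strsplit(sites, "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j)
    tabulate(factor(chm[, j], levels = .BASES), nbins = 4L),
    integer(4L))
  probs <- (counts + pseudocount * background) /
    (length(sites) + pseudocount)
  dimnames(probs) <- list(.BASES, NULL)
  new("MotifPWM", probs = probs, background = background,
      pseudocount = pseudocount, nsites = length(sites))
}

## 0-order base composition with a floor so backgrounds are never 0
.baseFreqs <- function(seqs, floor = 0.01) {
  ch <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  cnt <- tabulate(factor(ch, levels = .BASES), nbins = 4L)
  f <- cnt / max(sum(cnt), 1L)
  f <- (f + floor) / (1 + 4 * floor)
  names(f) <- .BASES
  f
}

#' @describeIn MotifPWM motif width (number of columns).
#' @param x a \code{MotifPWM}.
#' @export
setMethod("width", "MotifPWM", function(x) ncol(x@probs))

#' PWM accessors
#'
#' @param x \code{\linkS4class{MotifPWM}} or
#'   \code{\linkS4class{MotifModel}}.
#' @return \code{pwmProbs}: the 4-by-width probability matrix;
#'   \code{pwmBackground}: named background frequencies;
#'   \code{motifConsensus}: the per-column argmax consensus string (ties
#'   broken in A < C < G < T order).
#' @name pwm-accessors
NULL

#' @rdname pwm-accessors
#' @export
pwmProbs <- function(x) x@probs

#' @rdname pwm-accessors
#' @export
pwmBackground <- function(x) x@background

#' @rdname pwm-accessors
#' @export
motifConsensus <- function(x) {
  if (is(x, "MotifModel"))
    return(c(p5 = motifConsensus(x@pwm5p), p3 = motifConsensus(x@pwm3p)))
  paste(.BASES[apply(x@probs, 2L, which.max)], collapse = "")
}

#' Information content of a PWM
#'
#' Total relative entropy (bits) of the matrix versus its background,
#' \eqn{\sum_j \sum_b p_{bj} \log_2 (p_{bj}/q_b)}.
#'
#' @param pwm \code{\linkS4class{MotifPWM}}.
#' @return single numeric (bits).
#' @export
informationContent <- function(pwm) {
  p <- pwm@probs
  lr <- log2(p / pwm@background)
  lr[p == 0] <- 0
  sum(p * lr)
}

setMethod("show", "MotifPWM", function(object) {
  cat(sprintf("MotifPWM of width %d (%.1f sites, pseudocount %.3g)\n",
              width(object), object@nsites, object@pseudocount))
  cat("  consensus:", motifConsensus(object), "\n")
  cat(sprintf("  information content: %.2f bits\n",
              informationContent(object)))
  cat("  background:",
      paste(sprintf("%s=%.3f", .BASES, object@background),
            collapse = " "), "\n")
})

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel (unit category:", object@unit, ")\n")
  cat(sprintf("  5' motif: %s  threshold %.2f bits  E ~ %.3g\n",
              motifConsensus(object@pwm5p), object@threshold5p,
              object@evalue5p))
  cat(sprintf("  3' motif: %s  threshold %.2f bits  E ~ %.3g\n",
              motifConsensus(object@pwm3p), object@threshold3p,
              object@evalue3p))
})

#' Model accessors
#'
#' @param x \code{\linkS4class{MotifModel}}.
#' @return \code{pwm5p}/\code{pwm3p}: the two
#'   \code{\linkS4class{MotifPWM}}s; \code{motifThresholds} /
#'   \code{motifEvalues}: named numerics with elements \code{p5},
#'   \code{p3}.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
pwm5p <- function(x) x@pwm5p

#' @rdname model-accessors
#' @export
pwm3p <- function(x) x@pwm3p

#' @rdname model-accessors
#' @export
motifThresholds <- function(x) c(p5 = x@threshold5p, p3 = x@threshold3p)

#' @rdname model-accessors
#' @export
motifEvalues <- function(x) c(p5 = x@evalue5p, p3 = x@evalue3p)

#' Log-odds score of a window against a PWM
#'
#' \eqn{\sum_j \log_2(p_{b_j j}/q_{b_j})} in bits.  An \code{N} in the
#' window contributes 0 at its column (neither evidence for nor against).
#'
#' @param pwm \code{\linkS4class{MotifPWM}}.
#' @param window string of length \code{width(pwm)} over A/C/G/T/N.
#' @return single numeric score (bits); \code{-Inf} is possible when the
#'   PWM was built with pseudocount 0.
#' @examples
#' p <- buildPWM(c("ACGT", "ACGT"), pseudocount = 0.1)
#' logOddsScore(p, "ACGT") > logOddsScore(p, "TGCA")
#' @export
logOddsScore <- function(pwm, window) {
  stopifnot(is(pwm, "MotifPWM"))
  window <- toupper(window)
  w <- width(pwm)
  if (nchar(window) != w)
    stop("window length ", nchar(window), " != PWM width ", w,
         call. = FALSE)
  ch <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c(.BASES, "N")))
    stop("window must be over {A,C,G,T,N}", call. = FALSE)
  idx <- match(ch, .BASES)
  keep <- !is.na(idx)
  if (!any(keep)) return(0)
  j <- which(keep)
  sum(log2(pwm@probs[cbind(idx[keep], j)] / pwm@background[idx[keep]]))
}

## scoring table: 4 x width log-odds matrix with N handled by the caller
.lodTable <- function(pwm) log2(pwm@probs / pwm@background)

#' Best motif match within a flank
#'
#' Slides the PWM over every window of the flank (forward strand only —
#' flanks are already stranded with their locus) and returns the
#' maximal-score window; ties go to the smallest offset.  Windows
#' containing \code{N} score with those columns contributing 0, as in
#' \code{\link{logOddsScore}}.
#'
#' @param flank string over A/C/G/T/N.
#' @param pwm \code{\linkS4class{MotifPWM}}.
#' @return one-row \code{data.frame} with \code{offset} (0-based),
#'   \code{score} (bits) and \code{match} (the window sequence), or
#'   \code{NULL} when the flank is shorter than the motif width.
#' @export
scanFlank <- function(flank, pwm) {
  stopifnot(is(pwm, "MotifPWM"))
  flank <- toupper(flank)
  w <- width(pwm)
  L <- nchar(flank)
  if (L < w) return(NULL)
  ch <- strsplit(flank, "", fixed = TRUE)[[1L]]
  if (!all(ch %in% c(.BASES, "N")))
    stop("flank must be over {A,C,G,T,N}", call. = FALSE)
  lod <- .lodTable(pwm)
  idx <- match(ch, .BASES)
  m <- L - w + 1L
  scores <- numeric(m)
  for (j in seq_len(w)) {
    v <- lod[cbind(idx[j:(j + m - 1L)], j)]
    v[is.na(v)] <- 0
    scores <- scores + v
  }
  best <- which.max(scores) # first index on ties
  data.frame(offset = best - 1L, score = scores[best],
             match = substr(flank, best, best + w - 1L),
             stringsAsFactors = FALSE)
}

#' Discover one motif from a set of flanks by ZOOPS EM
#'
#' A MEME-style zero-or-one-occurrence-per-sequence (ZOOPS) finite
#' mixture: each sequence carries at most one motif occurrence, at a
#' uniformly distributed position, with prior probability \eqn{\gamma}.
#' EM alternates posterior site assignment (E) with PWM and \eqn{\gamma}
#' re-estimation (M) until the observed-data log-likelihood improves by
#' less than \code{tol} or \code{maxIter} iterations.  Runs are started
#' from the \code{nStarts} enumerated width-mers of highest
#' self-information under the background (rarest composition first) and
#' the start with the best final log-likelihood wins.  The log-likelihood
#' is non-decreasing over iterations; the trace is returned so callers
#' can assert it.
#'
#' The significance approximation: writing \eqn{I} for the final PWM's
#' information content over \eqn{n} effective sites and \eqn{w} for the
#' width, \eqn{2 n \ln 2 \cdot I} is compared to its null distribution
#' (approximately \eqn{\chi^2_{3w}}, normal-approximated) and the
#' one-sided tail probability is multiplied by the number of enumerated
#' starting points.  It is a rough multiple-testing-corrected score for
#' "is there any motif here at all", not comparable with MEME's E-values.
#'
#' @param flanks character vector (>= 2) of A/C/G/T/N sequences, each at
#'   least \code{motifWidth} long.
#' @param motifWidth motif width (default 11).
#' @param nStarts number of seeded EM starts.
#' @param seed integer RNG seed (recorded; the search itself is
#'   deterministic given the inputs, the seed only feeds optional
#'   downstream resampling).
#' @param pseudocount forwarded to the PWM M-step.
#' @param tol,maxIter EM stopping rule.
#' @param minPosterior a sequence is an accepted site when its
#'   posterior probability of containing an occurrence (the sum of its
#'   window posteriors) reaches this value (default 0.5); the reported
#'   location is the best window.
#' @return list with elements \code{pwm}
#'   (\code{\linkS4class{MotifPWM}}), \code{sites} (\code{data.frame}:
#'   \code{seq} index, \code{offset} 0-based, \code{site},
#'   \code{posterior}), \code{evalue}, \code{gamma}, \code{logLik}
#'   (final), \code{logLikTrace}, \code{consensus}, \code{nStarts},
#'   \code{converged}.
#' @examples
#' set.seed(1)
#' fl <- generateFlankSet(7, 25, "GCGCATATGCG", occurrence = 6 / 7,
#'                        seed = 1)
#' fit <- discoverMotif(fl$flanks, motifWidth = 11, nStarts = 5, seed = 1)
#' fit$consensus
#' @export
discoverMotif <- function(flanks, motifWidth = 11L, nStarts = 10L,
                          seed = 1L, pseudocount = 0.25, tol = 1e-6,
                          maxIter = 200L, minPosterior = 0.5) {
  motifWidth <- .assertScalarCount(motifWidth, "motifWidth", min = 2L)
  nStarts <- .assertScalarCount(nStarts, "nStarts", min = 1L)
  flanks <- toupper(flanks)
  usable <- nchar(flanks) >= motifWidth
  if (sum(usable) < 2L)
    stop("need at least 2 flanks of length >= ", motifWidth,
         call. = FALSE)
  if (any(!usable))
    warning(sum(!usable), " flank(s) shorter than the motif width were ",
            "dropped from discovery")
  flanks <- flanks[usable]
  set.seed(seed)
  background <- .baseFreqs(flanks)

  ## per-sequence candidate windows (N-containing windows excluded)
  w <- motifWidth
  winlist <- lapply(flanks, function(s) {
    m <- nchar(s) - w + 1L
    wins <- substring(s, seq_len(m), seq_len(m) + w - 1L)
    wins[grepl("^[ACGT]+$", wins)]
  })
  offlist <- lapply(flanks, function(s) {
    m <- nchar(s) - w + 1L
    wins <- substring(s, seq_len(m), seq_len(m) + w - 1L)
    which(grepl("^[ACGT]+$", wins)) - 1L
  })
  if (any(lengths(winlist) == 0L))
    stop("a flank has no N-free window of the motif width", call. = FALSE)

  ## seed ranking by coverage: how well (identical positions of the best
  ## window per sequence) each enumerated width-mer is echoed across all
  ## sequences; ties broken lexicographically for determinism
  allw <- unique(unlist(winlist, use.names = FALSE))
  wmat <- do.call(rbind, strsplit(allw, "", fixed = TRUE))
  seqmats <- lapply(winlist, function(wins)
    do.call(rbind, strsplit(wins, "", fixed = TRUE)))
  coverage <- vapply(seq_along(allw), function(k) {
    seedRow <- wmat[k, ]
    sum(vapply(seqmats, function(wm)
      max(rowSums(wm == rep(seedRow, each = nrow(wm)))), numeric(1L)))
  }, numeric(1L))
  ord <- order(-coverage, allw)
  seeds <- allw[ord[seq_len(min(nStarts, length(allw)))]]

  fits <- lapply(seeds, function(sd)
    .zoopsEM(winlist, sd, background, pseudocount, tol, maxIter))

  ## materialise each fit (PWM, accepted sites, approximate E-value) and,
  ## as MEME does, report the starting point whose fitted model is most
  ## significant; the objective breaks exact ties
  mat <- lapply(fits, function(f)
    .materialiseFit(f, winlist, offlist, background, pseudocount,
                    minPosterior, nSeeds = length(allw), w = w))
  ev <- vapply(mat, function(m) m$evalue, numeric(1L))
  ll <- vapply(fits, function(f) f$logLik, numeric(1L))
  best <- order(ev, -ll)[1L]
  fit <- fits[[best]]
  sites <- mat[[best]]$sites
  pwm <- mat[[best]]$pwm
  evalue <- mat[[best]]$evalue

  list(pwm = pwm, sites = sites, evalue = evalue, gamma = fit$gamma,
       logLik = fit$logLik, logLikTrace = fit$trace,
       consensus = motifConsensus(pwm), nStarts = length(seeds),
       converged = fit$converged, seed = seed)
}

## turn one converged EM run into (PWM, accepted sites, approximate
## E-value); significance: 2 n ln2 * IC against its ~chi^2_{3w} null,
## normal-approximated, Bonferroni-scaled by the number of enumerated
## starting points
.materialiseFit <- function(fit, winlist, offlist, background,
                            pseudocount, minPosterior, nSeeds, w) {
  sites <- data.frame(seq = integer(), offset = integer(),
                      site = character(), posterior = numeric(),
                      stringsAsFactors = FALSE)
  for (i in seq_along(winlist)) {
    z <- fit$z[[i]]
    if (!length(z)) next
    ## acceptance is by the sequence-level posterior P(site present) =
    ## sum of window posteriors, so ties between identical windows (as
    ## in periodic flanks) do not dilute acceptance; the best window
    ## gives the reported location
    j <- which.max(z)
    if (sum(z) >= minPosterior)
      sites <- rbind(sites, data.frame(
        seq = i, offset = offlist[[i]][j], site = winlist[[i]][j],
        posterior = sum(z), stringsAsFactors = FALSE))
  }
  pwm <- new("MotifPWM", probs = fit$probs, background = background,
             pseudocount = pseudocount, nsites = max(fit$nsites, 1e-6))
  ic <- informationContent(pwm)
  neff <- max(nrow(sites), 2L)
  stat <- 2 * neff * log(2) * ic
  zval <- (stat - 3 * w) / sqrt(6 * w)
  list(pwm = pwm, sites = sites,
       evalue = nSeeds * pnorm(zval, lower.tail = FALSE))
}

## one EM run from a single seed width-mer.  winlist: per-sequence
## candidate windows (ACGT only, equal width).
.zoopsEM <- function(winlist, seedWord, background, pseudocount, tol,
                     maxIter) {
  w <- nchar(seedWord)
  nseq <- length(winlist)
  ## window base indices, precomputed: list of m_i x w integer matrices
  idxlist <- lapply(winlist, function(wins) {
    t(vapply(strsplit(wins, "", fixed = TRUE),
             function(ch) match(ch, .BASES), integer(w)))
  })
  ## init: the seed treated as one observed site plus one background
  ## pseudo-site
  sch <- match(strsplit(seedWord, "", fixed = TRUE)[[1L]], .BASES)
  probs <- matrix(rep(background, w), nrow = 4L,
                  dimnames = list(.BASES, NULL))
  probs <- probs / 2
  probs[cbind(sch, seq_len(w))] <- probs[cbind(sch, seq_len(w))] + 0.5
  gamma <- 0.5
  ## the all-background likelihood term is constant across iterations and
  ## is dropped from the tracked objective; monotonicity is unaffected
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  z <- NULL
  for (iter in seq_len(maxIter)) {
    lodd <- log(probs / background) # natural log for the likelihood
    ## E step
    z <- vector("list", nseq)
    llik <- 0
    for (i in seq_len(nseq)) {
      m <- idxlist[[i]]
      lr <- exp(rowSums(matrix(lodd[cbind(as.vector(m),
                                          rep(seq_len(w), each = nrow(m)))],
                               nrow = nrow(m))))
      mi <- nrow(m)
      num <- gamma / mi * lr
      denom <- (1 - gamma) + sum(num)
      z[[i]] <- num / denom
      llik <- llik + log(denom)
    }
    ## the M step maximises the pseudocount-penalised (MAP) objective, so
    ## that is the quantity EM provably ascends and the one traced
    obj <- llik + pseudocount * sum(background * log(probs))
    trace <- c(trace, obj)
    if (is.finite(prev) && abs(obj - prev) < tol) {
      converged <- TRUE
      break
    }
    prev <- obj
    ## M step
    counts <- matrix(0, nrow = 4L, ncol = w,
                     dimnames = list(.BASES, NULL))
    tot <- 0
    for (i in seq_len(nseq)) {
      m <- idxlist[[i]]
      zi <- z[[i]]
      tot <- tot + sum(zi)
      for (j in seq_len(w)) {
        counts[, j] <- counts[, j] +
          vapply(1:4, function(b) sum(zi[m[, j] == b]), numeric(1L))
      }
    }
    probs <- (counts + pseudocount * background) / (tot + pseudocount)
    gamma <- min(max(tot / nseq, 1e-6), 1 - 1e-6)
  }
  list(probs = probs, gamma = gamma, z = z,
       nsites = sum(vapply(z, sum, numeric(1L))),
       logLik = trace[length(trace)], trace = trace,
       converged = converged)
}

#' Train a paired 5'/3' flanking-motif model from a known-locus panel
#'
#' Runs \code{\link{discoverMotif}} separately on the upstream and
#' downstream flank sets of a panel of known unstable loci.  All panel
#' loci must share one repeat unit — motif discovery is done within a
#' unit category.  Acceptance thresholds default to the minimum log-odds
#' score among each motif's accepted training sites, reproducing the
#' "motif found in most training flanks" behaviour at scan time.
#'
#' @param knownLoci \code{DataFrame}/\code{data.frame} as returned by
#'   \code{\link{readKnownLoci}}.
#' @param motifWidth motif width.
#' @param nStarts,seed,pseudocount forwarded to
#'   \code{\link{discoverMotif}}.
#' @return \code{\linkS4class{MotifModel}}.
#' @export
trainMotifModel <- function(knownLoci, motifWidth = 11L, nStarts = 10L,
                            seed = 1L, pseudocount = 0.25) {
  kl <- as.data.frame(knownLoci)
  if (nrow(kl) < 2L)
    stop("need at least 2 known loci to train a model", call. = FALSE)
  units <- unique(kl$unit)
  if (length(units) != 1L) {
    off <- kl$locus_id[kl$unit != units[1L]][1L]
    stop("known loci mix repeat-unit categories (locus '", off,
         "' has unit ", kl$unit[kl$locus_id == off][1L],
         ", expected ", units[1L],
         "); train one model per unit category", call. = FALSE)
  }
  fit5 <- discoverMotif(kl$upstream_flank, motifWidth = motifWidth,
                        nStarts = nStarts, seed = seed,
                        pseudocount = pseudocount)
  fit3 <- discoverMotif(kl$downstream_flank, motifWidth = motifWidth,
                        nStarts = nStarts, seed = seed + 1L,
                        pseudocount = pseudocount)
  thr5 <- min(vapply(fit5$sites$site, function(s)
    logOddsScore(fit5$pwm, s), numeric(1L)))
  thr3 <- min(vapply(fit3$sites$site, function(s)
    logOddsScore(fit3$pwm, s), numeric(1L)))
  if (!nrow(fit5$sites) || !nrow(fit3$sites))
    stop("motif discovery accepted no training sites on one flank side; ",
         "no usable model (this mirrors panels for which no significant ",
         "motif exists)", call. = FALSE)
  new("MotifModel", pwm5p = fit5$pwm, pwm3p = fit3$pwm,
      threshold5p = thr5, threshold3p = thr3,
      evalue5p = fit5$evalue, evalue3p = fit3$evalue,
      unit = units[1L])
}
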