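#' Generate a synthetic genome with planted tandem repeats
#'
#' Builds contigs of i.i.d. background bases and writes the requested
#' repeat tracts into them, optionally embedding exact motif consensus
#' sequences inside the 25-nt flanks, so every downstream stage can be
#' checked against recorded ground truth.  Planted tracts are forced to
#' be maximal (the unit-length windows adjacent to a tract are mutated
#' away from the unit if the background happened to extend it), tract
#' placements keep at least \code{flankLen + nchar(motif5p)} nucleotides
#' between plants and \code{flankLen} to each contig edge, and the
#' generator verifies by re-scanning that the planted loci are exactly
#' the loci a scan recovers — an error asks for a different seed in the
#' (vanishingly unlikely) case a spontaneous run appears.
#'
#' Everything is a pure function of the arguments including \code{seed}.
#'
#' @param contigLengths named integer vector, one element per contig.
#' @param plants \code{data.frame} with columns \code{unit},
#'   \code{n_units}, \code{with_motifs} (logical), \code{contig} and
#'   optionally \code{position} (1-based tract start; \code{NA} =
#'   place randomly).
#' @param motif5p,motif3p consensus sequences embedded in the upstream /
#'   downstream flank of each \code{with_motifs} plant, at a random
#'   offset.
#' @param baseFreqs named background base frequencies.
#' @param flankLen flank width the truth is recorded for.
#' @param seed integer RNG seed.
#' @return list with \code{genome} (\code{DNAStringSet}) and
#'   \code{truth} (\code{GRanges} of planted loci with metadata
#'   \code{unit}, \code{n_units}, \code{with_motifs},
#'   \code{motif5p_offset}, \code{motif3p_offset} — 0-based offsets of
#'   the embedded motifs within their flank, \code{NA} when absent).
#' @examples
#' plants <- data.frame(unit = "CTTT", n_units = 12, with_motifs = TRUE,
#'                      contig = "c1", position = NA)
#' g <- generateGenome(c(c1 = 2000L), plants, "GCGCATATGCG",
#'                     "TTGACGTCAAG", seed = 7)
#' g$truth
#' @export
generateGenome <- function(contigLengths, plants,
                           motif5p = "GCGCATATGCG",
                           motif3p = "TTGACGTCAAG",
                           baseFreqs = c(A = 0.25, C = 0.25, G = 0.25,
                                         T = 0.25),
                           flankLen = 25L, seed = 1L) {
  if (is.null(names(contigLengths)) || any(!nzchar(names(contigLengths))))
    stop("'contigLengths' must be named", call. = FALSE)
  baseFreqs <- .normBaseFreqs(baseFreqs)
  plants <- as.data.frame(plants)
  if (nrow(plants)) {
    plants$unit <- vapply(plants$unit, checkRepeatUnit, character(1L))
    if (!all(plants$contig %in% names(contigLengths)))
      stop("plant contig not in 'contigLengths'", call. = FALSE)
    if (is.null(plants$position)) plants$position <- NA_integer_
    for (m in c(motif5p, motif3p))
      if (!grepl("^[ACGT]+$", m))
        stop("motifs must be A/C/G/T strings", call. = FALSE)
    if (any(plants$with_motifs) &&
        flankLen < max(nchar(motif5p), nchar(motif3p)))
      stop("flankLen too small to embed the motifs", call. = FALSE)
  }
  set.seed(seed)
  sep <- flankLen + nchar(motif5p)
  seqs <- lapply(contigLengths, function(L)
    strsplit(.randomBases(L, baseFreqs), "", fixed = TRUE)[[1L]])
  truth <- list()
  for (cg in names(contigLengths)) {
    p <- plants[plants$contig == cg, , drop = FALSE]
    if (nrow(p) == 0L) next
    L <- contigLengths[[cg]]
    tractLen <- nchar(p$unit) * p$n_units
    ## resolve positions: fixed ones first, then random placement with
    ## the separation rule
    pos <- as.integer(p$position)
    for (i in order(is.na(pos))) {
      lo <- flankLen + 1L
      hi <- L - flankLen - tractLen[i] + 1L
      if (hi < lo)
        stop("plant ", i, " does not fit in contig ", cg, call. = FALSE)
      if (is.na(pos[i])) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          cand <- sample(lo:hi, 1L)
          if (.farEnough(cand, tractLen[i], pos, tractLen, sep)) {
            pos[i] <- cand
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place plant ", i, " in contig ", cg,
               " without violating the separation rule", call. = FALSE)
      } else {
        if (pos[i] < lo || pos[i] + tractLen[i] - 1L > L - flankLen)
          stop("fixed plant position leaves no room for flanks",
               call. = FALSE)
        if (!.farEnough(pos[i], tractLen[i], pos[-i], tractLen[-i], sep))
          stop("planted loci overlap or violate the separation rule",
               call. = FALSE)
      }
    }
    ch <- seqs[[cg]]
    off5 <- rep(NA_integer_, nrow(p))
    off3 <- rep(NA_integer_, nrow(p))
    for (i in seq_len(nrow(p))) {
      a <- pos[i]
      b <- a + tractLen[i] - 1L
      ch[a:b] <- strsplit(strrep(p$unit[i], p$n_units[i]), "",
                          fixed = TRUE)[[1L]]
      if (isTRUE(p$with_motifs[i])) {
        off5[i] <- sample.int(flankLen - nchar(motif5p) + 1L, 1L) - 1L
        s5 <- a - flankLen + off5[i]
        ch[s5:(s5 + nchar(motif5p) - 1L)] <-
          strsplit(motif5p, "", fixed = TRUE)[[1L]]
        off3[i] <- sample.int(flankLen - nchar(motif3p) + 1L, 1L) - 1L
        s3 <- b + 1L + off3[i]
        ch[s3:(s3 + nchar(motif3p) - 1L)] <-
          strsplit(motif3p, "", fixed = TRUE)[[1L]]
      }
    }
    ## enforce maximality: the unit-length window butting each tract end
    ## must not equal the unit (mutate one base away if it does)
    for (i in seq_len(nrow(p))) {
      k <- nchar(p$unit[i])
      a <- pos[i]
      b <- a + tractLen[i] - 1L
      u <- strsplit(p$unit[i], "", fixed = TRUE)[[1L]]
      if (a - k >= 1L && identical(ch[(a - k):(a - 1L)], u))
        ch[a - 1L] <- setdiff(.BASES, u[k])[1L]
      if (b + k <= L && identical(ch[(b + 1L):(b + k)], u))
        ch[b + 1L] <- setdiff(.BASES, u[1L])[1L]
    }
    seqs[[cg]] <- ch
    truth[[cg]] <- GRanges(cg, IRanges(pos, pos + tractLen - 1L),
                           strand = "+", unit = p$unit,
                           n_units = as.integer(p$n_units),
                           with_motifs = as.logical(p$with_motifs),
                           motif5p_offset = off5, motif3p_offset = off3)
  }
  genome <- DNAStringSet(vapply(seqs, paste, character(1L),
                                collapse = ""))
  names(genome) <- names(contigLengths)
  truthGr <- if (length(truth))
    sort(suppressWarnings(do.call(c, unname(truth))),
         ignore.strand = TRUE)
  else GRanges()
  GenomeInfoDb::seqlevels(truthGr) <- names(contigLengths)
  ## self-check: scanning must recover exactly the planted loci
  if (length(truthGr)) {
    for (u in unique(mcols(truthGr)$unit)) {
      want <- truthGr[mcols(truthGr)$unit == u]
      minU <- min(mcols(want)$n_units)
      got <- scanGenome(genome, u, minUnits = minU)
      if (length(got) != length(want) ||
          any(start(got) != start(want)) || any(end(got) != end(want)))
        stop("generated genome contains repeat runs beyond the planted ",
             "truth for unit ", u, "; use a different seed", call. = FALSE)
    }
  }
  list(genome = genome, truth = truthGr)
}

.farEnough <- function(cand, len, pos, lens, sep) {
  keep <- !is.na(pos)
  pos <- pos[keep]
  lens <- lens[keep]
  if (length(pos) == 0L) return(TRUE)
  all(cand + len - 1L + sep < pos | pos + lens - 1L + sep < cand)
}

#' Generate a motif-training flank set with planted sites
#'
#' Emulates the situation motif discovery faces: \code{nSeqs} background
#' flanks, a single fixed-width motif planted in
#' \code{round(occurrence * nSeqs)} of them (which ones is drawn at
#' random), each planted site carrying \code{mutationsPerSite} random
#' point mutations at distinct positions.
#'
#' @param nSeqs number of flanks (default 7).
#' @param flankLen flank length (default 25).
#' @param motif the planted consensus (length <= \code{flankLen}).
#' @param occurrence fraction of flanks that receive a site (default
#'   6/7).
#' @param mutationsPerSite point mutations per planted site.
#' @param baseFreqs background base frequencies.
#' @param seed integer RNG seed.
#' @return list with \code{flanks} (character vector) and \code{truth}
#'   (\code{data.frame}: \code{seq}, \code{planted}, \code{offset}
#'   0-based or \code{NA}, \code{site} as planted after mutation).
#' @export
generateFlankSet <- function(nSeqs = 7L, flankLen = 25L, motif,
                             occurrence = 6 / 7, mutationsPerSite = 0L,
                             baseFreqs = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                             seed = 1L) {
  nSeqs <- .assertScalarCount(nSeqs, "nSeqs", min = 1L)
  flankLen <- .assertScalarCount(flankLen, "flankLen", min = 1L)
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop("'motif' must be an A/C/G/T string", call. = FALSE)
  if (nchar(motif) > flankLen)
    stop("'motif' longer than the flank", call. = FALSE)
  if (occurrence < 0 || occurrence > 1)
    stop("'occurrence' must be in [0, 1]", call. = FALSE)
  mutationsPerSite <- .assertScalarCount(mutationsPerSite,
                                         "mutationsPerSite", min = 0L)
  if (mutationsPerSite > nchar(motif))
    stop("'mutationsPerSite' exceeds the motif length", call. = FALSE)
  baseFreqs <- .normBaseFreqs(baseFreqs)
  set.seed(seed)
  flanks <- vapply(seq_len(nSeqs), function(i)
    .randomBases(flankLen, baseFreqs), character(1L))
  nPlant <- round(occurrence * nSeqs)
  which_ <- sort(sample.int(nSeqs, nPlant))
  truth <- data.frame(seq = seq_len(nSeqs), planted = FALSE,
                      offset = NA_integer_, site = NA_character_,
                      stringsAsFactors = FALSE)
  w <- nchar(motif)
  for (i in which_) {
    site <- strsplit(motif, "", fixed = TRUE)[[1L]]
    if (mutationsPerSite > 0L) {
      at <- sample.int(w, mutationsPerSite)
      for (j in at)
        site[j] <- sample(setdiff(.BASES, site[j]), 1L)
    }
    off <- sample.int(flankLen - w + 1L, 1L) - 1L
    substr(flanks[i], off + 1L, off + w) <- paste(site, collapse = "")
    truth$planted[i] <- TRUE
    truth$offset[i] <- off
    truth$site[i] <- paste(site, collapse = "")
  }
  list(flanks = flanks, truth = truth)
}

#' Generate a synthetic repeat-count table with planted instability
#'
#' Statistical structure mirrors published marker tables: each marker
#' gets a published unit count drawn from 14–18; each animal's normal
#' count deviates from it with probability
#' \code{pNormalInstability}; each tumor count deviates from its
#' matched normal with probability \code{pEmast}.  Deviations are drawn
#' from \code{deltaDistribution} over unit shifts \{-2, -1, +1, +2\}.
#'
#' @param nMarkers,nMice table dimensions.
#' @param pNormalInstability,pEmast planting probabilities in [0, 1].
#' @param deltaDistribution named numeric over \code{"-2"}, \code{"-1"},
#'   \code{"1"}, \code{"2"}; normalised internally.
#' @param seed integer RNG seed.
#' @return list with \code{experiment}
#'   (\code{\linkS4class{RepeatCountExperiment}}) and \code{truth}
#'   (list of logical marker-by-mouse matrices \code{normalEvents},
#'   \code{emastEvents}).
#' @examples
#' g <- generateCountTable(5, 7, 0.2, 0.3, seed = 42)
#' identical(unname(lengths(callEmast(g$experiment))),
#'           unname(rowSums(g$truth$emastEvents)))
#' @export
generateCountTable <- function(nMarkers, nMice, pNormalInstability,
                               pEmast,
                               deltaDistribution = c("-2" = 0.1,
                                                     "-1" = 0.4,
                                                     "1" = 0.4,
                                                     "2" = 0.1),
                               seed = 1L) {
  nMarkers <- .assertScalarCount(nMarkers, "nMarkers", min = 1L)
  nMice <- .assertScalarCount(nMice, "nMice", min = 1L)
  stopifnot(pNormalInstability >= 0, pNormalInstability <= 1,
            pEmast >= 0, pEmast <= 1)
  deltas <- as.integer(names(deltaDistribution))
  if (any(is.na(deltas)) || any(deltas == 0L))
    stop("'deltaDistribution' must be named by non-zero integer shifts",
         call. = FALSE)
  pd <- deltaDistribution / sum(deltaDistribution)
  set.seed(seed)
  markers <- sprintf("M%02d", seq_len(nMarkers))
  mice <- as.character(seq_len(nMice))
  pub <- sample(14:18, nMarkers, replace = TRUE)
  normalEvents <- matrix(rbinom(nMarkers * nMice, 1L,
                                pNormalInstability) == 1L,
                         nMarkers, nMice,
                         dimnames = list(markers, mice))
  emastEvents <- matrix(rbinom(nMarkers * nMice, 1L, pEmast) == 1L,
                        nMarkers, nMice,
                        dimnames = list(markers, mice))
  shift <- function(n) sample(deltas, n, replace = TRUE, prob = pd)
  normal <- matrix(rep(pub, times = nMice), nMarkers, nMice,
                   dimnames = list(markers, mice))
  normal[normalEvents] <- normal[normalEvents] + shift(sum(normalEvents))
  tumor <- normal
  ## shifts are non-zero, so planted events are exactly the cells where
  ## tumor differs from normal
  tumor[emastEvents] <- tumor[emastEvents] + shift(sum(emastEvents))
  if (any(normal < 1L) || any(tumor < 1L))
    stop("'deltaDistribution' shifts drove a count below 1",
         call. = FALSE)
  rce <- RepeatCountExperiment(normal, tumor, publishedUnits = pub,
                               algorithmIdentified = rep(TRUE, nMarkers))
  list(experiment = rce,
       truth = list(normalEvents = normalEvents,
                    emastEvents = emastEvents))
}
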