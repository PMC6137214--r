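#' Filter flanked loci by dual-flank motif presence
#'
#' The decision step of the discovery chain: a locus survives exactly
#' when its 5' flank's best window score reaches the model's 5'
#' threshold \emph{and} its 3' flank's best score reaches the 3'
#' threshold.  Surviving loci gain the match annotations and a
#' \code{combined_score} (the sum of the two best window scores, in
#' bits).  Loci with incomplete flanks cannot be motif-checked on both
#' sides and are dropped by default; flanks shorter than the motif width
#' never pass.
#'
#' @param loci \code{GRanges} from \code{\link{extractFlanks}}.
#' @param model \code{\linkS4class{MotifModel}}.
#' @param requireCompleteFlanks drop loci whose flanks are truncated by a
#'   contig edge (default \code{TRUE}).
#' @return \code{GRanges} subset of \code{loci} with metadata columns
#'   \code{offset5p}, \code{score5p}, \code{match5p}, \code{offset3p},
#'   \code{score3p}, \code{match3p}, \code{combined_score} added.
#' @seealso \code{\link{annotateSimilarity}}, \code{\link{rankCandidates}},
#'   \code{\link{selectCandidates}}
#' @export
filterByMotifs <- function(loci, model, requireCompleteFlanks = TRUE) {
  stopifnot(is(loci, "GRanges"), is(model, "MotifModel"))
  need <- c("upstream_flank", "downstream_flank", "complete_flanks")
  if (!all(need %in% colnames(mcols(loci))))
    stop("'loci' must carry flank columns; run extractFlanks() first",
         call. = FALSE)
  if (requireCompleteFlanks)
    loci <- loci[mcols(loci)$complete_flanks]
  n <- length(loci)
  if (n == 0L) return(.emptyCandidates(loci))
  m5 <- lapply(mcols(loci)$upstream_flank, scanFlank, pwm = model@pwm5p)
  m3 <- lapply(mcols(loci)$downstream_flank, scanFlank, pwm = model@pwm3p)
  ok5 <- vapply(m5, function(m) !is.null(m) && m$score >= model@threshold5p,
                logical(1L))
  ok3 <- vapply(m3, function(m) !is.null(m) && m$score >= model@threshold3p,
                logical(1L))
  keep <- ok5 & ok3
  out <- loci[keep]
  m5 <- m5[keep]
  m3 <- m3[keep]
  mcols(out)$offset5p <- vapply(m5, `[[`, integer(1L), "offset")
  mcols(out)$score5p <- vapply(m5, `[[`, numeric(1L), "score")
  mcols(out)$match5p <- vapply(m5, `[[`, character(1L), "match")
  mcols(out)$offset3p <- vapply(m3, `[[`, integer(1L), "offset")
  mcols(out)$score3p <- vapply(m3, `[[`, numeric(1L), "score")
  mcols(out)$match3p <- vapply(m3, `[[`, character(1L), "match")
  mcols(out)$combined_score <- mcols(out)$score5p + mcols(out)$score3p
  out
}

.emptyCandidates <- function(loci) {
  out <- loci[0L]
  mcols(out)$offset5p <- integer()
  mcols(out)$score5p <- numeric()
  mcols(out)$match5p <- character()
  mcols(out)$offset3p <- integer()
  mcols(out)$score3p <- numeric()
  mcols(out)$match3p <- character()
  mcols(out)$combined_score <- numeric()
  out
}

#' Percent similarity between two repeat regions
#'
#' Global (Needleman–Wunsch) alignment with match +1, mismatch -1, gap
#' -2 and no end-gap forgiveness; similarity is 100 times the number of
#' identical alignment columns divided by the alignment length.  Among
#' score-optimal alignments the one maximising identical columns (then
#' minimising length) is used, which makes the value symmetric in its
#' arguments; remaining traceback ties prefer diagonal, then up, then
#' left.  Regions are conventionally \code{upstream flank + repeat tract
#' + downstream flank}.
#'
#' @param a,b non-empty character strings.
#' @param details return the full alignment (\code{list} with
#'   \code{score}, \code{matches}, \code{length}, \code{aligned_a},
#'   \code{aligned_b}, \code{similarity}) instead of the bare number.
#' @return numeric in [0, 100] (or a list when \code{details = TRUE}).
#' @examples
#' percentSimilarity("ACGTACGT", "ACGTACGT") # 100
#' @export
percentSimilarity <- function(a, b, details = FALSE) {
  if (!nzchar(a) || !nzchar(b))
    stop("both regions must be non-empty", call. = FALSE)
  r <- .nwAlign(toupper(a), toupper(b))
  r$similarity <- 100 * r$matches / r$length
  if (details) r else r$similarity
}

## candidate region = 5' flank + tract + 3' flank
.candidateRegions <- function(candidates, genome) {
  chrom <- as.character(seqnames(candidates))
  tract <- vapply(seq_along(candidates), function(i) {
    s <- genome[[chrom[i]]][start(candidates)[i]:end(candidates)[i]]
    if (as.character(strand(candidates))[i] == "-")
      s <- reverseComplement(s)
    as.character(s)
  }, character(1L))
  paste0(mcols(candidates)$upstream_flank, tract,
         mcols(candidates)$downstream_flank)
}

.knownRegions <- function(panel) {
  p <- as.data.frame(panel)
  paste0(p$upstream_flank, strrep(p$unit, p$n_units), p$downstream_flank)
}

#' Annotate candidates with similarity to a known-locus panel
#'
#' Computes \code{\link{percentSimilarity}} between each candidate's
#' region (5' flank + repeat tract + 3' flank) and every panel member's
#' region, keeping the best value and the id of the best panel locus
#' (ties: first panel entry in input order).
#'
#' @param candidates \code{GRanges} from \code{\link{filterByMotifs}}.
#' @param panel known-locus panel (see \code{\link{readKnownLoci}});
#'   must be non-empty.
#' @param genome the \code{DNAStringSet} the candidates live on (used to
#'   fetch the repeat tract).
#' @return \code{candidates} with \code{best_similarity_pct} and
#'   \code{best_similarity_locus} metadata columns added.
#' @export
annotateSimilarity <- function(candidates, panel, genome) {
  stopifnot(is(candidates, "GRanges"))
  panel <- as.data.frame(panel)
  if (nrow(panel) == 0L)
    stop("known-locus panel is empty", call. = FALSE)
  if (is.character(genome)) genome <- DNAStringSet(genome)
  known <- .knownRegions(panel)
  if (length(candidates) == 0L) {
    mcols(candidates)$best_similarity_pct <- numeric()
    mcols(candidates)$best_similarity_locus <- character()
    return(candidates)
  }
  regions <- .candidateRegions(candidates, genome)
  bestPct <- numeric(length(regions))
  bestId <- character(length(regions))
  for (i in seq_along(regions)) {
    sims <- vapply(known, function(k) percentSimilarity(regions[i], k),
                   numeric(1L))
    j <- which.max(sims) # first on ties
    bestPct[i] <- sims[j]
    bestId[i] <- panel$locus_id[j]
  }
  mcols(candidates)$best_similarity_pct <- bestPct
  mcols(candidates)$best_similarity_locus <- bestId
  candidates
}

#' Rank candidates by combined PWM score percentile
#'
#' Percentile of the combined score within the candidate set, computed
#' as \code{100 * rank / n} with average ranks on ties; a candidate is
#' in the top decile when its percentile strictly exceeds 90 (with n
#' distinct scores that is the top tenth of the set, e.g. exactly 1 of
#' 10).
#'
#' @param candidates non-empty \code{GRanges} carrying
#'   \code{combined_score}.
#' @return \code{candidates} with \code{score_percentile} and
#'   \code{top_decile} metadata columns added.
#' @export
rankCandidates <- function(candidates) {
  stopifnot(is(candidates, "GRanges"))
  if (length(candidates) == 0L) {
    mcols(candidates)$score_percentile <- numeric()
    mcols(candidates)$top_decile <- logical()
    return(candidates)
  }
  s <- mcols(candidates)$combined_score
  if (is.null(s))
    stop("candidates lack 'combined_score'; run filterByMotifs() first",
         call. = FALSE)
  pct <- 100 * rank(s, ties.method = "average") / length(s)
  mcols(candidates)$score_percentile <- pct
  mcols(candidates)$top_decile <- pct > 90
  candidates
}

#' Select the reportable candidate panel
#'
#' Final selection step: keep candidates at least
#' \code{minSimilarityPct} percent similar to the known panel and at
#' least \code{minUnits} repeat units long, sorted by contig and start.
#' Selected loci are named \code{C<contig>R<n_units>} (chromosome number
#' + repeat length, any leading "chr" stripped), with a numeric
#' \code{.k} suffix when several selected loci share a name.
#'
#' @param candidates annotated \code{GRanges} (after
#'   \code{\link{annotateSimilarity}}).
#' @param minSimilarityPct similarity threshold, percent (default 85).
#' @param minUnits minimum repeat-unit count (default 13).
#' @return sorted, named \code{GRanges}.
#' @export
selectCandidates <- function(candidates, minSimilarityPct = 85,
                             minUnits = 13L) {
  stopifnot(is(candidates, "GRanges"))
  m <- mcols(candidates)
  if (length(candidates) &&
      (is.null(m$best_similarity_pct) || is.null(m$n_units)))
    stop("candidates must carry 'best_similarity_pct' and 'n_units'",
         call. = FALSE)
  keep <- if (length(candidates))
    m$best_similarity_pct >= minSimilarityPct & m$n_units >= minUnits
  else logical(0)
  out <- sort(candidates[keep], ignore.strand = TRUE)
  names(out) <- locusNames(out)
  out
}

#' Generate panel-style locus names
#'
#' \code{C<contig>R<n_units>} with a leading "chr"/"Chr" prefix stripped
#' from the contig; when several loci collide on one name they are
#' disambiguated with \code{.1}, \code{.2}, ... in input order.
#'
#' @param loci \code{GRanges} with an \code{n_units} metadata column.
#' @return character vector of names.
#' @examples
#' gr <- GenomicRanges::GRanges(c("chr9", "chr18", "chr18"),
#'                              IRanges::IRanges(c(1, 1, 100), width = 68))
#' gr$n_units <- c(17L, 14L, 14L)
#' locusNames(gr)
#' @export
locusNames <- function(loci) {
  if (length(loci) == 0L) return(character())
  contig <- sub("^[Cc]hr", "", as.character(seqnames(loci)))
  n <- mcols(loci)$n_units
  if (is.null(n)) n <- width(loci)
  base <- paste0("C", contig, "R", n)
  dup <- ave(seq_along(base), base, FUN = seq_along)
  many <- base %in% base[duplicated(base)]
  ifelse(many, paste0(base, ".", dup), base)
}

#' Run the full candidate-discovery pipeline
#'
#' Scan, flank, motif-filter, similarity-annotate, rank and select in one
#' call — the programmatic equivalent of the \code{pipeline} CLI command.
#'
#' @param genome \code{DNAStringSet} or path to a FASTA file.
#' @param model \code{\linkS4class{MotifModel}} or path to a model JSON.
#' @param panel known-locus panel (object or TSV path).
#' @param unit repeat unit (default \code{"CTTT"}).
#' @param minUnits minimum unit count for the scan (default 10).
#' @param flankLen flank width (default 25).
#' @param scanReverse scan the reverse complement too.
#' @param minSimilarityPct,minUnitsSelect selection thresholds
#'   (defaults 85 and 13).
#' @param requireCompleteFlanks forwarded to
#'   \code{\link{filterByMotifs}}.
#' @return named, sorted \code{GRanges}: the selected candidate panel
#'   with all annotation columns.  Attributes \code{"n_scanned"} and
#'   \code{"n_filtered"} record the funnel sizes (loci found by the raw
#'   scan, and loci surviving the dual-motif filter).
#' @export
runCandidatePipeline <- function(genome, model, panel, unit = "CTTT",
                                 minUnits = 10L, flankLen = 25L,
                                 scanReverse = FALSE,
                                 minSimilarityPct = 85,
                                 minUnitsSelect = 13L,
                                 requireCompleteFlanks = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- readGenome(genome)
  if (is.character(model))
    model <- readMotifModel(model)
  if (is.character(panel) && length(panel) == 1L)
    panel <- readKnownLoci(panel, flankLen = flankLen)
  loci <- scanGenome(genome, unit, minUnits = minUnits,
                     scanReverse = scanReverse)
  flanked <- extractFlanks(loci, genome, flankLen = flankLen)
  cand <- filterByMotifs(flanked, model,
                         requireCompleteFlanks = requireCompleteFlanks)
  cand <- annotateSimilarity(cand, panel, genome)
  if (length(cand)) cand <- rankCandidates(cand)
  sel <- selectCandidates(cand, minSimilarityPct = minSimilarityPct,
                          minUnits = minUnitsSelect)
  attr(sel, "n_scanned") <- length(loci)
  attr(sel, "n_filtered") <- length(cand)
  sel
}
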