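#' Find maximal perfect tandem repeats of one unit
#'
#' Scans a single sequence for every maximal run of \code{unit} repeated
#' head-to-tail at least \code{minUnits} times.  Matching is exact:
#' interruptions are not tolerated (one mismatching base ends a run),
#' \code{N} never matches, only complete unit copies are counted (a
#' trailing partial unit is excluded), and rotated phases of the unit
#' (e.g. \code{TTTC} when the unit is \code{CTTT}) are not reported — the
#' unit is matched verbatim on the given strand only.  Maximality means a
#' reported run can be extended by a full unit copy on neither side.
#'
#' @param sequence single character string or \code{DNAString} over
#'   A/C/G/T/N.
#' @param unit repeat unit, validated by \code{\link{checkRepeatUnit}}.
#' @param minUnits minimum number of complete unit copies (>= 2).
#' @param seqname contig name used in the returned \code{GRanges}.
#' @return \code{GRanges} (1-based coordinates, as all Bioconductor
#'   ranges) in ascending start order with metadata columns \code{unit}
#'   and \code{n_units}; strand \code{"+"}.
#' @examples
#' findTandemRepeats("AACTTTCTTTGG", "CTTT", minUnits = 2)
#' @seealso \code{\link{scanGenome}}, \code{\link{extractFlanks}}
#' @export
findTandemRepeats <- function(sequence, unit, minUnits = 10L,
                              seqname = "seq") {
  unit <- checkRepeatUnit(unit)
  minUnits <- .assertScalarCount(minUnits, "minUnits", min = 2L)
  s <- toupper(as.character(sequence))
  k <- nchar(unit)
  ## a greedy counted regex yields exactly the maximal perfect runs:
  ## leftmost scanning gives left-maximality, greedy repetition gives
  ## right-maximality in complete units
  pat <- sprintf("(?:%s){%d,}", unit, minUnits)
  hits <- gregexpr(pat, s, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    gr <- GRanges()
    GenomeInfoDb::seqlevels(gr) <- seqname
    mcols(gr)$unit <- character()
    mcols(gr)$n_units <- integer()
    return(gr)
  }
  st <- as.integer(hits)
  len <- attr(hits, "match.length")
  n_units <- len %/% k
  gr <- GRanges(seqname, IRanges(st, st + n_units * k - 1L), strand = "+")
  mcols(gr)$unit <- unit
  mcols(gr)$n_units <- n_units
  gr
}

#' Scan a genome for tandem repeats of one unit
#'
#' Applies \code{\link{findTandemRepeats}} to every contig.  The scanner
#' reads one strand; with \code{scanReverse = TRUE} it additionally scans
#' the reverse complement of each contig and reports those runs in
#' forward coordinates with strand \code{"-"} (a \code{(AAAG)n} tract on
#' the forward strand is a \code{(CTTT)n} tract on the other strand).
#'
#' @param genome \code{DNAStringSet} (see \code{\link{readGenome}}) or
#'   named character vector; must be non-empty.
#' @param unit repeat unit.
#' @param minUnits minimum number of complete unit copies.
#' @param scanReverse also scan the reverse complement.
#' @return \code{GRanges} with metadata columns \code{unit} (as given,
#'   i.e. the unit on the reported strand) and \code{n_units}; sorted by
#'   contig and start.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("CTTT", 12)))
#' scanGenome(g, "CTTT", minUnits = 10)
#' @export
scanGenome <- function(genome, unit, minUnits = 10L, scanReverse = FALSE) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  if (length(genome) == 0L)
    stop("'genome' must contain at least one sequence", call. = FALSE)
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("'genome' sequences must be named", call. = FALSE)
  unit <- checkRepeatUnit(unit)
  res <- list()
  for (i in seq_along(genome)) {
    nm <- names(genome)[i]
    fwd <- findTandemRepeats(genome[[i]], unit, minUnits, seqname = nm)
    res[[length(res) + 1L]] <- fwd
    if (scanReverse) {
      L <- length(genome[[i]])
      rc <- reverseComplement(genome[[i]])
      rev <- findTandemRepeats(rc, unit, minUnits, seqname = nm)
      if (length(rev)) {
        ## map [s, e] on the reverse complement to forward coordinates
        gr <- GRanges(nm, IRanges(L - end(rev) + 1L, L - start(rev) + 1L),
                      strand = "-")
        mcols(gr)$unit <- mcols(rev)$unit
        mcols(gr)$n_units <- mcols(rev)$n_units
        res[[length(res) + 1L]] <- gr
      }
    }
  }
  out <- suppressWarnings(do.call(c, res))
  GenomeInfoDb::seqlevels(out) <- names(genome)
  sort(out, ignore.strand = TRUE)
}

#' Attach fixed-width flanking sequences to repeat loci
#'
#' Extracts the \code{flankLen} nucleotides immediately upstream and
#' downstream of each locus (in forward-genome orientation for \code{+}
#' loci; for \code{-} loci the flanks are reverse-complemented and
#' swapped so that \code{upstream_flank} is always 5' of the repeat tract
#' on the strand that carries the unit).  Flanks truncated by a contig
#' edge are kept with \code{complete_flanks = FALSE}.
#'
#' @param loci \code{GRanges} from \code{\link{scanGenome}}.
#' @param genome the \code{DNAStringSet} the loci were found on.
#' @param flankLen flank width in nucleotides.
#' @return the input \code{GRanges} with metadata columns
#'   \code{upstream_flank}, \code{downstream_flank},
#'   \code{complete_flanks} added.
#' @export
extractFlanks <- function(loci, genome, flankLen = 25L) {
  stopifnot(is(loci, "GRanges"))
  if (is.character(genome)) genome <- DNAStringSet(genome)
  flankLen <- .assertScalarCount(flankLen, "flankLen", min = 1L)
  chrom <- as.character(seqnames(loci))
  bad <- !(chrom %in% names(genome))
  if (any(bad))
    stop("locus contig not present in genome: ", chrom[which(bad)[1L]],
         call. = FALSE)
  up <- character(length(loci))
  dn <- character(length(loci))
  complete <- logical(length(loci))
  for (i in seq_along(loci)) {
    s <- genome[[chrom[i]]]
    L <- length(s)
    a <- start(loci)[i]
    b <- end(loci)[i]
    if (a < 1L || b > L)
      stop("locus ", i, " exceeds contig ", chrom[i], " bounds",
           call. = FALSE)
    u0 <- max(1L, a - flankLen)
    upseq <- if (a > 1L) as.character(s[u0:(a - 1L)]) else ""
    d1 <- min(L, b + flankLen)
    dnseq <- if (b < L) as.character(s[(b + 1L):d1]) else ""
    if (as.character(strand(loci))[i] == "-") {
      tmp <- .revcomp(dnseq)
      dnseq <- .revcomp(upseq)
      upseq <- tmp
    }
    up[i] <- upseq
    dn[i] <- dnseq
    complete[i] <- nchar(upseq) == flankLen && nchar(dnseq) == flankLen
  }
  mcols(loci)$upstream_flank <- up
  mcols(loci)$downstream_flank <- dn
  mcols(loci)$complete_flanks <- complete
  loci
}

#' Repeat-length abundance spectrum
#'
#' Counts maximal repeat loci per contig for each exact unit count
#' between \code{minUnits} and \code{maxUnits}; longer loci are pooled in
#' an overflow bin.  Used to compare the abundance of, e.g., CTTT tracts
#' of 10–25 units across chromosomes or between genomes.
#'
#' @param genome \code{DNAStringSet}.
#' @param unit repeat unit.
#' @param minUnits,maxUnits inclusive bin range (\code{minUnits <=
#'   maxUnits}).
#' @param scanReverse forwarded to \code{\link{scanGenome}}.
#' @return \code{data.frame} with columns \code{contig}, \code{n_units}
#'   (integer, or \code{NA} for the overflow bin labelled in
#'   \code{bin}), \code{bin} (character, e.g. \code{"12"} or
#'   \code{">25"}) and \code{count}; the full contig-by-bin grid is
#'   present, zeros included.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = paste0(
#'   strrep("A", 30), strrep("CTTT", 12), strrep("A", 30))))
#' repeatLengthSpectrum(g, "CTTT", 10, 25)
#' @export
repeatLengthSpectrum <- function(genome, unit, minUnits = 10L,
                                 maxUnits = 25L, scanReverse = FALSE) {
  minUnits <- .assertScalarCount(minUnits, "minUnits", min = 2L)
  maxUnits <- .assertScalarCount(maxUnits, "maxUnits", min = 2L)
  if (minUnits > maxUnits)
    stop("'minUnits' must not exceed 'maxUnits'", call. = FALSE)
  if (is.character(genome)) genome <- DNAStringSet(genome)
  loci <- scanGenome(genome, unit, minUnits = minUnits,
                     scanReverse = scanReverse)
  bins <- c(as.character(minUnits:maxUnits), paste0(">", maxUnits))
  contigs <- names(genome)
  grid <- expand.grid(contig = contigs, bin = bins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_units <- suppressWarnings(as.integer(grid$bin))
  n <- mcols(loci)$n_units
  key <- ifelse(n > maxUnits, paste0(">", maxUnits), as.character(n))
  tab <- table(contig = as.character(seqnames(loci)), bin = key)
  grid$count <- 0L
  if (length(loci)) {
    idx <- cbind(match(grid$contig, rownames(tab)),
                 match(grid$bin, colnames(tab)))
    ok <- !is.na(idx[, 1L]) & !is.na(idx[, 2L])
    grid$count[ok] <- as.integer(tab[idx[ok, , drop = FALSE]])
  }
  grid[order(match(grid$contig, contigs), match(grid$bin, bins)),
       c("contig", "n_units", "bin", "count")]
}
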