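#' Read a genome from FASTA
#'
#' Reads a (optionally gzip-compressed, detected by content) multi-record
#' FASTA file into a \code{DNAStringSet}.  Soft-masked lowercase bases are
#' uppercased — masking case carries no information for repeat scanning —
#' while hard-masked \code{N} is kept and never matches a repeat unit.
#' Any character outside \code{{A,C,G,T,N}} (including IUPAC ambiguity
#' codes) is a parse error reported with the offending record and 1-based
#' sequence offset.
#'
#' @param path path to a FASTA file, plain or gzip.
#' @return \code{DNAStringSet}, one element per FASTA record, input order
#'   preserved, names taken from the first whitespace-delimited header
#'   token.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' readGenome(fa)
#' @seealso \code{\link{writeGenome}}, \code{\link{scanGenome}}
#' @export
readGenome <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  dropped <- FALSE
  x <- withCallingHandlers(
    readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        dropped <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (dropped)
    .reportBadFastaChar(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(names(x))))
    stop("malformed FASTA header: empty record id in ", path, call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  if (length(x)) {
    bad <- letterFrequency(x, "ACGTN") != width(x)
    if (any(bad)) {
      i <- which(bad)[1L]
      s <- as.character(x[[i]])
      off <- regexpr("[^ACGTN]", s)[1L]
      stop(sprintf(
        "illegal character '%s' in record '%s' at offset %d (only A/C/G/T/N allowed)",
        substr(s, off, off), names(x)[i], off), call. = FALSE)
    }
  }
  x
}

## locate the first character Biostrings refused to parse, so the error
## can name the record and offset (the parser itself only warns)
.reportBadFastaChar <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  rec <- ""
  off <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (startsWith(line, ">")) {
      rec <- sub("\\s.*$", "", sub("^>", "", line))
      off <- 0L
      next
    }
    hit <- regexpr("[^ACGTNacgtn]", line)[1L]
    if (hit > 0L)
      stop(sprintf(
        "illegal character '%s' in record '%s' at offset %d (only A/C/G/T/N allowed)",
        substr(line, hit, hit), rec, off + hit), call. = FALSE)
    off <- off + nchar(line)
  }
  stop("FASTA file ", path, " contains characters the parser rejected",
       call. = FALSE)
}

#' Write sequences to FASTA
#'
#' @param x \code{DNAStringSet} (or named character vector).
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(x, path, width = 70L) {
  if (is.character(x)) x <- DNAStringSet(x)
  writeXStringSet(x, path, width = width,
                  compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a known-locus panel
#'
#' Reads the reference panel of known unstable microsatellite loci used
#' for motif training and similarity ranking.  The tab-separated file must
#' have a header with columns \code{locus_id}, \code{unit},
#' \code{n_units}, \code{upstream_flank}, \code{downstream_flank}.
#' Flanks whose length differs from \code{flankLen} are kept but flagged
#' \code{flank_complete = FALSE}.
#'
#' @param path path to the panel TSV.
#' @param flankLen expected flank length in nucleotides.
#' @return \code{DataFrame} with the panel columns plus
#'   \code{flank_complete}.
#' @seealso \code{\link{trainMotifModel}}, \code{\link{annotateSimilarity}}
#' @export
readKnownLoci <- function(path, flankLen = 25L) {
  if (!file.exists(path))
    stop("known-locus file not found: ", path, call. = FALSE)
  d <- read.delim(path, header = TRUE, sep = "\t",
                  colClasses = "character", comment.char = "#")
  need <- c("locus_id", "unit", "n_units", "upstream_flank",
            "downstream_flank")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("known-locus file missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$n_units <- as.integer(d$n_units)
  if (any(is.na(d$n_units)) || any(d$n_units < 1))
    stop("'n_units' must be positive integers", call. = FALSE)
  d$unit <- toupper(d$unit)
  d$upstream_flank <- toupper(d$upstream_flank)
  d$downstream_flank <- toupper(d$downstream_flank)
  badf <- !grepl("^[ACGTN]*$", d$upstream_flank) |
          !grepl("^[ACGTN]*$", d$downstream_flank)
  if (any(badf))
    stop("non-ACGTN characters in flanks of locus ",
         d$locus_id[which(badf)[1L]], call. = FALSE)
  out <- DataFrame(d)
  out$flank_complete <- nchar(d$upstream_flank) == flankLen &
                        nchar(d$downstream_flank) == flankLen
  out
}

#' Write a known-locus panel
#'
#' @param panel data.frame/DataFrame with the columns produced by
#'   \code{\link{readKnownLoci}} (the \code{flank_complete} column is not
#'   written).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeKnownLoci <- function(panel, path) {
  cols <- c("locus_id", "unit", "n_units", "upstream_flank",
            "downstream_flank")
  d <- as.data.frame(panel)[, cols]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## TSV column order for candidate output; only columns actually present
## on the GRanges are emitted (plus the dual coordinate columns)
.CANDIDATE_COLS <- c("unit", "n_units", "complete_flanks",
                     "upstream_flank", "downstream_flank",
                     "offset5p", "score5p", "match5p",
                     "offset3p", "score3p", "match3p", "combined_score",
                     "best_similarity_pct", "best_similarity_locus",
                     "score_percentile", "top_decile")

#' Write repeat loci or candidates to TSV or BED
#'
#' TSV output reports coordinates both 0-based half-open (\code{start0},
#' \code{end0}) and 1-based inclusive (\code{start1}, \code{end1})
#' alongside every annotation column present.  BED output is 6-column
#' (0-based half-open); the score column is the combined PWM score mapped
#' to 0–1000 (via the score percentile when available, otherwise min–max
#' scaled over the written set).
#'
#' @param candidates \code{GRanges} from the scanning/candidate pipeline;
#'   locus names are taken from \code{names(candidates)} or generated with
#'   \code{\link{locusNames}}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"bed"}.
#' @return \code{path}, invisibly.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 140),
#'                              strand = "+")
#' gr$unit <- "CTTT"; gr$n_units <- 10L
#' writeCandidates(gr, tempfile(fileext = ".tsv"))
#' @seealso \code{\link{readCandidates}}
#' @export
writeCandidates <- function(candidates, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(is(candidates, "GRanges"))
  nm <- names(candidates)
  if (is.null(nm)) nm <- locusNames(candidates)
  if (format == "bed") {
    gr <- granges(candidates)
    gr$name <- nm
    gr$score <- .bedScore(candidates)
    export(gr, path, format = "BED")
    return(invisible(path))
  }
  m <- mcols(candidates)
  d <- data.frame(
    locus_id = nm,
    contig = as.character(seqnames(candidates)),
    start0 = start(candidates) - 1L,
    end0 = end(candidates),
    start1 = start(candidates),
    end1 = end(candidates),
    strand = as.character(strand(candidates)),
    stringsAsFactors = FALSE
  )
  for (col in intersect(.CANDIDATE_COLS, colnames(m)))
    d[[col]] <- m[[col]]
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.bedScore <- function(candidates) {
  m <- mcols(candidates)
  if (length(candidates) == 0L) return(integer())
  if ("score_percentile" %in% colnames(m))
    return(as.integer(round(m$score_percentile * 10)))
  if ("combined_score" %in% colnames(m)) {
    s <- m$combined_score
    rng <- range(s)
    if (diff(rng) == 0) return(rep(0L, length(s)))
    return(as.integer(round(1000 * (s - rng[1L]) / diff(rng))))
  }
  rep(0L, length(candidates))
}

#' Read candidates back from TSV or BED
#'
#' Inverse of \code{\link{writeCandidates}}; mainly used for round-trip
#' checks and for feeding saved panels back into the caller.
#'
#' @param path file written by \code{\link{writeCandidates}}.
#' @param format \code{"tsv"} or \code{"bed"}; default inferred from the
#'   file extension.
#' @return \code{GRanges}.
#' @export
readCandidates <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  format <- match.arg(format, c("tsv", "bed"))
  if (format == "bed") {
    gr <- import(path, format = "BED")
    names(gr) <- gr$name
    return(gr)
  }
  d <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  gr <- GRanges(d$contig, IRanges(d$start1, d$end1), strand = d$strand)
  names(gr) <- d$locus_id
  for (col in intersect(.CANDIDATE_COLS, colnames(d)))
    mcols(gr)[[col]] <- d[[col]]
  gr
}
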