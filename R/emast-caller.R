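#' Construct a RepeatCountExperiment
#'
#' @param normal,tumor integer matrices (markers x samples) of
#'   repeat-unit counts, \code{NA} for missing measurements; dimnames
#'   required on \code{normal} and shared by all assays.
#' @param publishedUnits integer vector, reference-genome repeat count
#'   per marker.
#' @param algorithmIdentified logical vector, \code{FALSE} for control
#'   markers.
#' @param parental optional integer matrix of counts from unaffected
#'   parental-strain animals (same shape).
#' @param unit optional repeat unit string stored in the metadata.
#' @return \code{\linkS4class{RepeatCountExperiment}}.
#' @examples
#' n <- matrix(17L, 1, 3, dimnames = list("C8R17", c("1", "2", "3")))
#' t <- n; t[1, 3] <- 18L
#' rce <- RepeatCountExperiment(n, t, publishedUnits = 17L,
#'                              algorithmIdentified = TRUE)
#' callEmast(rce)
#' @export
RepeatCountExperiment <- function(normal, tumor, publishedUnits,
                                  algorithmIdentified =
                                    rep(TRUE, nrow(normal)),
                                  parental = NULL, unit = NA_character_) {
  normal <- .countMatrix(normal, "normal")
  tumor <- .countMatrix(tumor, "tumor")
  stopifnot(identical(dim(normal), dim(tumor)))
  assays <- list(normal = normal, tumor = tumor)
  if (!is.null(parental))
    assays$parental <- .countMatrix(parental, "parental")
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(
      publishedUnits = as.integer(publishedUnits),
      algorithmIdentified = as.logical(algorithmIdentified),
      row.names = rownames(normal)))
  metadata(se)$unit <- unit
  new("RepeatCountExperiment", se)
}

.countMatrix <- function(m, what) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("'", what, "' matrix needs marker rownames and sample colnames",
         call. = FALSE)
  m
}

#' Accessors for RepeatCountExperiment assays and metadata
#'
#' @param x \code{\linkS4class{RepeatCountExperiment}}.
#' @return \code{normalCounts}/\code{tumorCounts}/\code{parentalCounts}:
#'   integer matrices (\code{parentalCounts} is \code{NULL} when absent);
#'   \code{publishedUnits}: named integer vector;
#'   \code{algorithmIdentified}: named logical vector.
#' @name rce-accessors
NULL

#' @rdname rce-accessors
#' @export
normalCounts <- function(x) assay(x, "normal")

#' @rdname rce-accessors
#' @export
tumorCounts <- function(x) assay(x, "tumor")

#' @rdname rce-accessors
#' @export
parentalCounts <- function(x) {
  if ("parental" %in% SummarizedExperiment::assayNames(x))
    assay(x, "parental")
  else NULL
}

#' @rdname rce-accessors
#' @export
publishedUnits <- function(x)
  setNames(rowData(x)$publishedUnits, rownames(x))

#' @rdname rce-accessors
#' @export
algorithmIdentified <- function(x)
  setNames(rowData(x)$algorithmIdentified, rownames(x))

#' Read a marker-by-sample repeat-count table
#'
#' Long-format TSV with header columns \code{marker_id},
#' \code{published_n_units}, \code{sample_id}, \code{tissue} (one of
#' \code{normal}, \code{tumor}, \code{parental}), \code{n_units} (blank
#' for a missing measurement) and \code{algorithm_identified} (0/1).
#'
#' @param path TSV path.
#' @return \code{\linkS4class{RepeatCountExperiment}}.
#' @seealso the packaged fixture
#'   \code{system.file("extdata", "table1.tsv", package = "emastscan")}
#' @export
readCountTable <- function(path) {
  if (!file.exists(path))
    stop("count table not found: ", path, call. = FALSE)
  d <- read.delim(path, header = TRUE, sep = "\t",
                  colClasses = "character", comment.char = "#")
  need <- c("marker_id", "published_n_units", "sample_id", "tissue",
            "n_units", "algorithm_identified")
  miss <- setdiff(need, colnames(d))
  if (length(miss))
    stop("count table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0L)
    stop("count table is empty", call. = FALSE)
  d$tissue <- tolower(d$tissue)
  bad <- !d$tissue %in% c("normal", "tumor", "parental")
  if (any(bad))
    stop("unknown tissue '", d$tissue[which(bad)[1L]], "' in row ",
         which(bad)[1L], call. = FALSE)
  d$n_units <- suppressWarnings(as.integer(d$n_units))
  markers <- unique(d$marker_id)
  samples <- unique(d$sample_id)
  mk <- function(tissue) {
    m <- matrix(NA_integer_, length(markers), length(samples),
                dimnames = list(markers, samples))
    sub <- d[d$tissue == tissue & !is.na(d$n_units), , drop = FALSE]
    m[cbind(match(sub$marker_id, markers),
            match(sub$sample_id, samples))] <- sub$n_units
    m
  }
  pub <- vapply(markers, function(mid)
    as.integer(d$published_n_units[d$marker_id == mid][1L]), integer(1L))
  alg <- vapply(markers, function(mid)
    d$algorithm_identified[d$marker_id == mid][1L] %in% c("1", "TRUE",
                                                          "true"),
    logical(1L))
  parental <- if (any(d$tissue == "parental")) mk("parental") else NULL
  RepeatCountExperiment(mk("normal"), mk("tumor"), publishedUnits = pub,
                        algorithmIdentified = alg, parental = parental)
}

#' Write a repeat-count experiment as long-format TSV
#'
#' Inverse of \code{\link{readCountTable}} (missing cells written
#' blank).
#'
#' @param x \code{\linkS4class{RepeatCountExperiment}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(x, path) {
  rows <- list()
  tissues <- intersect(c("normal", "tumor", "parental"),
                       SummarizedExperiment::assayNames(x))
  for (tis in tissues) {
    m <- assay(x, tis)
    rows[[tis]] <- data.frame(
      marker_id = rep(rownames(m), times = ncol(m)),
      published_n_units = rep(publishedUnits(x), times = ncol(m)),
      sample_id = rep(colnames(m), each = nrow(m)),
      tissue = tis,
      n_units = as.vector(m),
      algorithm_identified = as.integer(rep(algorithmIdentified(x),
                                            times = ncol(m))),
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d <- d[order(match(d$marker_id, rownames(x)),
               match(d$tissue, c("normal", "tumor", "parental")),
               d$sample_id), ]
  d$n_units[is.na(d$n_units)] <- ""
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repeat-unit count difference between two sequenced regions
#'
#' Finds the single maximal run of \code{unit} in each sequence and
#' returns the sample-minus-reference difference in complete unit
#' counts.  The two repeat tracts (including any trailing/leading
#' partial unit copy) must differ by a whole number of unit lengths —
#' a gap of four, or a multiple of four, nucleotides for a
#' tetranucleotide — otherwise the difference is flagged as a non-unit
#' indel and rejected.
#'
#' @param referenceSeq,sampleSeq character sequences each containing
#'   exactly one maximal run of \code{unit} with at least 2 copies.
#' @param unit repeat unit.
#' @return integer: sample unit count minus reference unit count.
#' @examples
#' ref <- paste0("GGAA", strrep("CTTT", 18), "GACC")
#' smp <- paste0("GGAA", strrep("CTTT", 17), "GACC")
#' repeatCountDelta(ref, smp, "CTTT") # -1
#' @export
repeatCountDelta <- function(referenceSeq, sampleSeq, unit) {
  unit <- checkRepeatUnit(unit)
  r <- .singleTract(referenceSeq, unit, "referenceSeq")
  s <- .singleTract(sampleSeq, unit, "sampleSeq")
  k <- nchar(unit)
  if ((s$tractLen - r$tractLen) %% k != 0L)
    stop("repeat tracts differ by ", abs(s$tractLen - r$tractLen),
         " nt, not a multiple of the unit length (", k,
         "): non-unit indel", call. = FALSE)
  s$n_units - r$n_units
}

## locate the unique maximal run and its tract length extended over
## partial unit copies at both ends
.singleTract <- function(seq, unit, what) {
  gr <- findTandemRepeats(seq, unit, minUnits = 2L)
  if (length(gr) != 1L)
    stop("'", what, "' must contain exactly one maximal run of ", unit,
         " with >= 2 copies (found ", length(gr), ")", call. = FALSE)
  s <- toupper(as.character(seq))
  k <- nchar(unit)
  a <- start(gr)
  b <- end(gr)
  ## extend over a partial trailing copy ...
  ext <- 0L
  while (b + ext < nchar(s) &&
         substr(s, b + ext + 1L, b + ext + 1L) ==
         substr(unit, ext %% k + 1L, ext %% k + 1L))
    ext <- ext + 1L
  b <- b + min(ext, k - 1L)
  ## ... and a partial leading copy
  ext <- 0L
  while (a - ext > 1L &&
         substr(s, a - ext - 1L, a - ext - 1L) ==
         substr(unit, k - ext %% k, k - ext %% k))
    ext <- ext + 1L
  a <- a - min(ext, k - 1L)
  list(n_units = mcols(gr)$n_units, tractLen = b - a + 1L)
}

#' Call normal-tissue instability per marker
#'
#' A marker is unstable in normal tissue when any present normal-tissue
#' count differs from the published reference count
#' (\code{compare = "published"}, the default) or, alternatively, when
#' the normal counts differ between animals
#' (\code{compare = "across_mice"}).
#'
#' @param x \code{\linkS4class{RepeatCountExperiment}}.
#' @param compare instability definition, see above.
#' @return named logical vector, one element per marker.
#' @export
callNormalInstability <- function(x, compare = c("published",
                                                 "across_mice")) {
  compare <- match.arg(compare)
  nm <- normalCounts(x)
  pub <- publishedUnits(x)
  res <- logical(nrow(nm))
  for (i in seq_len(nrow(nm))) {
    v <- nm[i, ][!is.na(nm[i, ])]
    if (length(v) == 0L)
      stop("marker '", rownames(nm)[i], "' has no normal counts",
           call. = FALSE)
    res[i] <- if (compare == "published") any(v != pub[i])
              else length(unique(v)) > 1L
  }
  setNames(res, rownames(nm))
}

#' Call per-mouse EMAST events per marker
#'
#' A sample shows EMAST at a marker when both its normal and tumor
#' counts are present and differ; samples with a missing count are
#' skipped, never called.
#'
#' @param x \code{\linkS4class{RepeatCountExperiment}}.
#' @return named list (one element per marker) of character vectors of
#'   sample ids.
#' @export
callEmast <- function(x) {
  nm <- normalCounts(x)
  tm <- tumorCounts(x)
  out <- vector("list", nrow(nm))
  names(out) <- rownames(nm)
  for (i in seq_len(nrow(nm))) {
    comparable <- !is.na(nm[i, ]) & !is.na(tm[i, ])
    if (!any(comparable))
      stop("marker '", rownames(nm)[i],
           "' has no sample with both normal and tumor counts",
           call. = FALSE)
    hit <- comparable & nm[i, ] != tm[i, ]
    out[[i]] <- colnames(nm)[which(hit)]
  }
  out
}

#' Classify tumors as EMAST-positive
#'
#' A tumor (sample) is EMAST-positive when at least
#' \code{minUnstableMarkers} panel markers show an EMAST event for it.
#' Control markers are excluded from the panel by default.
#'
#' @param x \code{\linkS4class{RepeatCountExperiment}}.
#' @param minUnstableMarkers threshold (default 1; 0 vacuously marks
#'   every sample positive).
#' @param algorithmOnly restrict the panel to algorithm-identified
#'   markers (default \code{TRUE}).
#' @return character vector of EMAST-positive sample ids (column
#'   order).
#' @export
classifyTumors <- function(x, minUnstableMarkers = 1L,
                           algorithmOnly = TRUE) {
  keep <- if (algorithmOnly) algorithmIdentified(x)
          else rep(TRUE, nrow(x))
  if (!any(keep))
    stop("marker panel is empty", call. = FALSE)
  sub <- x[keep, ]
  events <- callEmast(sub)
  samples <- colnames(sub)
  nUnstable <- vapply(samples, function(s)
    sum(vapply(events, function(e) s %in% e, logical(1L))), integer(1L))
  samples[nUnstable >= minUnstableMarkers]
}

#' Summarize a marker panel
#'
#' Aggregates \code{\link{callNormalInstability}} and
#' \code{\link{callEmast}} over the panel: how many
#' algorithm-identified markers show normal-tissue instability, how
#' many show EMAST in at least one tumor, their overlap, how many show
#' either, and which tumors are EMAST-positive.  Control markers are
#' tallied separately and never enter the panel counts.
#'
#' @param x \code{\linkS4class{RepeatCountExperiment}}.
#' @param minUnstableMarkers forwarded to \code{\link{classifyTumors}}.
#' @param compare forwarded to \code{\link{callNormalInstability}}.
#' @return \code{\linkS4class{PanelSummary}}.
#' @examples
#' tab <- system.file("extdata", "table1.tsv", package = "emastscan")
#' summarizePanel(readCountTable(tab))
#' @export
summarizePanel <- function(x, minUnstableMarkers = 1L,
                           compare = "published") {
  ni <- callNormalInstability(x, compare = compare)
  em <- callEmast(x)
  alg <- algorithmIdentified(x)
  emHit <- lengths(em) > 0L
  anyI <- ni | emHit
  per <- DataFrame(
    normalInstability = ni,
    emastMice = vapply(em, paste, character(1L), collapse = ","),
    nEmastMice = lengths(em),
    anyInstability = anyI,
    algorithmIdentified = alg,
    row.names = rownames(x))
  new("PanelSummary",
      perMarker = per,
      nMarkersEmast = sum(emHit[alg]),
      nMarkersNormalInstability = sum(ni[alg]),
      nMarkersOverlap = sum((ni & emHit)[alg]),
      nMarkersAnyInstability = sum(anyI[alg]),
      emastPositiveMice = classifyTumors(
        x, minUnstableMarkers = minUnstableMarkers),
      nControls = sum(!alg),
      nControlsAnyInstability = sum(anyI[!alg]))
}

setMethod("show", "PanelSummary", function(object) {
  n <- sum(object@perMarker$algorithmIdentified)
  cat("EMAST panel summary —", n, "panel marker(s),",
      object@nControls, "control(s)\n")
  cat(sprintf("  markers with normal-tissue instability: %d/%d\n",
              object@nMarkersNormalInstability, n))
  cat(sprintf("  markers with EMAST in >=1 tumor:        %d/%d\n",
              object@nMarkersEmast, n))
  cat(sprintf("  overlap of the two:                     %d/%d\n",
              object@nMarkersOverlap, n))
  cat(sprintf("  markers with any instability:           %d/%d\n",
              object@nMarkersAnyInstability, n))
  cat("  EMAST-positive tumors:",
      if (length(object@emastPositiveMice))
        paste(object@emastPositiveMice, collapse = ", ")
      else "none", "\n")
  if (object@nControls > 0L)
    cat(sprintf("  controls with any instability:          %d/%d\n",
                object@nControlsAnyInstability, object@nControls))
})

#' Panel-summary accessors
#'
#' @param x \code{\linkS4class{PanelSummary}}.
#' @return \code{panelCounts}: named integer vector of the four panel
#'   counts; \code{emastPositiveMice}: character vector;
#'   \code{perMarkerCalls}: the per-marker \code{DataFrame}.
#' @name summary-accessors
NULL

#' @rdname summary-accessors
#' @export
panelCounts <- function(x) c(
  emast = x@nMarkersEmast,
  normal_instability = x@nMarkersNormalInstability,
  overlap = x@nMarkersOverlap,
  any_instability = x@nMarkersAnyInstability)

#' @rdname summary-accessors
#' @export
emastPositiveMice <- function(x) x@emastPositiveMice

#' @rdname summary-accessors
#' @export
perMarkerCalls <- function(x) x@perMarker

#' Write panel calls and summary
#'
#' @param summary \code{\linkS4class{PanelSummary}}.
#' @param callsPath per-marker calls TSV path (optional).
#' @param summaryPath JSON summary path (optional).
#' @return invisible list with the written paths.
#' @export
writePanelSummary <- function(summary, callsPath = NULL,
                              summaryPath = NULL) {
  if (!is.null(callsPath)) {
    d <- as.data.frame(summary@perMarker)
    d <- cbind(marker_id = rownames(d), d)
    write.table(d, callsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(summaryPath)) {
    obj <- c(as.list(panelCounts(summary)),
             list(emast_positive_mice = I(summary@emastPositiveMice),
                  n_controls = summary@nControls,
                  n_controls_any_instability =
                    summary@nControlsAnyInstability))
    write_json(obj, summaryPath, auto_unbox = TRUE, digits = NA,
               pretty = TRUE)
  }
  invisible(list(calls = callsPath, summary = summaryPath))
}
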