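#' Position weight matrix for a fixed-width motif
#'
#' A per-column base-probability model of a fixed-width DNA motif together
#' with the 0-order background it is scored against.  Columns of
#' \code{probs} are motif positions, rows are the bases A, C, G, T; each
#' column sums to one.  \code{nsites} records the (possibly fractional,
#' when estimated from EM posteriors) number of sites the matrix was
#' estimated from; it feeds the significance approximation in
#' \code{\link{discoverMotif}}.
#'
#' @slot probs numeric matrix, 4 rows (A, C, G, T) by \code{width} columns;
#'   every column sums to 1.
#' @slot background named numeric of length 4, base frequencies summing
#'   to 1.
#' @slot pseudocount single non-negative numeric used when the matrix was
#'   built (see \code{\link{buildPWM}}).
#' @slot nsites single numeric, effective number of training sites.
#'
#' @seealso \code{\link{buildPWM}}, \code{\link{logOddsScore}},
#'   \code{\link{scanFlank}}
#' @export
setClass("MotifPWM",
  representation(
    probs = "matrix",
    background = "numeric",
    pseudocount = "numeric",
    nsites = "numeric"
  )
)

setValidity("MotifPWM", function(object) {
  p <- object@probs
  msg <- character()
  if (!is.numeric(p) || nrow(p) != 4L)
    msg <- c(msg, "'probs' must be a numeric matrix with 4 rows")
  if (is.null(rownames(p)) || !identical(rownames(p), .BASES))
    msg <- c(msg, "'probs' rows must be named A, C, G, T (in that order)")
  if (ncol(p) < 1L)
    msg <- c(msg, "'probs' must have at least one column")
  if (any(p < 0))
    msg <- c(msg, "'probs' entries must be non-negative")
  if (length(msg) == 0L && any(abs(colSums(p) - 1) > 1e-9))
    msg <- c(msg, "each 'probs' column must sum to 1 (tolerance 1e-9)")
  b <- object@background
  if (length(b) != 4L || is.null(names(b)) || !identical(names(b), .BASES))
    msg <- c(msg, "'background' must be length 4, named A, C, G, T")
  else if (any(b <= 0) || abs(sum(b) - 1) > 1e-9)
    msg <- c(msg, "'background' must be positive and sum to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    msg <- c(msg, "'pseudocount' must be a single non-negative number")
  if (object@pseudocount > 0 && length(msg) == 0L && any(p <= 0))
    msg <- c(msg, "all probabilities must be positive when pseudocount > 0")
  if (length(msg)) msg else TRUE
})

#' Paired 5'/3' flanking-motif model
#'
#' Bundles the two position weight matrices learned from the upstream (5')
#' and downstream (3') flanks of a panel of known unstable microsatellite
#' loci, together with per-matrix acceptance score thresholds (in bits)
#' and approximate motif significance values.  Both matrices share the
#' same width.  \code{unit} records the repeat-unit category the model was
#' trained on (models are trained within one unit category, e.g. all-CTTT).
#'
#' @slot pwm5p,pwm3p \code{\linkS4class{MotifPWM}} objects for the
#'   upstream and downstream flank motifs.
#' @slot threshold5p,threshold3p single numerics; a flank "carries" a
#'   motif when its best window log-odds score (bits) reaches the
#'   threshold.  Defaults from \code{\link{trainMotifModel}} are the
#'   minimum accepted training-site scores.
#' @slot evalue5p,evalue3p single numerics, approximate motif
#'   significance (see \code{\link{discoverMotif}}).
#' @slot unit single character, repeat-unit category (may be \code{NA}).
#'
#' @seealso \code{\link{trainMotifModel}}, \code{\link{filterByMotifs}},
#'   \code{\link{writeMotifModel}}
#' @export
setClass("MotifModel",
  representation(
    pwm5p = "MotifPWM",
    pwm3p = "MotifPWM",
    threshold5p = "numeric",
    threshold3p = "numeric",
    evalue5p = "numeric",
    evalue3p = "numeric",
    unit = "character"
  )
)

setValidity("MotifModel", function(object) {
  msg <- character()
  if (ncol(object@pwm5p@probs) != ncol(object@pwm3p@probs))
    msg <- c(msg, "5' and 3' PWMs must have the same width")
  for (s in c("threshold5p", "threshold3p", "evalue5p", "evalue3p")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v))
      msg <- c(msg, sprintf("'%s' must be a single non-NA number", s))
  }
  if (length(msg) == 0L &&
      (!is.finite(object@threshold5p) || !is.finite(object@threshold3p)))
    msg <- c(msg, "thresholds must be finite")
  if (length(object@unit) != 1L)
    msg <- c(msg, "'unit' must be a single character value")
  if (length(msg)) msg else TRUE
})

#' Marker-by-sample repeat-count experiment
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} subclass
#' holding integer repeat-unit counts for a microsatellite marker panel.
#' Rows are markers, columns are animals/samples.  Assays \code{"normal"}
#' and \code{"tumor"} are always present; an optional \code{"parental"}
#' assay holds counts from unaffected parental-strain animals.  Missing
#' measurements are \code{NA} and are skipped, never imputed, by the
#' calling functions.  Row metadata carries \code{publishedUnits} (the
#' reference-genome repeat count each sample is compared against) and
#' \code{algorithmIdentified} (\code{FALSE} for control markers that were
#' not selected by the discovery pipeline).
#'
#' @seealso \code{\link{RepeatCountExperiment}} (constructor),
#'   \code{\link{readCountTable}}, \code{\link{callEmast}},
#'   \code{\link{summarizePanel}}
#' @export
setClass("RepeatCountExperiment", contains = "SummarizedExperiment")

setValidity("RepeatCountExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("normal", "tumor") %in% an))
    msg <- c(msg, "assays must include 'normal' and 'tumor'")
  rd <- rowData(object)
  if (!all(c("publishedUnits", "algorithmIdentified") %in% colnames(rd)))
    msg <- c(msg,
      "rowData must have 'publishedUnits' and 'algorithmIdentified'")
  else {
    if (any(is.na(rd$publishedUnits)) || any(rd$publishedUnits < 1))
      msg <- c(msg, "'publishedUnits' must be positive integers")
    if (!is.logical(rd$algorithmIdentified))
      msg <- c(msg, "'algorithmIdentified' must be logical")
  }
  for (a in intersect(c("normal", "tumor", "parental"), an)) {
    m <- assay(object, a)
    v <- m[!is.na(m)]
    if (length(v) && (any(v < 1) || any(v != round(v))))
      msg <- c(msg, sprintf("assay '%s' must hold positive integer counts", a))
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "markers (rownames) must be unique and non-NULL")
  if (length(msg)) msg else TRUE
})

#' Panel-level summary of instability and EMAST calls
#'
#' Returned by \code{\link{summarizePanel}}.  Marker-level counts are over
#' the algorithm-identified panel; control markers are tallied separately.
#'
#' @slot perMarker \code{DataFrame} with one row per marker (controls
#'   included): \code{normalInstability}, \code{emastMice} (comma-joined
#'   sample ids), \code{nEmastMice}, \code{anyInstability},
#'   \code{algorithmIdentified}.
#' @slot nMarkersEmast,nMarkersNormalInstability,nMarkersOverlap,nMarkersAnyInstability
#'   integer counts over the algorithm-identified panel.
#' @slot emastPositiveMice character, samples with at least the configured
#'   number of unstable panel markers.
#' @slot nControls,nControlsAnyInstability integer counts over control
#'   markers.
#'
#' @export
setClass("PanelSummary",
  representation(
    perMarker = "DataFrame",
    nMarkersEmast = "integer",
    nMarkersNormalInstability = "integer",
    nMarkersOverlap = "integer",
    nMarkersAnyInstability = "integer",
    emastPositiveMice = "character",
    nControls = "integer",
    nControlsAnyInstability = "integer"
  )
)

setValidity("PanelSummary", function(object) {
  msg <- character()
  if (object@nMarkersOverlap >
      min(object@nMarkersEmast, object@nMarkersNormalInstability))
    msg <- c(msg, "overlap count cannot exceed either marginal count")
  if (object@nMarkersAnyInstability <
      max(object@nMarkersEmast, object@nMarkersNormalInstability))
    msg <- c(msg, "any-instability count cannot be below either marginal")
  if (length(msg)) msg else TRUE
})
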