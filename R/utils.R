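.BASES <- c("A", "C", "G", "T")

#' @noRd
.assertScalarCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}

## minimal period of a unit string; a valid repeat unit has minimal period
## equal to its own length (rejects AAAA, ATAT and the like)
.minimalPeriod <- function(unit) {
  n <- nchar(unit)
  ch <- strsplit(unit, "", fixed = TRUE)[[1L]]
  for (p in seq_len(n - 1L)) {
    if (n %% p == 0L && all(ch == rep_len(ch[seq_len(p)], n)))
      return(p)
  }
  n
}

#' Validate a repeat unit
#'
#' A repeat unit must be a 3- or 4-letter string over A/C/G/T whose minimal
#' period equals its length, so that a tetranucleotide query cannot
#' silently be a mono- or dinucleotide repeat (\code{"CTTT"} is valid;
#' \code{"AAAA"} and \code{"ATAT"} are rejected).
#'
#' @param unit single character string.
#' @return The validated unit (uppercased), invisibly usable downstream.
#' @examples
#' checkRepeatUnit("CTTT")
#' try(checkRepeatUnit("ATAT"))
#' @export
checkRepeatUnit <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit))
    stop("repeat unit must be a single character string", call. = FALSE)
  unit <- toupper(unit)
  if (!nchar(unit) %in% c(3L, 4L))
    stop("repeat unit must have length 3 or 4, got '", unit, "'",
         call. = FALSE)
  if (!grepl("^[ACGT]+$", unit))
    stop("repeat unit must be over the alphabet {A,C,G,T}, got '", unit,
         "'", call. = FALSE)
  if (.minimalPeriod(unit) != nchar(unit))
    stop("repeat unit '", unit, "' is periodic (minimal period ",
         .minimalPeriod(unit), "); pass the minimal unit instead",
         call. = FALSE)
  unit
}

## reverse complement for plain character vectors
.revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

## draw i.i.d. bases; freqs must be named A/C/G/T
.randomBases <- function(n, freqs) {
  paste(sample(.BASES, n, replace = TRUE, prob = freqs[.BASES]),
        collapse = "")
}

.normBaseFreqs <- function(freqs) {
  if (is.null(names(freqs)) || !all(.BASES %in% names(freqs)))
    stop("base frequencies must be named A, C, G, T", call. = FALSE)
  freqs <- freqs[.BASES]
  if (any(freqs < 0) || sum(freqs) <= 0)
    stop("base frequencies must be non-negative and sum > 0", call. = FALSE)
  freqs / sum(freqs)
}
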