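#' Write PWMs in MEME minimal text format
#'
#' Emits a motif file that third-party scanners (FIMO, MAST, ...) can
#' consume: version line, alphabet, background frequencies and one
#' letter-probability matrix per motif.
#'
#' @param x \code{\linkS4class{MotifModel}} (written as two motifs named
#'   \code{flank_5p} and \code{flank_3p}) or a single
#'   \code{\linkS4class{MotifPWM}}.
#' @param path output path.
#' @param name motif name used when \code{x} is a single PWM.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readMemeMotifs}}
#' @export
writeMemeMotifs <- function(x, path, name = "motif") {
  if (is(x, "MotifModel")) {
    pwms <- list(flank_5p = x@pwm5p, flank_3p = x@pwm3p)
    evals <- c(x@evalue5p, x@evalue3p)
  } else {
    stopifnot(is(x, "MotifPWM"))
    pwms <- setNames(list(x), name)
    evals <- NA_real_
  }
  bg <- pwms[[1L]]@background
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", .BASES, bg), collapse = " "),
    ""
  )
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    ev <- if (is.na(evals[i])) 0 else evals[i]
    lines <- c(lines,
      paste("MOTIF", names(pwms)[i]),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %.3g",
              width(p), max(1L, round(p@nsites)), ev),
      apply(p@probs, 2L, function(col)
        paste(sprintf("%.6f", col), collapse = " ")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path a file written by \code{\link{writeMemeMotifs}} or by MEME
#'   itself (minimal format).
#' @return named list of \code{\linkS4class{MotifPWM}}; the approximate
#'   E-value parsed from each matrix header is attached as attribute
#'   \code{"evalue"}.
#' @export
readMemeMotifs <- function(path) {
  ln <- readLines(path)
  bgline <- which(grepl("^Background letter frequencies", ln))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  if (length(bgline)) {
    tok <- strsplit(trimws(ln[bgline[1L] + 1L]), "\\s+")[[1L]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[.BASES]
  }
  starts <- which(grepl("^MOTIF ", ln))
  out <- list()
  for (s in starts) {
    nm <- strsplit(ln[s], "\\s+")[[1L]][2L]
    h <- s + which(grepl("^letter-probability matrix:", ln[(s + 1L):length(ln)]))[1L]
    hdr <- ln[h]
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", hdr))
    nsites <- as.numeric(sub(".*nsites= *([0-9.]+).*", "\\1", hdr))
    ev <- suppressWarnings(as.numeric(sub(".*E= *([0-9.eE+-]+).*", "\\1", hdr)))
    rows <- ln[(h + 1L):(h + w)]
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]]), numeric(4L)))
    probs <- t(probs) # 4 x w
    ## renormalise away text round-off so validity holds exactly
    probs <- sweep(probs, 2L, colSums(probs), "/")
    dimnames(probs) <- list(.BASES, NULL)
    pwm <- new("MotifPWM", probs = probs, background = bg / sum(bg),
               pseudocount = 0.25, nsites = nsites)
    attr(pwm, "evalue") <- ev
    out[[nm]] <- pwm
  }
  out
}

.pwmToList <- function(p) {
  list(probs = unname(p@probs), background = as.list(p@background),
       pseudocount = p@pseudocount, nsites = p@nsites)
}

.pwmFromList <- function(l) {
  probs <- matrix(unlist(l$probs), nrow = 4L,
                  dimnames = list(.BASES, NULL))
  new("MotifPWM", probs = probs,
      background = unlist(l$background)[.BASES],
      pseudocount = l$pseudocount, nsites = l$nsites)
}

#' Serialize a motif model to/from JSON
#'
#' JSON round-trip preserving probabilities at full double precision,
#' used as the model interchange format of the command-line tools.
#'
#' @param model \code{\linkS4class{MotifModel}}.
#' @param path JSON file path.
#' @return \code{writeMotifModel}: \code{path}, invisibly;
#'   \code{readMotifModel}: the restored
#'   \code{\linkS4class{MotifModel}}.
#' @export
writeMotifModel <- function(model, path) {
  stopifnot(is(model, "MotifModel"))
  obj <- list(
    format = "emastscan-motif-model",
    version = 1L,
    unit = model@unit,
    pwm5p = .pwmToList(model@pwm5p),
    pwm3p = .pwmToList(model@pwm3p),
    threshold5p = model@threshold5p,
    threshold3p = model@threshold3p,
    evalue5p = model@evalue5p,
    evalue3p = model@evalue3p
  )
  write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeMotifModel
#' @export
readMotifModel <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "emastscan-motif-model"))
    stop(path, " is not an emastscan motif-model JSON file", call. = FALSE)
  new("MotifModel",
      pwm5p = .pwmFromList(obj$pwm5p), pwm3p = .pwmFromList(obj$pwm3p),
      threshold5p = obj$threshold5p, threshold3p = obj$threshold3p,
      evalue5p = obj$evalue5p, evalue3p = obj$evalue3p,
      unit = if (is.null(obj$unit)) NA_character_ else obj$unit)
}
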