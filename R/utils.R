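#' Normalize gene symbols for matching
#'
#' Trims surrounding whitespace and upper-cases symbols so that expression,
#' network and annotation files agree on gene identity (HGNC symbols are
#' conventionally upper-case). Original spellings are kept separately for
#' display wherever they matter.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Pick the most plausible field delimiter of a delimited text file by
# counting candidate separators on the first non-empty line.
detect_delimiter <- function(path) {
  lines <- readLines(path, n = 25L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return("\t")
  counts <- vapply(c("\t", ",", ";"), function(sep) {
    lengths(regmatches(lines[1L], gregexpr(sep, lines[1L], fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0L)) return("\t")
  c("\t", ",", ";")[which.max(counts)]
}

# Format numbers so a write -> read round trip is lossless in double
# precision.
format_full_precision <- function(x) {
  sprintf("%.17g", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_trc <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "trc_error")))
}
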