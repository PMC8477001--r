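# Internal helpers shared across modules.
# Coordinates are 0-based half-open throughout the package; conversion to the
# 1-based inclusive convention happens only at Biostrings/Rsamtools calls.

#' Extract a genomic subsequence
#'
#' @param genome a named `DNAStringSet` as returned by [read_genome()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval; clipped to chromosome bounds
#'   must hold (`start >= 0`, `end <= width`).
#' @return character scalar (uppercased sequence).
#' @keywords internal
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom, call. = FALSE)
  }
  w <- length(genome[[chrom]])  # bases in the DNAString
  if (start < 0 || end > w || start > end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, w), call. = FALSE)
  }
  toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
}

#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Longest run of character `ch` in each string of `x` (vectorized).
#' @keywords internal
max_char_run <- function(x, ch) {
  pat <- sprintf("%s+", ch)
  vapply(gregexpr(pat, x), function(m) {
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
}

# Count occurrences of character `ch` in each string (vectorized).
#' @keywords internal
count_char <- function(x, ch) {
  nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal timestamped logger used by the pipeline.
#' @keywords internal
log_line <- function(con, ..., echo = FALSE) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", ...)
  if (!is.null(con)) writeLines(msg, con)
  if (echo) message(msg)
  invisible(msg)
}
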