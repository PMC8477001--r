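#' Read a genome FASTA
#'
#' Loads all records of a FASTA file into a named `DNAStringSet`. Sequence
#' access elsewhere in the package is case-insensitive (sequences are
#' uppercased on extraction); `N` bases are preserved.
#'
#' @param path path to a FASTA file.
#' @return a named `Biostrings::DNAStringSet`, one element per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "ACGTACGT", ">chrB", "GGGG"), fa)
#' g <- read_genome(fa)
#' names(g)
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  g <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # keep only the first whitespace-delimited token of each header
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) {
    stop("duplicate sequence names in ", path, call. = FALSE)
  }
  g
}

#' Write a genome FASTA
#'
#' @param genome named `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
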