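# Internal-priming artifact detection. Oligo(dT) priming on a genomic A-rich
# stretch rather than a real poly(A) tail leaves the mapped 3' end sitting
# immediately upstream of that stretch, so a read is flagged when the 20-nt
# genomic window strictly downstream of its 3' end (in the read's sense
# orientation) contains more than 12 'A's in total or a run of 8 or more
# consecutive 'A's. 'N' bases never count as A; the comparison is
# case-insensitive. Near a chromosome edge the available bases are used.

#' Test read 3'-end positions for internal priming
#'
#' @param genome named `DNAStringSet` (see [read_genome()]).
#' @param chrom,strand,pos vectors (recycled to a common length) giving the
#'   strand-aware read 3'-end positions (0-based).
#' @param window downstream window length in nt.
#' @param max_a flag when the window holds strictly more than this many A's.
#' @param run_a flag when the window holds a run of at least this many A's.
#' @return logical vector, `TRUE` where the position looks internally primed.
#' @export
#' @examples
#' g <- Biostrings::DNAStringSet(c(chrA = paste0("C", strrep("A", 8),
#'                                               strrep("G", 20))))
#' is_internal_priming(g, "chrA", "+", 0)   # 8-A run downstream -> TRUE
is_internal_priming <- function(genome, chrom, strand, pos,
                                window = 20L, max_a = 12L, run_a = 8L) {
  n <- max(length(chrom), length(strand), length(pos))
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  pos <- rep_len(as.integer(pos), n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) {
      stop("unknown chromosome: ", ch, call. = FALSE)
    }
    seq_str <- toupper(as.character(genome[[ch]]))
    len <- nchar(seq_str)
    sel <- chrom == ch
    plus <- sel & strand == "+"
    minus <- sel & strand == "-"
    if (any(plus)) {
      # window pos+1 .. pos+window (0-based) -> 1-based pos+2 .. pos+1+window
      from <- pmin(pos[plus] + 2L, len + 1L)
      to <- pmin(pos[plus] + 1L + window, len)
      w <- substr(rep(seq_str, sum(plus)), from, to)
      out[plus] <- count_char(w, "A") > max_a |
        max_char_run(w, "A") >= run_a
    }
    if (any(minus)) {
      # reference window pos-window .. pos-1, read in sense = revcomp:
      # A's in sense are T's on the reference
      from <- pmax(pos[minus] - window + 1L, 1L)
      to <- pmax(pos[minus], 0L)
      w <- substr(rep(seq_str, sum(minus)), from, to)
      out[minus] <- count_char(w, "T") > max_a |
        max_char_run(w, "T") >= run_a
    }
  }
  out
}

#' Remove internally primed read ends
#'
#' Applies [is_internal_priming()] to every read and drops the flagged ones.
#'
#' @param read_ends data.frame with `chrom`, `strand`, `pos`, `sample_id`.
#' @param genome named `DNAStringSet` covering every chromosome seen.
#' @inheritParams is_internal_priming
#' @return list with `kept` (the surviving rows) and `n_filtered`
#'   (named integer vector of removed reads per sample).
#' @export
filter_read_ends <- function(read_ends, genome,
                             window = 20L, max_a = 12L, run_a = 8L) {
  if (nrow(read_ends) == 0) {
    return(list(kept = read_ends, n_filtered = integer(0)))
  }
  bad <- is_internal_priming(genome, read_ends$chrom, read_ends$strand,
                             read_ends$pos, window = window,
                             max_a = max_a, run_a = run_a)
  n_filtered <- vapply(split(bad, read_ends$sample_id), sum, integer(1))
  list(kept = read_ends[!bad, , drop = FALSE], n_filtered = n_filtered)
}
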