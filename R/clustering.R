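# Snowball clustering of read 3'-end positions into poly(A)-site clusters.
# Greedy seed-and-grow, run independently per (chrom, strand): the position
# with the highest remaining read count seeds a cluster (ties broken to the
# leftmost coordinate), absorbs every remaining position within +/- window nt,
# and the procedure repeats until no reads remain. Clusters totalling fewer
# than `min_cluster_reads` reads are discarded (set it to 0 to keep all).
# The result depends only on the position/count multiset, never on input
# order, and the emitted clusters partition the kept positions.

#' Cluster read 3'-end positions into poly(A)-site clusters
#'
#' @param read_ends data.frame with `chrom`, `strand`, `pos`, `sample_id`
#'   (typically the `kept` element of [filter_read_ends()]).
#' @param window absorption half-width in nt (> 0); positions within
#'   `window` nt of a seed join its cluster.
#' @param min_cluster_reads discard clusters with fewer total reads.
#' @return data.frame with one row per kept cluster: `cluster_id`, `chrom`,
#'   `strand`, `rep_pos` (the seed position, the mode of member positions),
#'   `span_start`/`span_end` (0-based half-open hull of member positions),
#'   `count` (total reads) and one `count.<sample>` column per sample.
#'   Attribute `n_discarded_reads` counts reads in discarded clusters.
#' @export
cluster_read_ends <- function(read_ends, window = 24L, min_cluster_reads = 5L) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  samples <- sort(unique(read_ends$sample_id))
  pieces <- list()
  n_discarded <- 0L
  if (nrow(read_ends) > 0) {
    key <- paste(read_ends$chrom, read_ends$strand)
    for (k in sort(unique(key))) {
      sub <- read_ends[key == k, , drop = FALSE]
      pieces[[k]] <- snowball_one(sub, window, samples)
    }
  }
  cl <- do.call(rbind, unname(pieces))
  if (is.null(cl)) {
    cl <- data.frame(chrom = character(), strand = character(),
                     rep_pos = integer(), span_start = integer(),
                     span_end = integer(), count = integer())
    for (s in samples) cl[[paste0("count.", s)]] <- integer()
  }
  keep <- cl$count >= min_cluster_reads
  n_discarded <- sum(cl$count[!keep])
  cl <- cl[keep, , drop = FALSE]
  cl <- cl[order(cl$chrom, cl$rep_pos, cl$strand), , drop = FALSE]
  rownames(cl) <- NULL
  cl <- cbind(cluster_id = sprintf("PAS%05d", seq_len(nrow(cl))), cl,
              stringsAsFactors = FALSE)
  attr(cl, "n_discarded_reads") <- n_discarded
  cl
}

# One (chrom, strand) group. Works on the per-position count table so the
# outcome is independent of read order.
#' @keywords internal
snowball_one <- function(sub, window, samples) {
  upos <- sort(unique(sub$pos))
  counts <- as.integer(table(factor(sub$pos, levels = upos)))
  # per-sample counts per position
  sm <- table(factor(sub$pos, levels = upos),
              factor(sub$sample_id, levels = samples))
  remaining <- rep(TRUE, length(upos))
  rows <- list()
  while (any(remaining)) {
    cnt <- ifelse(remaining, counts, -1L)
    seed_i <- which.max(cnt)  # first max = leftmost since upos is sorted
    members <- remaining & abs(upos - upos[seed_i]) <= window
    row <- data.frame(chrom = sub$chrom[1], strand = sub$strand[1],
                      rep_pos = upos[seed_i],
                      span_start = min(upos[members]),
                      span_end = max(upos[members]) + 1L,
                      count = sum(counts[members]),
                      stringsAsFactors = FALSE)
    scounts <- colSums(sm[members, , drop = FALSE])
    for (s in samples) row[[paste0("count.", s)]] <- as.integer(scounts[[s]])
    rows[[length(rows) + 1L]] <- row
    remaining <- remaining & !members
  }
  do.call(rbind, rows)
}
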