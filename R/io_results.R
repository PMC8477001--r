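# Results and cluster tables on disk: TSV with header for APA results,
# BED6 for poly(A)-site clusters (score = total read count).

results_cols <- c("gene_id", "n_pas", "culi", "trend_stat", "p", "q", "call")

#' Write APA results as TSV
#'
#' Columns `gene_id`, `n_pas`, `culi`, `trend_stat`, `p`, `q`, `call` in that
#' order, rows sorted by `gene_id`; numeric fields carry enough digits to
#' round-trip at 6 significant digits or better.
#'
#' @param results data.frame of per-gene APA results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  res <- results[results_cols]
  res <- res[order(res$gene_id), , drop = FALSE]
  for (col in c("culi", "trend_stat", "p", "q")) {
    res[[col]] <- signif(res[[col]], 10)
  }
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an APA results TSV written by [write_results()]
#'
#' @param path path to the TSV.
#' @return data.frame with the standard result columns.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "numeric",
                                   "numeric", "numeric", "numeric",
                                   "character"))
}

#' Write poly(A)-site clusters as BED6
#'
#' One line per cluster sorted by (`chrom`, `rep_pos`): the interval is the
#' single representative base, the name field is `cluster_id`, and the score
#' carries the total read count.
#'
#' @param clusters cluster data.frame from [cluster_read_ends()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pas_bed <- function(clusters, path) {
  cl <- clusters[order(clusters$chrom, clusters$rep_pos, clusters$strand), ]
  bed <- data.frame(cl$chrom, cl$rep_pos, cl$rep_pos + 1L, cl$cluster_id,
                    cl$count, cl$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
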