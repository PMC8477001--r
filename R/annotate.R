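# Genomic annotation of poly(A)-site clusters against gene models and an
# optional known-site database. Categories are mutually exclusive with
# precedence TTS > UTR3 > exon > intron > intergenic; the non-exclusive
# TTS / 3'UTR indicator columns are also reported because annotated TTSs sit
# inside annotated 3'UTRs and summaries over the two overlap.

#' Annotate poly(A)-site clusters
#'
#' A cluster is `TTS` when its representative position lies within
#' `tts_window` nt of a same-strand gene's transcription terminal site,
#' `UTR3` when it falls in a same-strand annotated 3'UTR, then `exon`,
#' `intron`, and `intergenic`. `gene_id` is the gene granting the
#' highest-precedence category (nearest TTS on ties). A cluster is `known`
#' when a same-strand database site lies within `match_tolerance` nt of its
#' representative position.
#'
#' @param clusters data.frame from [cluster_read_ends()].
#' @param gene_models data.frame from [read_gene_models()].
#' @param known_pas optional data.frame with `chrom`, `strand`, `pos`
#'   (0-based site positions), or `NULL`.
#' @param tts_window nt tolerance for the TTS category.
#' @param match_tolerance nt tolerance for the known-site match.
#' @return `clusters` with columns `category`, `gene_id`, `known`,
#'   `in_tts_window`, `in_utr3` appended.
#' @export
annotate_clusters <- function(clusters, gene_models, known_pas = NULL,
                              tts_window = 100L, match_tolerance = 24L) {
  n <- nrow(clusters)
  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  known <- rep(FALSE, n)
  in_tts <- rep(FALSE, n)
  in_utr3 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    pos <- clusters$rep_pos[i]
    g <- gene_models[gene_models$chrom == clusters$chrom[i] &
                       gene_models$strand == clusters$strand[i], , drop = FALSE]
    if (nrow(g) > 0) {
      d_tts <- abs(pos - g$tts_pos)
      in_tts[i] <- any(d_tts <= tts_window)
      utr_hit <- pos >= g$utr3_start & pos < g$utr3_end
      in_utr3[i] <- any(utr_hit)
      if (in_tts[i]) {
        category[i] <- "TTS"
        gene_id[i] <- g$gene_id[which.min(d_tts)]
      } else if (in_utr3[i]) {
        category[i] <- "UTR3"
        gene_id[i] <- g$gene_id[which(utr_hit)[1]]
      } else {
        exon_hit <- vapply(seq_len(nrow(g)), function(j) {
          any(pos >= g$exon_starts[[j]] & pos < g$exon_ends[[j]])
        }, logical(1))
        body_hit <- pos >= g$start & pos < g$end
        if (any(exon_hit)) {
          category[i] <- "exon"
          gene_id[i] <- g$gene_id[which(exon_hit)[1]]
        } else if (any(body_hit)) {
          category[i] <- "intron"
          gene_id[i] <- g$gene_id[which(body_hit)[1]]
        }
      }
    }
    if (!is.null(known_pas) && nrow(known_pas) > 0) {
      db <- known_pas[known_pas$chrom == clusters$chrom[i] &
                        known_pas$strand == clusters$strand[i], , drop = FALSE]
      known[i] <- nrow(db) > 0 && min(abs(pos - db$pos)) <= match_tolerance
    }
  }
  clusters$category <- category
  clusters$gene_id <- gene_id
  clusters$known <- known
  clusters$in_tts_window <- in_tts
  clusters$in_utr3 <- in_utr3
  clusters
}

#' Count UTR-type poly(A)-site clusters per gene
#'
#' Only clusters categorized `TTS` or `UTR3` count as a gene's poly(A)
#' sites; genes with no such cluster are absent from the table.
#'
#' @param clusters annotated clusters from [annotate_clusters()].
#' @return list with `per_gene` (data.frame `gene_id`, `n_pas`) and
#'   `histogram` (named integer vector over `1`, `2`, `3`, `4+`).
#' @export
summarize_pas_per_gene <- function(clusters) {
  utr <- clusters[clusters$category %in% c("TTS", "UTR3") &
                    !is.na(clusters$gene_id), , drop = FALSE]
  tab <- table(utr$gene_id)
  per_gene <- data.frame(gene_id = as.character(names(tab) %||% character()),
                         n_pas = as.integer(tab), stringsAsFactors = FALSE)
  per_gene <- per_gene[order(per_gene$gene_id), , drop = FALSE]
  rownames(per_gene) <- NULL
  bins <- cut(per_gene$n_pas, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("1", "2", "3", "4+"))
  hist <- table(bins)
  histogram <- stats::setNames(as.integer(hist), names(hist))
  list(per_gene = per_gene, histogram = histogram)
}
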