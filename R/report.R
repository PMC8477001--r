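# Post-run report: dataset-level summary tables over a completed pipeline
# output directory - genomic category percentages of the poly(A)-site
# clusters (both the mutually exclusive categorization and the overlapping
# TTS / 3'UTR percentages, which can both exceed their exclusive shares
# because annotated TTSs sit inside 3'UTRs), the genes-per-PAS histogram,
# the known/novel split, the shift-call summary, and per-gene CULI scatter
# data (CULI vs FDR).

#' Summarize a completed pipeline run
#'
#' Reads `clusters_annotated.tsv`, `results.tsv` and `summary.json` from
#' `out_dir` and writes `report_category_percentages.tsv`,
#' `report_genes_per_pas.tsv`, `report_known_novel.tsv`,
#' `report_apa_calls.tsv` and `report_culi_scatter.tsv` next to them.
#'
#' @param out_dir a directory produced by [run_pipeline()].
#' @return invisibly, a list with the report tables.
#' @export
make_report <- function(out_dir) {
  need <- file.path(out_dir, c("clusters_annotated.tsv", "results.tsv",
                               "summary.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing pipeline artifact(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  clusters <- utils::read.table(need[1], sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  results <- read_results(need[2])
  summ <- jsonlite::read_json(need[3], simplifyVector = TRUE)

  n_cl <- nrow(clusters)
  cats <- c("TTS", "UTR3", "exon", "intron", "intergenic")
  cat_counts <- vapply(cats, function(cc) sum(clusters$category == cc),
                       integer(1))
  category <- data.frame(
    category = c(cats, "TTS_overlapping", "UTR3_overlapping"),
    n = c(cat_counts,
          if (n_cl) sum(clusters$in_tts_window) else 0L,
          if (n_cl) sum(clusters$in_utr3) else 0L))
  category$percent <- if (n_cl) round(100 * category$n / n_cl, 2) else 0

  pas_summary <- summarize_pas_per_gene(clusters)
  genes_per_pas <- data.frame(n_pas = names(pas_summary$histogram),
                              n_genes = as.integer(pas_summary$histogram))

  known_novel <- data.frame(
    status = c("known", "novel"),
    n = c(if (n_cl) sum(clusters$known == 1) else 0L,
          if (n_cl) sum(clusters$known == 0) else 0L))
  known_novel$fraction <- if (n_cl) round(known_novel$n / n_cl, 4) else 0

  calls <- data.frame(
    metric = c("n_genes_tested", "n_altered", "n_shortened", "n_lengthened",
               "frac_shortened_among_altered"),
    value = c(nrow(results),
              sum(results$call != "unchanged"),
              sum(results$call == "shortened"),
              sum(results$call == "lengthened"),
              if (sum(results$call != "unchanged") > 0)
                round(sum(results$call == "shortened") /
                        sum(results$call != "unchanged"), 4) else 0))

  scatter <- results[c("gene_id", "culi", "q", "call")]

  tabs <- list(category_percentages = category,
               genes_per_pas = genes_per_pas,
               known_novel = known_novel,
               apa_calls = calls,
               culi_scatter = scatter)
  for (nm in names(tabs)) {
    utils::write.table(tabs[[nm]],
                       file.path(out_dir, sprintf("report_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tabs)
}
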