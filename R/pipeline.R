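# Pipeline orchestration: filter -> cluster -> annotate -> profile -> test,
# from a single JSON (or in-memory list) configuration, with per-stage
# accounting written to a summary JSON. All data artifacts are sorted and
# deterministically formatted, so a rerun with identical inputs is
# byte-identical; run.log additionally carries wall-clock stage timings and
# is the one file excluded from that contract.

default_params <- function() {
  list(ip_window = 20L, ip_max_a = 12L, ip_run_a = 8L,
       cluster_window = 24L, min_cluster_reads = 5L,
       tts_window = 100L, match_tol = 24L, alpha = 0.05,
       exact_max_total = 200L)
}

#' Read a known poly(A)-site database from BED6
#'
#' @param path BED6 file of single-base site positions.
#' @return data.frame with `chrom`, `pos`, `strand`, `site_id`.
#' @export
read_known_pas <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), site_id = character()))
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character"))
  data.frame(chrom = bed$V1, pos = bed$V2, strand = bed$V6,
             site_id = bed$V4, stringsAsFactors = FALSE)
}

#' Load and validate a pipeline run configuration
#'
#' @param path path to a JSON configuration as written by
#'   [simulate_apa_experiment()] (fields: `genome`, `gene_models`, `sidecar`,
#'   optional `known_pas`, `reads` (sample -> path), `conditions`
#'   (sample -> condition), `control`, `treated`, `out_dir`, `params`).
#' @return validated configuration list.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$reads <- as.list(cfg$reads)
  cfg$conditions <- unlist(cfg$conditions)
  # relative paths are resolved against the config file's directory
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (f in c("genome", "gene_models", "sidecar", "known_pas", "out_dir")) {
    cfg[[f]] <- resolve(cfg[[f]])
  }
  cfg$reads <- lapply(cfg$reads, resolve)
  validate_run_config(cfg)
}

#' @keywords internal
validate_run_config <- function(cfg) {
  for (f in c("genome", "gene_models", "sidecar", "reads", "conditions",
              "control", "treated", "out_dir")) {
    if (is.null(cfg[[f]])) stop("run config missing field: ", f, call. = FALSE)
  }
  conds <- sort(unique(unname(cfg$conditions)))
  if (length(conds) != 2) {
    stop("condition map must name exactly two conditions, got: ",
         paste(conds, collapse = ", "), call. = FALSE)
  }
  if (!all(c(cfg$control, cfg$treated) %in% conds)) {
    stop("control/treated must match the condition map", call. = FALSE)
  }
  if (!setequal(names(cfg$reads), names(cfg$conditions))) {
    stop("read paths and condition map must cover the same samples",
         call. = FALSE)
  }
  files <- c(cfg$genome, cfg$gene_models, cfg$sidecar,
             unlist(cfg$reads), cfg$known_pas)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg$params <- utils::modifyList(default_params(), as.list(cfg$params))
  cfg
}

#' Run the APA analysis pipeline
#'
#' Executes internal-priming filtering, snowball clustering, annotation,
#' profile assembly and the trend-test/CULI analysis, writing `clusters.bed`,
#' `clusters_annotated.tsv`, `results.tsv`, `dpas_ppas_ratio.tsv`,
#' `summary.json` and `run.log` to the configured output directory. Read
#' conservation (input = kept + filtered; kept = clustered + discarded) is
#' asserted stage by stage and recorded in the summary.
#'
#' @param config a configuration list (see [load_run_config()]) or a path to
#'   a JSON configuration file.
#' @param quiet suppress console progress messages.
#' @return invisibly, a list with the main in-memory artifacts
#'   (`clusters`, `profiles`, `results`, `summary`, `out_dir`).
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  cfg <- if (is.character(config)) load_run_config(config) else
    validate_run_config(config)
  p <- cfg$params
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  echo <- !quiet
  t0 <- Sys.time()
  stage <- function(msg) log_line(con, msg, echo = echo)

  stage(paste0("parameters: ", jsonlite::toJSON(p, auto_unbox = TRUE)))

  stage("stage genome: reading FASTA")
  genome <- read_genome(cfg$genome)
  gene_models <- read_gene_models(cfg$gene_models, cfg$sidecar)
  known_pas <- if (!is.null(cfg$known_pas)) read_known_pas(cfg$known_pas) else
    NULL
  stage(sprintf("loaded %d chromosomes, %d genes, %d known sites",
                length(genome), nrow(gene_models),
                if (is.null(known_pas)) 0L else nrow(known_pas)))

  stage("stage reads: loading read 3' ends")
  reads <- do.call(rbind, lapply(names(cfg$reads), function(s)
    read_read_ends(cfg$reads[[s]], s)))
  n_input <- as.integer(table(reads$sample_id))
  names(n_input) <- names(table(reads$sample_id))
  stage(sprintf("loaded %d reads from %d samples", nrow(reads),
                length(cfg$reads)))

  stage("stage filter: internal-priming scan")
  flt <- filter_read_ends(reads, genome, window = p$ip_window,
                          max_a = p$ip_max_a, run_a = p$ip_run_a)
  n_kept <- nrow(flt$kept)
  stage(sprintf("filtered %d internally primed reads, kept %d",
                sum(flt$n_filtered), n_kept))
  stopifnot(nrow(reads) == n_kept + sum(flt$n_filtered))

  stage("stage cluster: snowball clustering")
  clusters <- cluster_read_ends(flt$kept, window = p$cluster_window,
                                min_cluster_reads = p$min_cluster_reads)
  n_discarded <- attr(clusters, "n_discarded_reads")
  stage(sprintf("%d clusters kept (>= %d reads), %d reads in discarded clusters",
                nrow(clusters), p$min_cluster_reads, n_discarded))
  stopifnot(n_kept == sum(clusters$count) + n_discarded)

  stage("stage annotate: gene-model and known-site annotation")
  clusters <- annotate_clusters(clusters, gene_models, known_pas,
                                tts_window = p$tts_window,
                                match_tolerance = p$match_tol)
  write_pas_bed(clusters, file.path(cfg$out_dir, "clusters.bed"))
  ann <- clusters
  ann$known <- as.integer(ann$known)
  utils::write.table(ann, file.path(cfg$out_dir, "clusters_annotated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("stage profile: per-gene APA profiles")
  profiles <- build_profiles(clusters, gene_models, cfg$conditions)
  stage(sprintf("%d genes with >= 2 UTR-type sites (%d skipped)",
                length(profiles), length(attr(profiles, "skipped"))))

  stage("stage test: CULI + linear trend test + BH FDR")
  results <- apa_test(profiles, treated = cfg$treated, control = cfg$control,
                      alpha = p$alpha, exact_max_total = p$exact_max_total)
  write_results(results, file.path(cfg$out_dir, "results.tsv"))

  ratios <- do.call(rbind, lapply(results$gene_id, function(gid) {
    r <- distal_proximal_ratio(profiles[[gid]], cfg$treated, cfg$control)
    data.frame(gene_id = gid,
               ratio_control = signif(r$ratio[[cfg$control]], 10),
               ratio_treated = signif(r$ratio[[cfg$treated]], 10),
               fold_change = signif(r$fold_change, 10),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ratios)) {
    ratios <- data.frame(gene_id = character(), ratio_control = numeric(),
                         ratio_treated = numeric(), fold_change = numeric())
  }
  utils::write.table(ratios, file.path(cfg$out_dir, "dpas_ppas_ratio.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summ <- attr(results, "summary")
  summary <- list(
    parameters = p,
    samples = as.list(cfg$conditions),
    control = cfg$control, treated = cfg$treated,
    n_reads_input = as.list(n_input),
    n_reads_filtered = as.list(flt$n_filtered),
    n_reads_kept = n_kept,
    n_reads_in_clusters = sum(clusters$count),
    n_reads_discarded_clusters = n_discarded,
    conservation_ok = nrow(reads) == sum(flt$n_filtered) +
      sum(clusters$count) + n_discarded,
    n_clusters = nrow(clusters),
    n_clusters_utr_type = sum(clusters$category %in% c("TTS", "UTR3")),
    n_genes_profiled = length(profiles),
    n_genes_tested = summ$n_tested,
    n_altered = summ$n_altered,
    frac_shortened = summ$frac_shortened)
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage(sprintf("done: %d genes tested, %d altered (%.0f s elapsed)",
                summ$n_tested, summ$n_altered,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(clusters = clusters, profiles = profiles, results = results,
                 summary = summary, out_dir = cfg$out_dir))
}
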