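# Synthetic 3'-end-seq experiment generator. Emulates the statistical
# structure of 3T-seq libraries: read 3' ends pile up at true cleavage sites
# with small Gaussian positional jitter, a configurable subset of genes has a
# planted proximal/distal usage shift between two conditions, and A-rich
# "trap" stretches inside some 3'UTRs create internal-priming artifact reads
# immediately upstream of them. 3'UTR sequence (and a short margin past the
# TTS) is generated A-depleted (no run of 4 A's, at most 10 A's per 20 nt in
# the sense orientation) so that no accidental window triggers the
# internal-priming rule - every flagged read is a planted artifact or a
# jitter edge case.

#' Configuration for the synthetic 3'-end-seq experiment
#'
#' @param n_genes number of genes.
#' @param pas_per_gene_probs probabilities for a gene carrying 1, 2, 3 or 4
#'   poly(A) sites (defaults give ~30% of genes three or more).
#' @param utr_length_range min/max annotated 3'UTR length (nt).
#' @param pas_spacing_min minimum distance between true PAS of one gene (nt);
#'   must exceed the downstream clustering window (`cluster_window`) so
#'   distinct sites never merge by construction.
#' @param cluster_window the clustering half-width the data are built for.
#' @param frac_shifted_genes fraction of genes with a planted usage shift.
#' @param frac_shortened_among_shifted fraction of shifted genes whose shift
#'   is toward the proximal site (3'UTR shortening) in the treated condition.
#' @param proximal_usage_baseline,proximal_usage_shifted usage fraction of
#'   the most proximal PAS in the baseline and shifted state (the remaining
#'   mass is split equally over the other sites).
#' @param reads_per_gene mean (Poisson) reads per gene per sample.
#' @param jitter_sd SD (nt) of the rounded Gaussian cleavage-position jitter.
#' @param n_priming_traps number of genes given an A-rich internal-priming
#'   trap in their 3'UTR.
#' @param trap_read_frac expected fraction of a trapped gene's reads that are
#'   internal-priming artifacts.
#' @param frac_known_pas fraction of true PAS included in the known-site
#'   database (the rest are "novel").
#' @param replicates_per_condition libraries per condition.
#' @param seed RNG seed; identical seeds give byte-identical outputs.
#' @return a validated `apa_sim_config` list.
#' @export
sim_config <- function(n_genes = 300L,
                       pas_per_gene_probs = c(`1` = 0.30, `2` = 0.40,
                                              `3` = 0.20, `4` = 0.10),
                       utr_length_range = c(400L, 2000L),
                       pas_spacing_min = 100L,
                       cluster_window = 24L,
                       frac_shifted_genes = 0.20,
                       frac_shortened_among_shifted = 0.85,
                       proximal_usage_baseline = 0.30,
                       proximal_usage_shifted = 0.80,
                       reads_per_gene = 200,
                       jitter_sd = 3,
                       n_priming_traps = 30L,
                       trap_read_frac = 0.05,
                       frac_known_pas = 1 / 3,
                       replicates_per_condition = 2L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              pas_per_gene_probs = pas_per_gene_probs,
              utr_length_range = as.integer(utr_length_range),
              pas_spacing_min = as.integer(pas_spacing_min),
              cluster_window = as.integer(cluster_window),
              frac_shifted_genes = frac_shifted_genes,
              frac_shortened_among_shifted = frac_shortened_among_shifted,
              proximal_usage_baseline = proximal_usage_baseline,
              proximal_usage_shifted = proximal_usage_shifted,
              reads_per_gene = reads_per_gene,
              jitter_sd = jitter_sd,
              n_priming_traps = as.integer(n_priming_traps),
              trap_read_frac = trap_read_frac,
              frac_known_pas = frac_known_pas,
              replicates_per_condition = as.integer(replicates_per_condition),
              seed = as.integer(seed))
  fracs <- c(cfg$frac_shifted_genes, cfg$frac_shortened_among_shifted,
             cfg$proximal_usage_baseline, cfg$proximal_usage_shifted,
             cfg$trap_read_frac, cfg$frac_known_pas)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$pas_per_gene_probs) - 1) > 1e-8 ||
      length(cfg$pas_per_gene_probs) != 4) {
    stop("pas_per_gene_probs must be 4 probabilities summing to 1",
         call. = FALSE)
  }
  if (cfg$pas_spacing_min <= cfg$cluster_window) {
    stop("pas_spacing_min must exceed cluster_window so that distinct true ",
         "PAS never merge", call. = FALSE)
  }
  if (cfg$n_genes < 1 || cfg$reads_per_gene <= 0 || cfg$jitter_sd < 0 ||
      cfg$replicates_per_condition < 1) {
    stop("invalid simulation sizes", call. = FALSE)
  }
  class(cfg) <- "apa_sim_config"
  cfg
}

# Rewrite a sense-oriented character vector so that no A run exceeds 3 and no
# 20-nt window holds more than 10 A's; replacements drawn from C/G/T.
#' @keywords internal
scrub_a_rich <- function(chars) {
  n <- length(chars)
  run <- 0L
  win_a <- 0L
  is_a <- logical(n)
  for (i in seq_len(n)) {
    if (i > 20L && is_a[i - 20L]) win_a <- win_a - 1L
    if (chars[i] == "A") {
      if (run >= 3L || win_a >= 10L) {
        chars[i] <- sample(c("C", "G", "T"), 1L)
        run <- 0L
      } else {
        run <- run + 1L
        win_a <- win_a + 1L
        is_a[i] <- TRUE
      }
    } else {
      run <- 0L
    }
  }
  chars
}

#' Generate the synthetic genome, gene models, truth and known-PAS database
#'
#' Genes are laid out without overlap on two chromosomes and both strands;
#' each gene's most distal true PAS coincides with its annotated TTS, and
#' every other PAS sits in the 3'UTR at least `pas_spacing_min` nt from its
#' neighbours. `n_priming_traps` genes receive a 16-nt A stretch (sense
#' orientation) in their 3'UTR at least 30 nt from every true PAS.
#'
#' @param config an `apa_sim_config` from [sim_config()]. The caller is
#'   responsible for seeding the RNG (see [simulate_apa_experiment()]).
#' @return list with `genome` (`DNAStringSet`), `gene_models` (data.frame as
#'   in [read_gene_models()]), `known_pas` (data.frame `chrom`, `pos`,
#'   `strand`, `site_id`), `truth` (per-gene ground-truth data.frame) and
#'   `traps` (per-trap data.frame with the artifact read position).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "apa_sim_config"))
  ng <- config$n_genes
  spacing <- config$pas_spacing_min
  gap <- 300L

  k <- sample(1:4, ng, replace = TRUE, prob = config$pas_per_gene_probs)
  utr_len <- as.integer(round(stats::runif(ng, config$utr_length_range[1],
                                           config$utr_length_range[2])))
  utr_len <- pmax(utr_len, (k - 1L) * spacing + 150L)
  cds_len <- as.integer(round(stats::runif(ng, 500, 1500)))
  gene_len <- cds_len + utr_len
  chrom <- rep(c("chr1", "chr2"), length.out = ng)
  strand <- rep(c("+", "-"), length.out = ceiling(ng / 2) * 2)[seq_len(ng)]

  start <- integer(ng)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    start[idx] <- as.integer(cumsum(c(gap, gene_len[idx[-length(idx)]] + gap)))
  }
  end <- start + gene_len
  chrom_len <- vapply(unique(chrom),
                      function(ch) max(end[chrom == ch]) + gap,
                      integer(1))

  plus <- strand == "+"
  utr3_start <- ifelse(plus, start + cds_len, start)
  utr3_end <- ifelse(plus, end, start + utr_len)
  stop_codon <- ifelse(plus, utr3_start - 1L, utr3_end)
  tts <- ifelse(plus, end - 1L, start)
  # two exons; the intron interrupts the CDS, never the 3'UTR
  exon_starts <- lapply(seq_len(ng), function(i) {
    if (plus[i]) c(start[i], start[i] + 300L) else c(start[i], end[i] - 200L)
  })
  exon_ends <- lapply(seq_len(ng), function(i) {
    if (plus[i]) c(start[i] + 200L, end[i]) else c(end[i] - 300L, end[i])
  })

  # true PAS as sense distances from the stop codon; the distal one is the TTS
  pas_dist <- lapply(seq_len(ng), function(i) {
    if (k[i] == 1L) return(utr_len[i])
    m <- k[i] - 1L
    slack <- utr_len[i] - (k[i] - 1L) * spacing - 80L
    extras <- sort(stats::runif(m, 0, slack))
    d <- 80L + (seq_len(m) - 1L) * spacing + round(extras)
    c(d, utr_len[i])
  })
  pas_ref <- lapply(seq_len(ng), function(i) {
    if (plus[i]) stop_codon[i] + pas_dist[[i]] else stop_codon[i] - pas_dist[[i]]
  })

  # shift classes: only genes with >= 2 PAS can shift
  eligible <- which(k >= 2L)
  n_shift <- min(round(config$frac_shifted_genes * ng), length(eligible))
  shifted <- if (n_shift > 0) sort(sample(eligible, n_shift)) else integer(0)
  n_short <- round(config$frac_shortened_among_shifted * n_shift)
  class_vec <- rep("unchanged", ng)
  if (n_shift > 0) {
    short_idx <- if (n_short > 0) shifted[seq_len(n_short)] else integer(0)
    class_vec[short_idx] <- "shortened"
    class_vec[setdiff(shifted, short_idx)] <- "lengthened"
  }

  usage_vec <- function(kk, p) {
    if (kk == 1L) return(1)
    c(p, rep((1 - p) / (kk - 1L), kk - 1L))
  }
  usage_control <- lapply(seq_len(ng), function(i) {
    p <- if (class_vec[i] == "lengthened") config$proximal_usage_shifted else
      config$proximal_usage_baseline
    usage_vec(k[i], p)
  })
  usage_treated <- lapply(seq_len(ng), function(i) {
    p <- switch(class_vec[i],
                shortened = config$proximal_usage_shifted,
                lengthened = config$proximal_usage_baseline,
                config$proximal_usage_baseline)
    usage_vec(k[i], p)
  })

  # genome sequence, then A-depletion of each 3'UTR plus a 30-nt margin past
  # the TTS (the downstream window of TTS reads), then trap planting
  seqs <- lapply(chrom_len, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  for (i in seq_len(ng)) {
    if (plus[i]) {
      lo <- utr3_start[i] + 1L
      hi <- min(end[i] + 30L, chrom_len[[chrom[i]]])
      region <- seqs[[chrom[i]]][lo:hi]
      seqs[[chrom[i]]][lo:hi] <- scrub_a_rich(region)
    } else {
      lo <- max(start[i] - 30L, 0L) + 1L
      hi <- utr3_end[i]
      region <- rev(comp_chars(seqs[[chrom[i]]][lo:hi]))
      seqs[[chrom[i]]][lo:hi] <- rev(comp_chars(scrub_a_rich(region)))
    }
  }

  trap_genes <- if (config$n_priming_traps > 0) {
    sample(seq_len(ng), min(config$n_priming_traps, ng))
  } else integer(0)
  traps <- list()
  for (i in trap_genes) {
    cand <- seq(40L, utr_len[i] - 60L)
    for (d in pas_dist[[i]]) {
      cand <- cand[cand > d + 30L | cand + 46L < d]
    }
    if (length(cand) == 0) next
    t0 <- if (length(cand) == 1L) cand else sample(cand, 1L)
    if (plus[i]) {
      lo <- stop_codon[i] + t0 + 1L
      seqs[[chrom[i]]][lo:(lo + 15L)] <- "A"
      read_pos <- stop_codon[i] + t0 - 1L
    } else {
      hi <- stop_codon[i] - t0 + 1L
      seqs[[chrom[i]]][(hi - 15L):hi] <- "T"
      read_pos <- stop_codon[i] - t0 + 1L
    }
    traps[[length(traps) + 1L]] <- data.frame(
      gene_id = sprintf("gene%04d", i), trap_dist = t0, read_pos = read_pos,
      stringsAsFactors = FALSE)
  }
  traps <- if (length(traps)) do.call(rbind, traps) else
    data.frame(gene_id = character(), trap_dist = integer(),
               read_pos = integer(), stringsAsFactors = FALSE)

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(chrom_len)

  gene_id <- sprintf("gene%04d", seq_len(ng))
  gm <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = start, end = end, stop_codon_pos = stop_codon,
                   utr3_start = utr3_start, utr3_end = utr3_end,
                   tts_pos = tts, stringsAsFactors = FALSE)
  gm$exon_starts <- exon_starts
  gm$exon_ends <- exon_ends

  all_sites <- data.frame(
    chrom = rep(chrom, k), strand = rep(strand, k),
    gene_id = rep(gene_id, k), pos = unlist(pas_ref),
    stringsAsFactors = FALSE)
  n_known <- round(config$frac_known_pas * nrow(all_sites))
  known_idx <- if (n_known > 0) sort(sample(nrow(all_sites), n_known)) else
    integer(0)
  known_pas <- all_sites[known_idx, c("chrom", "pos", "strand"), drop = FALSE]
  known_pas$site_id <- sprintf("dbPAS%05d", seq_len(nrow(known_pas)))
  rownames(known_pas) <- NULL

  truth <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand, n_pas = k,
    shift_class = class_vec,
    pas_pos = vapply(pas_ref, paste, character(1), collapse = ","),
    pas_dist = vapply(pas_dist, paste, character(1), collapse = ","),
    usage_control = vapply(usage_control, function(u)
      paste(signif(u, 8), collapse = ","), character(1)),
    usage_treated = vapply(usage_treated, function(u)
      paste(signif(u, 8), collapse = ","), character(1)),
    stringsAsFactors = FALSE)

  list(genome = genome, gene_models = gm, known_pas = known_pas,
       truth = truth, traps = traps)
}

#' @keywords internal
comp_chars <- function(chars) {
  chartr("ACGTN", "TGCAN", chars)
}

#' Simulate per-sample read 3'-end positions
#'
#' Per gene and sample, the read total is Poisson(`reads_per_gene`), each
#' read picks a true PAS by the condition's usage fractions, and its 3' end
#' is the PAS position plus rounded Gaussian jitter applied in the sense
#' orientation. Genes carrying a priming trap additionally emit
#' Binomial(n, `trap_read_frac`) artifact reads exactly at the position
#' immediately upstream of the A stretch.
#'
#' @param sim output of [generate_genome()].
#' @param config the same `apa_sim_config`.
#' @return data.frame of read ends (`chrom`, `strand`, `pos`, `sample_id`)
#'   with attribute `samples` (named condition vector).
#' @export
generate_reads <- function(sim, config) {
  truth <- sim$truth
  conds <- c("control", "treated")
  samples <- unlist(lapply(conds, function(cc)
    stats::setNames(rep(cc, config$replicates_per_condition),
                    sprintf("%s_rep%d", cc,
                            seq_len(config$replicates_per_condition)))))
  chrom_len <- stats::setNames(Biostrings::width(sim$genome),
                               names(sim$genome))
  out <- list()
  for (s in names(samples)) {
    cond <- samples[[s]]
    for (i in seq_len(nrow(truth))) {
      n <- stats::rpois(1, config$reads_per_gene)
      if (n == 0) next
      usage <- as.numeric(strsplit(
        if (cond == "control") truth$usage_control[i] else
          truth$usage_treated[i], ",")[[1]])
      pas <- as.integer(strsplit(truth$pas_pos[i], ",")[[1]])
      pick <- sample.int(length(pas), n, replace = TRUE, prob = usage)
      jit <- if (config$jitter_sd > 0)
        round(stats::rnorm(n, 0, config$jitter_sd)) else integer(n)
      pos <- if (truth$strand[i] == "+") pas[pick] + jit else pas[pick] - jit
      pos <- pmin(pmax(pos, 0L), chrom_len[[truth$chrom[i]]] - 1L)
      rows <- data.frame(chrom = truth$chrom[i], strand = truth$strand[i],
                         pos = as.integer(pos), sample_id = s,
                         stringsAsFactors = FALSE)
      trap <- sim$traps[sim$traps$gene_id == truth$gene_id[i], , drop = FALSE]
      if (nrow(trap) == 1) {
        n_art <- stats::rbinom(1, n, config$trap_read_frac)
        if (n_art > 0) {
          rows <- rbind(rows, data.frame(
            chrom = truth$chrom[i], strand = truth$strand[i],
            pos = rep(as.integer(trap$read_pos), n_art), sample_id = s,
            stringsAsFactors = FALSE))
        }
      }
      out[[length(out) + 1L]] <- rows
    }
  }
  reads <- do.call(rbind, out)
  attr(reads, "samples") <- samples
  reads
}

#' Run the full synthetic experiment and write its files
#'
#' Seeds the RNG from `config$seed`, generates genome, gene models,
#' known-site database, ground truth and per-sample reads, and writes them
#' under `out_dir` together with a ready-to-run pipeline configuration
#' (`config.json`). Identical configurations produce byte-identical files.
#'
#' @param config an `apa_sim_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the in-memory simulation objects plus a `paths` list.
#' @export
simulate_apa_experiment <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  sim <- generate_genome(config)
  reads <- generate_reads(sim, config)
  samples <- attr(reads, "samples")

  paths <- list(genome = file.path(out_dir, "genome.fa"),
                gene_models = file.path(out_dir, "genes.bed12"),
                sidecar = file.path(out_dir, "genes_sidecar.tsv"),
                known_pas = file.path(out_dir, "known_pas.bed"),
                truth = file.path(out_dir, "ground_truth.tsv"),
                config = file.path(out_dir, "config.json"))
  write_genome(sim$genome, paths$genome)
  write_gene_models(sim$gene_models, paths$gene_models, paths$sidecar)
  kp <- sim$known_pas[order(sim$known_pas$chrom, sim$known_pas$pos), ]
  utils::write.table(
    data.frame(kp$chrom, kp$pos, kp$pos + 1L, kp$site_id, 0L, kp$strand),
    paths$known_pas, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  read_paths <- list()
  for (s in names(samples)) {
    p <- file.path(out_dir, sprintf("reads_%s.bed", s))
    write_read_ends(reads[reads$sample_id == s, , drop = FALSE], p)
    read_paths[[s]] <- p
  }
  paths$reads <- read_paths

  # paths in the config are relative to the config file, so the whole
  # directory is byte-identical across runs and relocatable
  run_cfg <- list(genome = basename(paths$genome),
                  gene_models = basename(paths$gene_models),
                  sidecar = basename(paths$sidecar),
                  known_pas = basename(paths$known_pas),
                  reads = lapply(read_paths, basename),
                  conditions = as.list(samples),
                  control = "control", treated = "treated",
                  out_dir = "run",
                  params = list(ip_window = 20L, ip_max_a = 12L,
                                ip_run_a = 8L,
                                cluster_window = config$cluster_window,
                                min_cluster_reads = 5L, tts_window = 100L,
                                match_tol = 24L, alpha = 0.05,
                                exact_max_total = 200L))
  jsonlite::write_json(run_cfg, paths$config, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(sim, list(reads = reads, samples = samples, paths = paths)))
}
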