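# Shared fixtures and independent oracles. The oracles deliberately use
# different code paths from the implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# A genome where chrA consists of `prefix` then `window` then padding, so a
# plus-strand read ending at the last base of `prefix` sees exactly `window`
# downstream.
window_genome <- function(window, prefix = "CCCCC") {
  g <- Biostrings::DNAStringSet(paste0(prefix, window, strrep("G", 30)))
  names(g) <- "chrA"
  g
}

# One-row gene-model data.frame in the package convention.
make_gene <- function(gene_id, chrom, strand, start, end, stop_codon_pos,
                      utr3_start, utr3_end, tts_pos,
                      exon_starts = list(start), exon_ends = list(end)) {
  gm <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   start = start, end = end,
                   stop_codon_pos = stop_codon_pos,
                   utr3_start = utr3_start, utr3_end = utr3_end,
                   tts_pos = tts_pos, stringsAsFactors = FALSE)
  gm$exon_starts <- exon_starts
  gm$exon_ends <- exon_ends
  gm
}

make_read_ends <- function(pos, chrom = "chrA", strand = "+",
                           sample_id = "s1") {
  data.frame(chrom = chrom, strand = strand, pos = as.integer(pos),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# Independent snowball oracle: literal restatement of the rule on a
# position/count table, recomputing the maximum by scanning remaining
# positions each round (no vector bookkeeping shared with the implementation).
oracle_snowball <- function(pos, counts, window) {
  df <- data.frame(pos = pos, count = counts)
  df <- df[order(df$pos), ]
  clusters <- list()
  while (nrow(df) > 0) {
    best <- 1
    for (i in seq_len(nrow(df))) if (df$count[i] > df$count[best]) best <- i
    seed <- df$pos[best]
    member <- abs(df$pos - seed) <= window
    clusters[[length(clusters) + 1]] <-
      list(rep_pos = seed, count = sum(df$count[member]),
           members = df$pos[member])
    df <- df[!member, , drop = FALSE]
  }
  ord <- order(vapply(clusters, `[[`, numeric(1), "rep_pos"))
  clusters[ord]
}

# Independent internal-priming oracle: character-level re-scan of one read.
oracle_is_primed <- function(genome, chrom, strand, pos,
                             window = 20, max_a = 12, run_a = 8) {
  seq_str <- toupper(as.character(genome[[chrom]]))
  chars <- strsplit(seq_str, "")[[1]]
  n <- length(chars)
  if (strand == "+") {
    idx <- (pos + 2):(pos + 1 + window)  # 1-based downstream window
    w <- chars[idx[idx >= 1 & idx <= n]]
  } else {
    idx <- (pos - window + 1):pos
    w <- rev(chartr("ACGTN", "TGCAN", chars[idx[idx >= 1 & idx <= n]]))
  }
  n_a <- sum(w == "A")
  best <- 0; run <- 0
  for (ch in w) {
    run <- if (ch == "A") run + 1 else 0
    best <- max(best, run)
  }
  n_a > max_a || best >= run_a
}

# Two-sided exact p for a 2x2 table by direct enumeration of the fixed-margin
# family with dhyper, extremeness measured by deviation from the expected
# top-left cell.
oracle_exact_2x2 <- function(tab) {
  R1 <- sum(tab[1, ]); R2 <- sum(tab[2, ])
  C1 <- sum(tab[, 1]); N <- R1 + R2
  lo <- max(0, C1 - R2); hi <- min(R1, C1)
  supp <- lo:hi
  pr <- dhyper(supp, R1, R2, C1)
  E <- R1 * C1 / N
  min(sum(pr[abs(supp - E) >= abs(tab[1, 1] - E) - 1e-9]), 1)
}

# md5 of every file in a directory except those matched by `exclude`.
dir_checksums <- function(dir, exclude = "run\\.log$") {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl(exclude, files)]
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", dir, "/?"), "", names(sums))
  sums
}

# Small simulated experiment shared by several tests.
tiny_sim <- function(dir, seed = 11, ...) {
  args <- utils::modifyList(list(n_genes = 40, reads_per_gene = 120,
                                 n_priming_traps = 8, seed = seed),
                            list(...))
  simulate_apa_experiment(do.call(sim_config, args), dir)
}
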