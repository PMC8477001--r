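test_that("identical seeds give byte-identical outputs, different seeds differ", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  tiny_sim(d1, seed = 5)
  tiny_sim(d2, seed = 5)
  tiny_sim(d3, seed = 6)
  s1 <- dir_checksums(d1)
  s2 <- dir_checksums(d2)
  s3 <- dir_checksums(d3)
  expect_equal(names(s1), names(s2))
  expect_equal(unname(s1), unname(s2))
  expect_false(all(unname(s1) == unname(s3[names(s1)])))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frac_shifted_genes = 1.2), "fractions")
  expect_error(sim_config(pas_per_gene_probs = c(0.5, 0.5)), "probabilities")
  expect_error(sim_config(pas_spacing_min = 20, cluster_window = 24),
               "pas_spacing_min")
  expect_error(sim_config(n_genes = 0), "sizes")
})

test_that("trap-free 3'UTRs contain no window triggering the priming rule", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(dir, seed = 41, n_priming_traps = 0)
  gm <- sim$gene_models
  for (i in seq_len(nrow(gm))) {
    utr <- genome_subseq(sim$genome, gm$chrom[i], gm$utr3_start[i],
                         gm$utr3_end[i])
    sense <- if (gm$strand[i] == "+") utr else revcomp(utr)
    chars <- strsplit(sense, "")[[1]]
    expect_lt(max_char_run(sense, "A"), 8)
    if (length(chars) >= 20) {
      is_a <- chars == "A"
      win <- sum(is_a[1:20])
      worst <- win
      for (j in 21:length(chars)) {
        win <- win + is_a[j] - is_a[j - 20]
        worst <- max(worst, win)
      }
      expect_lte(worst, 12)
    }
  }
})

test_that("the known-site database holds the configured fraction of true PAS", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(dir, seed = 51, frac_known_pas = 1 / 3)
  total <- sum(sim$truth$n_pas)
  expect_equal(nrow(sim$known_pas), round(total / 3))
  # every database site is a true PAS
  truth_keys <- unlist(lapply(seq_len(nrow(sim$truth)), function(i)
    paste(sim$truth$chrom[i], sim$truth$strand[i],
          strsplit(sim$truth$pas_pos[i], ",")[[1]])))
  expect_true(all(paste(sim$known_pas$chrom, sim$known_pas$strand,
                        sim$known_pas$pos) %in% truth_keys))
})

test_that("shift classes match their planted usage fractions", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(dir, seed = 61)
  truth <- sim$truth
  shifted <- truth$shift_class != "unchanged"
  expect_equal(sum(shifted), round(0.2 * nrow(truth)))
  expect_equal(sum(truth$shift_class == "shortened"),
               round(0.85 * sum(shifted)))
  for (i in seq_len(nrow(truth))) {
    uc <- as.numeric(strsplit(truth$usage_control[i], ",")[[1]])
    ut <- as.numeric(strsplit(truth$usage_treated[i], ",")[[1]])
    expect_equal(sum(uc), 1, tolerance = 1e-6)
    expect_equal(sum(ut), 1, tolerance = 1e-6)
    cls <- truth$shift_class[i]
    if (cls == "shortened") expect_gt(ut[1], uc[1])
    if (cls == "lengthened") expect_lt(ut[1], uc[1])
    if (cls == "unchanged") expect_equal(ut, uc)
  }
})

test_that("jitter-free reads sit exactly on true PAS with the planted usage", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(dir, seed = 71, jitter_sd = 0, n_priming_traps = 0)
  truth <- sim$truth
  reads <- sim$reads
  samples <- sim$samples
  for (i in seq_len(nrow(truth))) {
    pas <- as.integer(strsplit(truth$pas_pos[i], ",")[[1]])
    sub <- reads[reads$chrom == truth$chrom[i] &
                   reads$strand == truth$strand[i] &
                   reads$pos %in% pas, , drop = FALSE]
    gene_reads <- reads[reads$chrom == truth$chrom[i] &
                          reads$pos >= min(pas) - 50 &
                          reads$pos <= max(pas) + 50 &
                          reads$strand == truth$strand[i], , drop = FALSE]
    expect_equal(nrow(sub), nrow(gene_reads))  # every read exactly at a PAS
  }
  # ground-truth usage fractions are recovered exactly by counting
  g <- truth[truth$n_pas >= 2, ][1, ]
  pas <- as.integer(strsplit(g$pas_pos, ",")[[1]])
  uc <- as.numeric(strsplit(g$usage_control, ",")[[1]])
  ctrl_samples <- names(samples)[samples == "control"]
  cnt <- vapply(pas, function(pp) sum(reads$pos == pp & reads$chrom == g$chrom &
                                        reads$strand == g$strand &
                                        reads$sample_id %in% ctrl_samples),
                numeric(1))
  # observed usage within 3 binomial SDs of the planted fractions
  n <- sum(cnt)
  expect_lt(abs(cnt[1] / n - uc[1]), 3 * sqrt(uc[1] * (1 - uc[1]) / n) + 1e-9)
})

test_that("multinomial PAS choice recovers planted usage at depth", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 2, reads_per_gene = 10000, jitter_sd = 0,
                    n_priming_traps = 0, frac_shifted_genes = 0,
                    pas_per_gene_probs = c(`1` = 0, `2` = 1, `3` = 0, `4` = 0),
                    proximal_usage_baseline = 0.3,
                    replicates_per_condition = 1, seed = 81)
  sim <- simulate_apa_experiment(cfg, dir)
  g <- sim$truth[1, ]
  pas <- as.integer(strsplit(g$pas_pos, ",")[[1]])
  reads <- sim$reads[sim$reads$sample_id == "control_rep1" &
                       sim$reads$chrom == g$chrom &
                       sim$reads$strand == g$strand &
                       sim$reads$pos %in% pas, ]
  n <- nrow(reads)
  prox_frac <- mean(reads$pos == pas[1])
  expect_lt(abs(prox_frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})
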