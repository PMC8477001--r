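ann_fixture <- function() {
  # plus-strand gene: [1000, 3000), CDS ends before 2400, UTR [2400, 3000),
  # TTS 2999, exons [1000,1500) and [1800,3000) (intron [1500,1800))
  make_gene("g1", "chrA", "+", 1000L, 3000L, 2399L, 2400L, 3000L, 2999L,
            exon_starts = list(c(1000L, 1800L)),
            exon_ends = list(c(1500L, 3000L)))
}

make_cluster <- function(rep_pos, strand = "+", chrom = "chrA") {
  data.frame(cluster_id = "c1", chrom = chrom, strand = strand,
             rep_pos = as.integer(rep_pos), span_start = as.integer(rep_pos),
             span_end = as.integer(rep_pos + 1), count = 10L,
             stringsAsFactors = FALSE)
}

test_that("cluster categories follow the TTS > UTR3 > exon > intron precedence", {
  gm <- ann_fixture()
  cases <- list(
    list(pos = 2999, cat = "TTS", gene = "g1"),      # exactly at the TTS
    list(pos = 2920, cat = "TTS", gene = "g1"),      # within tts_window
    list(pos = 2500, cat = "UTR3", gene = "g1"),     # mid-UTR, 499 nt from TTS
    list(pos = 1200, cat = "exon", gene = "g1"),
    list(pos = 1600, cat = "intron", gene = "g1"),
    list(pos = 5000, cat = "intergenic", gene = NA_character_))
  for (cs in cases) {
    a <- annotate_clusters(make_cluster(cs$pos), gm, tts_window = 100)
    expect_equal(a$category, cs$cat, info = paste("pos", cs$pos))
    expect_equal(a$gene_id, cs$gene, info = paste("pos", cs$pos))
  }
  # antisense cluster in the UTR is intergenic: same-strand genes only
  a <- annotate_clusters(make_cluster(2500, strand = "-"), gm)
  expect_equal(a$category, "intergenic")
})

test_that("known status needs a same-strand database site within tolerance", {
  gm <- ann_fixture()
  db <- data.frame(chrom = "chrA", pos = 2980L, strand = "+",
                   stringsAsFactors = FALSE)
  expect_true(annotate_clusters(make_cluster(2999), gm, db,
                                match_tolerance = 24)$known)
  expect_false(annotate_clusters(make_cluster(2999), gm, db,
                                 match_tolerance = 10)$known)
  db$strand <- "-"
  expect_false(annotate_clusters(make_cluster(2999), gm, db,
                                 match_tolerance = 24)$known)
  expect_false(annotate_clusters(make_cluster(5000), gm, NULL)$known)
})

test_that("per-gene PAS counts use only UTR-type clusters", {
  gm <- ann_fixture()
  cl <- rbind(make_cluster(2999), make_cluster(2500), make_cluster(1200))
  ann <- annotate_clusters(cl, gm)
  s <- summarize_pas_per_gene(ann)
  expect_equal(s$per_gene$n_pas[s$per_gene$gene_id == "g1"], 2L)

  only_exon <- annotate_clusters(make_cluster(1200), gm)
  s2 <- summarize_pas_per_gene(only_exon)
  expect_equal(nrow(s2$per_gene), 0L)
  expect_equal(unname(s2$histogram), rep(0L, 4))
})

test_that("jitter-free, trap-free discovery recovers the true PAS exactly", {
  dir <- withr::local_tempdir()
  sim <- tiny_sim(dir, seed = 31, jitter_sd = 0, n_priming_traps = 0)
  flt <- filter_read_ends(sim$reads, sim$genome)
  cl <- cluster_read_ends(flt$kept, window = 24, min_cluster_reads = 5)
  ann <- annotate_clusters(cl, sim$gene_models, sim$known_pas)

  truth_pos <- lapply(strsplit(sim$truth$pas_pos, ","), as.integer)
  truth_keys <- unlist(lapply(seq_len(nrow(sim$truth)), function(i)
    paste(sim$truth$chrom[i], sim$truth$strand[i], truth_pos[[i]])))
  expect_setequal(paste(ann$chrom, ann$strand, ann$rep_pos), truth_keys)
  expect_true(all(ann$category %in% c("TTS", "UTR3")))

  s <- summarize_pas_per_gene(ann)
  truth_counts <- setNames(sim$truth$n_pas, sim$truth$gene_id)
  expect_equal(s$per_gene$n_pas,
               unname(truth_counts[s$per_gene$gene_id]))
  expect_equal(nrow(s$per_gene), nrow(sim$truth))
})
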