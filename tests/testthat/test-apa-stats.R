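make_profile <- function(control_counts, treated_counts, distances,
                         strand = "+") {
  list(gene_id = "g", strand = strand,
       pas_pos = seq_along(distances),
       distances = distances,
       counts = rbind(control = control_counts, treated = treated_counts))
}

test_that("profiles order PAS proximal to distal, strand-aware", {
  cl_plus <- data.frame(
    cluster_id = c("c1", "c2"), chrom = "chrA", strand = "+",
    rep_pos = c(1800L, 1200L), span_start = c(1800L, 1200L),
    span_end = c(1801L, 1201L), count = c(10L, 20L),
    count.s1 = c(4L, 12L), count.s2 = c(6L, 8L),
    category = "UTR3", gene_id = "gp", known = FALSE,
    in_tts_window = FALSE, in_utr3 = TRUE, stringsAsFactors = FALSE)
  gm <- make_gene("gp", "chrA", "+", 500L, 2000L, 1000L, 1001L, 2000L, 1999L)
  prof <- build_profiles(cl_plus, gm, c(s1 = "control", s2 = "treated"))
  expect_equal(prof$gp$pas_pos, c(1200L, 1800L))
  expect_equal(prof$gp$distances, c(200L, 800L))
  expect_equal(prof$gp$counts["control", ], c(12, 4), ignore_attr = TRUE)

  cl_minus <- cl_plus
  cl_minus$strand <- "-"
  cl_minus$rep_pos <- c(1900L, 1100L)
  cl_minus$gene_id <- "gmn"
  gmn <- make_gene("gmn", "chrA", "-", 500L, 2500L, 2000L, 500L, 2000L, 500L)
  prof <- build_profiles(cl_minus, gmn, c(s1 = "control", s2 = "treated"))
  expect_equal(prof$gmn$pas_pos, c(1900L, 1100L))
  expect_equal(prof$gmn$distances, c(100L, 900L))

  # a gene with a single UTR-type cluster is excluded and reported
  single <- cl_plus[1, ]
  prof <- build_profiles(single, gm, c(s1 = "control", s2 = "treated"))
  expect_length(prof, 0L)
  expect_equal(attr(prof, "skipped"), "gp")
})

test_that("CULI reproduces its definition on worked examples", {
  # identical usage -> 0
  p <- make_profile(c(50, 50), c(20, 20), c(200, 800))
  expect_equal(compute_culi(p, "treated", "control"), 0)
  # all-proximal control vs all-distal treated -> 1 - 200/800
  p <- make_profile(c(100, 0), c(0, 100), c(200, 800))
  expect_equal(compute_culi(p, "treated", "control"), 0.75)
  # hand-computed mixed case
  p <- make_profile(c(80, 20), c(30, 70), c(200, 800))
  expect_equal(compute_culi(p, "treated", "control"), 0.375)
  # zero total in one condition -> NA (gene skipped)
  p <- make_profile(c(0, 0), c(30, 70), c(200, 800))
  expect_true(is.na(compute_culi(p, "treated", "control")))
})

test_that("CULI is antisymmetric and bounded by 1 - dmin/dmax", {
  set.seed(99)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    d <- sort(sample(50:2000, k))
    ctrl <- rmultinom(1, sample(20:500, 1), runif(k))[, 1]
    trt <- rmultinom(1, sample(20:500, 1), runif(k))[, 1]
    if (sum(ctrl) == 0 || sum(trt) == 0) next
    p <- make_profile(ctrl, trt, d)
    culi <- compute_culi(p, "treated", "control")
    expect_equal(culi, -compute_culi(p, "control", "treated"))
    expect_lte(abs(culi), 1 - min(d) / max(d) + 1e-12)
  }
})

test_that("the trend test handles flat, extreme and degenerate tables", {
  flat <- trend_test(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$p, 1)
  expect_equal(flat$stat, 0)

  # fully crossed 2x2: exact p equals the enumerated two-sided tail
  tab <- rbind(c(20, 0), c(0, 20))
  tt <- trend_test(tab)
  expect_equal(tt$method, "exact")
  expect_equal(tt$p, 2 / choose(40, 20), tolerance = 1e-12)
  expect_equal(tt$p, oracle_exact_2x2(tab), tolerance = 1e-12)

  # all-zero column dropped with re-ranking; collapse to one column untestable
  with_zero <- trend_test(rbind(c(10, 0, 5), c(8, 0, 9)))
  no_zero <- trend_test(rbind(c(10, 5), c(8, 9)))
  expect_equal(with_zero$p, no_zero$p)
  expect_equal(with_zero$k, 2L)
  expect_true(is.na(trend_test(rbind(c(10, 0), c(8, 0)))$p))
  expect_true(is.na(trend_test(rbind(c(0, 0), c(8, 2)))$p))

  expect_error(trend_test(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("exact p agrees with the hypergeometric oracle on random 2x2 tables", {
  set.seed(123)
  for (i in 1:100) {
    tab <- matrix(rpois(4, sample(3:30, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    tt <- trend_test(tab)
    expect_equal(tt$method, "exact")
    expect_equal(tt$p, oracle_exact_2x2(tab), tolerance = 1e-12)
  }
})

test_that("the asymptotic statistic matches the canonical trend chi-square", {
  # z^2 differs from prop.trend.test's chi-square only by the N/(N-1)
  # conditional-variance factor
  set.seed(7)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(2 * k, 80) + 1, 2)
    N <- sum(tab)
    tt <- trend_test(tab, exact_max_total = 0)
    pt <- suppressWarnings(stats::prop.trend.test(tab[2, ], colSums(tab),
                                                  score = seq_len(k)))
    expect_equal(tt$stat^2 * N / (N - 1), unname(pt$statistic),
                 tolerance = 1e-10)
  }
})

test_that("exact and asymptotic branches converge as tables grow", {
  diffs <- vapply(c(40, 100, 200, 400), function(n) {
    tab <- rbind(round(n * c(0.3, 0.4, 0.3)), round(n * c(0.38, 0.4, 0.22)))
    abs(trend_test(tab, exact_max_total = 2000)$p -
          trend_test(tab, exact_max_total = 0)$p)
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))  # shrinks with table size
  expect_lt(diffs[length(diffs)], 0.01)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # direct formula on an irregular vector
  p <- c(0.001, 0.02, 0.04, 0.2, 0.9)
  m <- length(p)
  manual <- rev(cummin(rev(sort(p) * m / seq_len(m))))[rank(p)]
  expect_equal(bh_fdr(p), pmin(manual, 1))
})

test_that("shift calls follow the q/CULI rule and are summarized", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    culi = c(-0.4, -0.9, 0.3, 0.0),
                    q = c(0.01, 0.2, 0.02, 0.001))
  cl <- classify_genes(res, alpha = 0.05)
  expect_equal(cl$results$call, c("shortened", "unchanged", "lengthened",
                                  "unchanged"))
  expect_equal(cl$summary$n_altered, 2L)
  expect_equal(cl$summary$frac_shortened, 0.5)
})

test_that("distal/proximal ratios apply the continuity correction", {
  p <- make_profile(c(50, 100), c(30, 60), c(200, 800))
  r <- distal_proximal_ratio(p, "treated", "control")
  expect_equal(unname(r$ratio["control"]), 2.0)
  expect_equal(r$fold_change, 1.0)

  p0 <- make_profile(c(0, 10), c(10, 10), c(200, 800))
  r0 <- distal_proximal_ratio(p0, "treated", "control")
  expect_equal(unname(r0$ratio["control"]), 10.5 / 0.5)
})
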