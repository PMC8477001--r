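# Linear trend test on a 2 x k condition-by-ordered-PAS count table:
# Cochran-Armitage with integer rank scores 1..k. Writing T = sum_j s_j * c_j
# for the treated-row counts c_j, the statistic is the standardized score sum
#   Z = (T - mu) / sigma
# with mu and sigma^2 the conditional (fixed-margin, multivariate
# hypergeometric) moments; Z > 0 means the treated row is weighted toward
# distal sites. For large tables the two-sided p-value comes from the normal
# reference; for small tables (total <= exact_max_total) the exact
# conditional distribution of T is computed by dynamic programming over the
# fixed-margin table family and the two-sided p is the probability of tables
# at least as extreme in |T - mu|.

#' Cochran-Armitage linear trend test for a 2 x k ordered count table
#'
#' Columns with zero total are dropped (re-ranking the remainder); a table
#' collapsing to fewer than two columns, or with an empty row, is untestable
#' and returns `NA` statistics.
#'
#' @param counts 2 x k integer matrix; row 1 = control, row 2 = treated,
#'   columns ordered proximal to distal.
#' @param exact_max_total use the exact conditional p when the table total is
#'   at most this (set to 0 to force the asymptotic branch).
#' @return list with `stat` (signed Z), `p` (two-sided), `method`
#'   (`"exact"` or `"asymptotic"`), `k` (columns used).
#' @export
#' @examples
#' trend_test(rbind(c(10, 10), c(10, 10)))$p   # 1: no trend
trend_test <- function(counts, exact_max_total = 200L) {
  stopifnot(is.matrix(counts), nrow(counts) == 2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  k <- ncol(counts)
  untestable <- list(stat = NA_real_, p = NA_real_, method = "untestable",
                     k = k)
  if (k < 2 || any(rowSums(counts) == 0)) return(untestable)

  s <- seq_len(k)
  n_j <- colSums(counts)
  N <- sum(n_j)
  Rt <- sum(counts[2, ])
  Rc <- N - Rt
  T_obs <- sum(s * counts[2, ])
  mu <- Rt / N * sum(s * n_j)
  v <- Rt * Rc / (N^2 * (N - 1)) * (N * sum(n_j * s^2) - sum(n_j * s)^2)
  if (v <= 0) return(list(stat = 0, p = 1, method = "degenerate", k = k))
  z <- (T_obs - mu) / sqrt(v)

  if (N <= exact_max_total) {
    dist <- exact_score_distribution(n_j, Rt, s)
    dev <- abs(dist$t - mu)
    p <- sum(dist$prob[dev >= abs(T_obs - mu) - 1e-9])
    list(stat = z, p = min(p, 1), method = "exact", k = k)
  } else {
    list(stat = z, p = 2 * stats::pnorm(-abs(z)), method = "asymptotic",
         k = k)
  }
}

# Exact conditional distribution of T = sum_j s_j * c_j where the treated row
# (c_1..c_k) ranges over all tables with column totals n_j and row total Rt,
# weighted by prod_j choose(n_j, c_j) (multivariate hypergeometric).
# DP over columns on a (row-total so far) x (score-sum so far) weight matrix.
#' @keywords internal
exact_score_distribution <- function(n_j, Rt, s) {
  k <- length(n_j)
  t_max <- sum(s * pmin(n_j, Rt))
  w <- matrix(0, nrow = Rt + 1L, ncol = t_max + 1L)
  w[1, 1] <- 1
  for (j in seq_len(k)) {
    nw <- matrix(0, nrow = Rt + 1L, ncol = t_max + 1L)
    for (c in 0:min(n_j[j], Rt)) {
      dt <- s[j] * c
      rows <- 1:(Rt + 1L - c)
      cols <- 1:(t_max + 1L - dt)
      nw[rows + c, cols + dt] <- nw[rows + c, cols + dt] +
        w[rows, cols] * choose(n_j[j], c)
    }
    w <- nw
  }
  weights <- w[Rt + 1L, ]
  keep <- weights > 0
  t_vals <- (0:t_max)[keep]
  prob <- weights[keep] / sum(weights[keep])
  list(t = t_vals, prob = prob)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_(j >= i) p_(j) * m / j`,
#' capped at 1. `NA` p-values propagate to `NA` q-values and do not count
#' toward `m`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Call per-gene APA shifts at an FDR threshold
#'
#' A gene is `shortened` when `q < alpha` and CULI < 0, `lengthened` when
#' `q < alpha` and CULI > 0, and `unchanged` otherwise.
#'
#' @param results data.frame with columns `culi` and `q`.
#' @param alpha FDR threshold (default 0.05).
#' @return list with `results` (input plus a `call` column) and `summary`
#'   (`n_tested`, `n_altered`, `frac_shortened` among altered genes).
#' @export
classify_genes <- function(results, alpha = 0.05) {
  sig <- !is.na(results$q) & results$q < alpha
  call <- ifelse(sig & results$culi < 0, "shortened",
                 ifelse(sig & results$culi > 0, "lengthened", "unchanged"))
  results$call <- call
  n_altered <- sum(call != "unchanged")
  list(results = results,
       summary = list(n_tested = sum(!is.na(results$q)),
                      n_altered = n_altered,
                      frac_shortened = if (n_altered > 0)
                        sum(call == "shortened") / n_altered else NA_real_))
}

#' Run the full per-gene APA shift analysis
#'
#' CULI, trend test, BH adjustment, and shift calls for a set of gene
#' profiles. Genes with zero total reads in either condition, or whose count
#' table collapses below two usable PAS columns, are skipped and listed in
#' the `skipped` attribute.
#'
#' @param profiles list from [build_profiles()].
#' @param treated,control condition names.
#' @param alpha FDR threshold for calls.
#' @param exact_max_total passed to [trend_test()].
#' @return data.frame with columns `gene_id`, `n_pas`, `culi`, `trend_stat`,
#'   `p`, `q`, `call`; attributes `summary` (from [classify_genes()]) and
#'   `skipped`.
#' @export
apa_test <- function(profiles, treated, control, alpha = 0.05,
                     exact_max_total = 200L) {
  rows <- list()
  skipped <- character(0)
  for (prof in profiles) {
    culi <- compute_culi(prof, treated, control)
    if (is.na(culi)) {
      skipped <- c(skipped, prof$gene_id)
      next
    }
    tt <- trend_test(prof$counts[c(control, treated), , drop = FALSE],
                     exact_max_total = exact_max_total)
    if (is.na(tt$p)) {
      skipped <- c(skipped, prof$gene_id)
      next
    }
    rows[[prof$gene_id]] <- data.frame(
      gene_id = prof$gene_id, n_pas = ncol(prof$counts), culi = culi,
      trend_stat = tt$stat, p = tt$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, unname(rows))
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), n_pas = integer(),
                      culi = numeric(), trend_stat = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  }
  res$q <- bh_fdr(res$p)
  cl <- classify_genes(res, alpha = alpha)
  res <- cl$results[order(cl$results$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "summary") <- cl$summary
  attr(res, "skipped") <- skipped
  res
}
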