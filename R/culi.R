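# CULI: a signed, per-gene 3'UTR length index. For each condition the mean
# normalized isoform length is L = sum_i u_i * d_i / d_max, where u_i is the
# condition's usage fraction of PAS i and d_i its distance from the stop
# codon; CULI = L(treated) - L(control). Positive values mean the treated
# condition uses longer 3'UTRs (lengthening), negative values shortening.
# The index is antisymmetric under condition swap and bounded:
# |CULI| <= 1 - d_min/d_max.

#' Compute the 3'UTR length index (CULI) for one gene
#'
#' @param profile one profile from [build_profiles()].
#' @param treated,control condition names (rows of `profile$counts`).
#' @return CULI value in `[-1, 1]`, or `NA` when either condition has zero
#'   total reads (the gene is untestable).
#' @export
#' @examples
#' prof <- list(counts = rbind(ctrl = c(80, 20), kd = c(30, 70)),
#'              distances = c(200, 800))
#' compute_culi(prof, treated = "kd", control = "ctrl")  # 0.375
compute_culi <- function(profile, treated, control) {
  counts <- profile$counts
  if (!all(c(treated, control) %in% rownames(counts))) {
    stop("treated/control must name rows of the profile count matrix",
         call. = FALSE)
  }
  tot_t <- sum(counts[treated, ])
  tot_c <- sum(counts[control, ])
  if (tot_t == 0 || tot_c == 0) return(NA_real_)
  d <- profile$distances / max(profile$distances)
  sum(counts[treated, ] / tot_t * d) - sum(counts[control, ] / tot_c * d)
}
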