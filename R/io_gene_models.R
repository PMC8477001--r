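# Gene models: BED12 (thickStart/thickEnd delimit the CDS; the 3'UTR is the
# block between the CDS end and the transcript end in transcription order)
# plus a sidecar TSV making the stop-codon and transcription-terminal-site
# (TTS) coordinates explicit.

bed12_cols <- c("chrom", "start", "end", "name", "score", "strand",
                "thickStart", "thickEnd", "itemRgb", "blockCount",
                "blockSizes", "blockStarts")

#' Read gene models from BED12 plus a sidecar TSV
#'
#' Coordinates are kept in the BED-native 0-based half-open convention.
#' On the plus strand the 3'UTR is `[thickEnd, end)` and the TTS is `end - 1`;
#' on the minus strand the 3'UTR is `[start, thickStart)` and the TTS is
#' `start`. The sidecar TSV (columns `gene_id`, `stop_codon_pos`, `tts_pos`)
#' states the stop-codon coordinate used for proximal/distal distances; every
#' BED gene must appear in it.
#'
#' @param bed12_path path to a BED12 file of gene models.
#' @param sidecar_path path to the sidecar TSV.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `stop_codon_pos`, `utr3_start`, `utr3_end`, `tts_pos` and
#'   list-columns `exon_starts`, `exon_ends` (0-based half-open).
#' @export
read_gene_models <- function(bed12_path, sidecar_path) {
  if (file.size(bed12_path) == 0) {
    return(empty_gene_models())
  }
  bed <- utils::read.table(bed12_path, sep = "\t", header = FALSE,
                           col.names = bed12_cols,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character", "character",
                                          "integer", "integer", "character",
                                          "integer", "character", "character"))
  side <- utils::read.table(sidecar_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  missing <- setdiff(bed$name, side$gene_id)
  if (length(missing)) {
    stop("gene(s) missing from sidecar TSV: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  side <- side[match(bed$name, side$gene_id), ]

  plus <- bed$strand == "+"
  utr3_start <- ifelse(plus, bed$thickEnd, bed$start)
  utr3_end   <- ifelse(plus, bed$end, bed$thickStart)

  sizes  <- lapply(strsplit(bed$blockSizes, ","), as.integer)
  starts <- lapply(strsplit(bed$blockStarts, ","), as.integer)
  exon_starts <- mapply(function(gs, st) gs + st, bed$start, starts,
                        SIMPLIFY = FALSE)
  exon_ends <- mapply(`+`, exon_starts, sizes, SIMPLIFY = FALSE)

  gm <- data.frame(gene_id = bed$name, chrom = bed$chrom, strand = bed$strand,
                   start = bed$start, end = bed$end,
                   stop_codon_pos = side$stop_codon_pos,
                   utr3_start = utr3_start, utr3_end = utr3_end,
                   tts_pos = side$tts_pos,
                   stringsAsFactors = FALSE)
  gm$exon_starts <- exon_starts
  gm$exon_ends <- exon_ends
  gm
}

#' @keywords internal
empty_gene_models <- function() {
  gm <- data.frame(gene_id = character(), chrom = character(),
                   strand = character(), start = integer(), end = integer(),
                   stop_codon_pos = integer(), utr3_start = integer(),
                   utr3_end = integer(), tts_pos = integer(),
                   stringsAsFactors = FALSE)
  gm$exon_starts <- list()
  gm$exon_ends <- list()
  gm
}

#' Write gene models as BED12 plus sidecar TSV
#'
#' Inverse of [read_gene_models()]; rows are written sorted by
#' (`chrom`, `start`).
#'
#' @param gene_models data.frame as returned by [read_gene_models()].
#' @param bed12_path,sidecar_path output paths.
#' @return `bed12_path`, invisibly.
#' @export
write_gene_models <- function(gene_models, bed12_path, sidecar_path) {
  gm <- gene_models[order(gene_models$chrom, gene_models$start), ]
  plus <- gm$strand == "+"
  thickStart <- ifelse(plus, gm$start, gm$utr3_end)
  thickEnd   <- ifelse(plus, gm$utr3_start, gm$end)
  sizes  <- mapply(function(s, e) paste(e - s, collapse = ","),
                   gm$exon_starts, gm$exon_ends)
  starts <- mapply(function(s, g) paste(s - g, collapse = ","),
                   gm$exon_starts, gm$start)
  bed <- data.frame(gm$chrom, gm$start, gm$end, gm$gene_id, 0L, gm$strand,
                    thickStart, thickEnd, "0",
                    lengths(gm$exon_starts), sizes, starts)
  utils::write.table(bed, bed12_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- data.frame(gene_id = gm$gene_id,
                     stop_codon_pos = gm$stop_codon_pos,
                     tts_pos = gm$tts_pos)
  utils::write.table(side, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(bed12_path)
}
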