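# Read 3'-end extraction: every mapped read is reduced to the genomic
# coordinate of its 3'-most aligned reference base (the candidate cleavage
# position). Plus strand: last aligned base; minus strand: first aligned
# reference base. Duplicates are not collapsed; counts are read counts.

#' Read per-sample read 3'-end positions
#'
#' Accepts either a BED6 file with one line per read (the interval is the
#' single 3'-end base, `[pos, pos + 1)`) or a SAM/BAM file of alignments.
#' For SAM/BAM, only mapped primary non-supplementary records are used; the
#' number of skipped records is reported in the `n_skipped` attribute.
#'
#' @param path path ending in `.bed`, `.sam` or `.bam`.
#' @param sample_id sample label attached to every read.
#' @return a `data.frame` with columns `chrom`, `strand`, `pos` (0-based
#'   coordinate of the read 3' end) and `sample_id`, plus attribute
#'   `n_skipped`.
#' @export
read_read_ends <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    read_ends_from_bed(path, sample_id)
  } else if (ext %in% c("sam", "bam")) {
    read_ends_from_sam(path, sample_id, is_sam = ext == "sam")
  } else {
    stop("unsupported read file extension '.", ext,
         "' (expected .bed, .sam or .bam)", call. = FALSE)
  }
}

#' @keywords internal
read_ends_from_bed <- function(path, sample_id) {
  if (file.size(path) == 0) {
    out <- data.frame(chrom = character(), strand = character(),
                      pos = integer(), sample_id = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character"))
  if (any(bed$V3 - bed$V2 != 1L)) {
    stop("read-end BED must contain single-base intervals", call. = FALSE)
  }
  if (!all(bed$V6 %in% c("+", "-"))) {
    stop("read-end BED strand column must be + or -", call. = FALSE)
  }
  out <- data.frame(chrom = bed$V1, strand = bed$V6, pos = bed$V2,
                    sample_id = sample_id, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- 0L
  out
}

# Reference-space width of a CIGAR string: sum of M/D/N/=/X operation lengths.
#' @keywords internal
cigar_ref_width <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    len <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

#' @keywords internal
read_ends_from_sam <- function(path, sample_id, is_sam) {
  if (is_sam) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam))
  } else {
    bam <- path
  }
  p <- Rsamtools::ScanBamParam(what = c("rname", "strand", "pos", "cigar"),
                               flag = Rsamtools::scanBamFlag(
                                 isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n_total <- Rsamtools::countBam(bam)$records
  n_used <- length(rec$pos)
  pos0 <- rec$pos - 1L  # SAM POS is 1-based leftmost
  minus <- as.character(rec$strand) == "-"
  end3 <- ifelse(minus, pos0, pos0 + cigar_ref_width(rec$cigar) - 1L)
  out <- data.frame(chrom = as.character(rec$rname),
                    strand = ifelse(minus, "-", "+"),
                    pos = as.integer(end3),
                    sample_id = sample_id, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_total - n_used
  out
}

#' Write read 3'-end positions as BED6
#'
#' One line per read, sorted by (`chrom`, `pos`, `strand`); the name field is
#' the sample id and the score field 0.
#'
#' @param read_ends data.frame with `chrom`, `strand`, `pos`, `sample_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_ends <- function(read_ends, path) {
  re <- read_ends[order(read_ends$chrom, read_ends$pos, read_ends$strand), ]
  bed <- data.frame(re$chrom, re$pos, re$pos + 1L, re$sample_id, 0L, re$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
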