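#' Aligned read records
#'
#' The package-internal abstraction over SAM records: one row per read
#' with the 1-based inclusive reference interval covered by its aligned
#' (CIGAR reference-consuming) bases. Soft-clipped bases are never part
#' of the interval, so `start` is the first RT-templated reference
#' position of the read.
#'
#' @param transcript transcript name (recycled if length 1).
#' @param start,end 1-based inclusive aligned interval; `start <= end`.
#' @param mapped logical; unmapped reads contribute nothing downstream.
#' @param strand `"+"` or `"-"`. Gene-specific priming makes the
#'   protocol strand-specific; minus-strand reads are rejected at
#'   counting.
#'
#' @return A `data.frame` of class `aligned_reads` with columns
#'   `transcript`, `start`, `end`, `mapped`, `strand`.
#' @examples
#' aligned_reads("toy", start = c(8, 8, 12), end = c(20, 20, 20))
#' @export
aligned_reads <- function(transcript, start, end, mapped = TRUE,
                          strand = "+") {
  n <- max(length(start), length(end))
  transcript <- rep_len(as.character(transcript), n)
  start <- as.integer(rep_len(start, n))
  end <- as.integer(rep_len(end, n))
  mapped <- rep_len(as.logical(mapped), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(start) | is.na(end))) stop("NA read coordinates")
  if (any(start < 1L)) stop("read start < 1")
  if (any(start > end)) stop("read start > end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  structure(
    data.frame(transcript = transcript, start = start, end = end,
               mapped = mapped, strand = strand,
               stringsAsFactors = FALSE),
    class = c("aligned_reads", "data.frame")
  )
}

#' Read alignments from SAM or BAM
#'
#' Wraps Rsamtools/GenomicAlignments: SAM input is converted to BAM on
#' the fly, reference-consumed widths come from the CIGAR (soft clips
#' excluded), and unmapped records are kept with `mapped = FALSE`.
#'
#' @param path SAM (`.sam`) or BAM file.
#' @param transcript optional transcript name; records on other
#'   references are dropped with a message.
#' @return An [aligned_reads()] data frame.
#' @export
read_alignments <- function(path, transcript = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar", "flag", "strand")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !bitwAnd(x$flag, 4L)
  rn <- as.character(x$rname)
  if (!is.null(transcript)) {
    keep <- is.na(rn) | rn == transcript
    if (!all(keep)) {
      message(sum(!keep), " records on other references dropped")
      x <- lapply(x, `[`, keep)
      mapped <- mapped[keep]
      rn <- rn[keep]
    }
    rn[is.na(rn)] <- transcript
  }
  width <- rep(1L, length(mapped))
  width[mapped] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar[mapped])
  start <- ifelse(mapped, x$pos, 1L)
  strand <- as.character(x$strand)
  strand[is.na(strand) | strand == "*"] <- "+"
  aligned_reads(
    transcript = rn,
    start = start,
    end = start + width - 1L,
    mapped = mapped,
    strand = strand
  )
}

#' Write aligned reads as SAM
#'
#' Emits a minimal, valid single-reference SAM file (used by the read
#' simulator; the counting functions read it back through
#' [read_alignments()]). Each mapped read gets a pure-match CIGAR and
#' its reference-forward sequence.
#'
#' @param reads an [aligned_reads()] data frame.
#' @param reference the [transcript_reference()] the reads belong to.
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  stopifnot(inherits(reference, "transcript_reference"))
  if (any(reads$transcript != reference$name)) {
    stop("reads reference a different transcript than ", reference$name)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$name, reference$length),
    sprintf("@PG\tID:tbseq\tPN:tbseq\tVN:%s",
            as.character(packageVersion("tbseq")))
  ), con)
  n <- nrow(reads)
  if (n == 0L) return(invisible(path))
  # DNA-alphabet copy of the reference for SEQ fields
  dna <- chartr("U", "T", reference$sequence)
  len <- reads$end - reads$start + 1L
  seqs <- substring(dna, reads$start, reads$end)
  flag <- ifelse(reads$mapped, ifelse(reads$strand == "-", 16L, 0L), 4L)
  lines <- sprintf(
    "read%07d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
    seq_len(n), flag,
    ifelse(reads$mapped, reads$transcript, "*"),
    ifelse(reads$mapped, reads$start, 0L),
    ifelse(reads$mapped, 60L, 0L),
    ifelse(reads$mapped, sprintf("%dM", len), "*"),
    ifelse(reads$mapped, seqs, "*")
  )
  writeLines(lines, con)
  invisible(path)
}
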