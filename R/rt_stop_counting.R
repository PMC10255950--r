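#' Count RT stop and read-through events per nucleotide
#'
#' Converts aligned RT-derived reads into per-position event counts on
#' one transcript. For a mapped read aligned over `[s, e]`, a *stop* is
#' recorded at `s + stop_offset` (the 5'-most aligned base by default:
#' reverse transcription, walking 3'->5' on the template, terminated
#' there, placing the scission on the phosphodiester 5' of that base)
#' and a *read-through* at every position `p` with `s < p <= e`. The
#' read's own terminal position is never a read-through for itself.
#'
#' @param reads an [aligned_reads()] data frame (or any data frame with
#'   columns `transcript`, `start`, `end`, and optionally `mapped`,
#'   `strand`).
#' @param reference a [transcript_reference()].
#' @param stop_offset where the stop is attributed relative to the
#'   read's 5'-most aligned base: one of -1, 0, +1. Default 0.
#' @param exclude_region optional `c(start, end)` 1-based inclusive
#'   interval (e.g. the RT primer binding site) whose positions record
#'   no stop events; read-throughs are still counted there.
#'
#' @details
#' Reads are validated before counting: unmapped reads contribute
#' nothing; minus-strand reads are rejected with a warning (the
#' gene-specific-primed protocol is strand-specific); reads whose
#' interval exceeds the reference length are rejected and counted in
#' the `n_rejected` attribute. Counts are order-invariant and additive
#' across read sets. A read whose offset stop position falls outside
#' the transcript or inside `exclude_region` still contributes its
#' read-throughs.
#'
#' @return A data frame of class `nt_coverage` with one row per
#'   reference position and columns `position`, `base`, `n_stop`,
#'   `n_readthrough`; attributes `transcript`, `n_rejected`,
#'   `n_reads_used`.
#' @examples
#' ref <- transcript_reference("toy", strrep("A", 20))
#' rd <- aligned_reads("toy", start = c(8, 8, 12), end = c(20, 20, 20))
#' cov <- count_rt_events(rd, ref)
#' cov$n_stop[c(8, 12)]       # 2, 1
#' cov$n_readthrough[c(10, 15)] # 2, 3
#' @export
count_rt_events <- function(reads, reference, stop_offset = 0L,
                            exclude_region = NULL) {
  stopifnot(inherits(reference, "transcript_reference"))
  stop_offset <- as.integer(stop_offset)
  if (!stop_offset %in% c(-1L, 0L, 1L)) {
    stop("stop_offset must be -1, 0 or +1")
  }
  if (!is.null(exclude_region)) {
    exclude_region <- as.integer(exclude_region)
    if (length(exclude_region) != 2L || exclude_region[1] > exclude_region[2]) {
      stop("exclude_region must be c(start, end) with start <= end")
    }
  }
  L <- reference$length
  stopifnot(is.data.frame(reads))
  n_rejected <- 0L
  if (nrow(reads) > 0L) {
    unknown <- unique(reads$transcript[reads$transcript != reference$name])
    if (length(unknown)) {
      stop("reads reference unknown transcript(s): ",
           paste(unknown, collapse = ", "))
    }
    mapped <- if ("mapped" %in% names(reads)) reads$mapped else TRUE
    reads <- reads[mapped, , drop = FALSE]
    if ("strand" %in% names(reads) && any(reads$strand == "-")) {
      n_minus <- sum(reads$strand == "-")
      warning(n_minus, " minus-strand read(s) rejected: ",
              "gene-specific priming yields forward-strand alignments only")
      n_rejected <- n_rejected + n_minus
      reads <- reads[reads$strand != "-", , drop = FALSE]
    }
    oob <- reads$start < 1L | reads$end > L
    if (any(oob)) {
      warning(sum(oob), " read(s) with interval outside the reference ",
              "rejected")
      n_rejected <- n_rejected + sum(oob)
      reads <- reads[!oob, , drop = FALSE]
    }
  }

  n_stop <- integer(L)
  n_rt <- integer(L)
  if (nrow(reads) > 0L) {
    sp <- reads$start + stop_offset
    ok <- sp >= 1L & sp <= L
    if (!is.null(exclude_region)) {
      ok <- ok & !(sp >= exclude_region[1] & sp <= exclude_region[2])
    }
    n_stop <- tabulate(sp[ok], nbins = L)
    # read-through over (s, e]: difference array then cumulative sum
    delta <- integer(L + 1L)
    from <- pmin(reads$start + 1L, L + 1L)
    d1 <- tabulate(from, nbins = L + 1L)
    d2 <- tabulate(pmin(reads$end + 1L, L + 1L), nbins = L + 1L)
    n_rt <- cumsum(d1 - d2)[seq_len(L)]
  }
  structure(
    data.frame(position = seq_len(L),
               base = reference_bases(reference),
               n_stop = as.integer(n_stop),
               n_readthrough = as.integer(n_rt),
               stringsAsFactors = FALSE),
    class = c("nt_coverage", "data.frame"),
    transcript = reference$name,
    n_rejected = n_rejected,
    n_reads_used = nrow(reads)
  )
}

#' Coverage mask for reliably estimable positions
#'
#' A position is usable only if enough independent reads traversed it:
#' the stop-probability estimator at a position is conditioned on reads
#' reaching it, so sparse 5'-distal coverage would otherwise yield
#' noise-dominated reactivities. The filter is strict: exactly
#' `min_readthrough` read-throughs is still masked.
#'
#' @param coverage an `nt_coverage` from [count_rt_events()].
#' @param min_readthrough usable positions must have
#'   `n_readthrough > min_readthrough`. Default 10000.
#' @return Logical vector, `TRUE` where the position is usable.
#' @export
mask_low_coverage <- function(coverage, min_readthrough = 10000L) {
  stopifnot(inherits(coverage, "nt_coverage"))
  min_readthrough <- as.numeric(min_readthrough)
  if (is.na(min_readthrough) || min_readthrough < 0) {
    stop("min_readthrough must be >= 0")
  }
  coverage$n_readthrough > min_readthrough
}

#' @export
print.nt_coverage <- function(x, ...) {
  cat(sprintf(
    "<nt_coverage> %s: %d positions, %d reads used (%d rejected), %d stops\n",
    attr(x, "transcript"), nrow(x), attr(x, "n_reads_used"),
    attr(x, "n_rejected"), sum(x$n_stop)))
  invisible(x)
}

#' Write per-nucleotide counts as TSV
#'
#' Columns: transcript, position (1-based), base, n_stop,
#' n_readthrough. Lines starting `#` are provenance comments.
#'
#' @param coverage an `nt_coverage`.
#' @param path output file.
#' @param comments optional character vector of extra header comments.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(coverage, path, comments = character()) {
  stopifnot(inherits(coverage, "nt_coverage"))
  out <- data.frame(transcript = attr(coverage, "transcript"),
                    coverage, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tbseq %s coverage",
                       as.character(packageVersion("tbseq"))),
               paste0("# ", comments)), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-nucleotide counts from TSV
#'
#' Inverse of [write_coverage_tsv()].
#'
#' @param path TSV written by [write_coverage_tsv()].
#' @return An `nt_coverage` data frame.
#' @export
read_coverage_tsv <- function(path) {
  x <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("transcript", "position", "base", "n_stop", "n_readthrough")
  if (!all(need %in% names(x))) {
    stop("coverage TSV must have columns: ", paste(need, collapse = ", "))
  }
  x <- x[order(x$position), , drop = FALSE]
  structure(
    data.frame(position = as.integer(x$position), base = x$base,
               n_stop = as.integer(x$n_stop),
               n_readthrough = as.integer(x$n_readthrough),
               stringsAsFactors = FALSE),
    class = c("nt_coverage", "data.frame"),
    transcript = x$transcript[1],
    n_rejected = NA_integer_,
    n_reads_used = NA_integer_
  )
}
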