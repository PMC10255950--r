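#' Single-transcript reference
#'
#' A minimal container for the one transcript that gene-specific-primed
#' probing libraries are aligned against. Coordinates throughout the
#' package are 1-based inclusive transcript positions, matching
#' nucleotide numbering in structure diagrams; 0-based half-open
#' coordinates appear only in exported BED/bedGraph tracks.
#'
#' @param name transcript identifier (non-empty string).
#' @param sequence nucleotide string over A, C, G, T, U, N
#'   (case-insensitive; RNA and DNA alphabets both accepted).
#'
#' @return An object of class `transcript_reference` with fields
#'   `name`, `sequence` (uppercased) and `length`.
#' @examples
#' ref <- transcript_reference("toy", "ACGUACGUACGU")
#' ref$length
#' @export
transcript_reference <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTUN]", "", sequence)
  if (nzchar(bad)) {
    stop("reference sequence contains non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "transcript_reference"
  )
}

#' @export
print.transcript_reference <- function(x, ...) {
  cat(sprintf("<transcript_reference> %s (%d nt)\n", x$name, x$length))
  invisible(x)
}

#' Read a transcript reference from FASTA
#'
#' @param path FASTA file with one or more records.
#' @param name optional record name to select; defaults to the first
#'   record.
#' @return A [transcript_reference()].
#' @export
read_transcript_fasta <- function(path, name = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  i <- if (is.null(name)) 1L else match(name, ids)
  if (is.na(i)) stop("transcript '", name, "' not found in ", path)
  transcript_reference(ids[i], as.character(seqs[[i]]))
}

#' Write a transcript reference to FASTA
#'
#' @param reference a [transcript_reference()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript_fasta <- function(reference, path) {
  stopifnot(inherits(reference, "transcript_reference"))
  x <- Biostrings::BStringSet(setNames(reference$sequence, reference$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

reference_bases <- function(reference) {
  strsplit(reference$sequence, "")[[1]]
}
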