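#' Protein-dependence (delta Tb) profile
#'
#' Differential reactivity between deproteinized and native lysate
#' probing of the same RNA: the normalized reactivity of the
#' Proteinase-K-treated arm minus that of the intact-lysate arm.
#' Positions losing reactivity on deproteinization (delta at or below
#' `-cutoff`) mark structure that depends on bound protein; gains (at
#' or above `+cutoff`) may reflect conformational rearrangement once
#' proteins are stripped. The class names are deliberately operational,
#' not mechanistic.
#'
#' @param protK `reactivity_profile` from lysate + Proteinase-K probing
#'   (context `cell_lysate_protK`).
#' @param lysate `reactivity_profile` from intact lysate probing
#'   (context `cell_lysate`).
#' @param cutoff symmetric classification cutoff on the normalized
#'   scale; the default 0.5 is deliberately stringent.
#' @param check_context verify the two contexts (default `TRUE`); the
#'   check exists to prevent silent sign errors in Eq.-style
#'   subtraction order.
#' @return A data frame of class `delta_tb_profile` with columns
#'   `position`, `base`, `delta`, `klass` (one of
#'   `loss_on_deproteinization`, `gain_on_deproteinization`,
#'   `unchanged`, `masked`); attributes `transcript`, `cutoff`.
#' @examples
#' # see vignette("tbseq-methods") for an end-to-end simulated example
#' @export
compute_delta <- function(protK, lysate, cutoff = 0.5,
                          check_context = TRUE) {
  stopifnot(inherits(protK, "reactivity_profile"),
            inherits(lysate, "reactivity_profile"))
  if (attr(protK, "transcript") != attr(lysate, "transcript")) {
    stop("profiles are on different transcripts")
  }
  if (nrow(protK) != nrow(lysate)) stop("profiles differ in length")
  if (!is.numeric(cutoff) || cutoff < 0) stop("cutoff must be >= 0")
  if (check_context) {
    cp <- attr(protK, "condition")$context
    cl <- attr(lysate, "condition")$context
    if (cp != "cell_lysate_protK" || cl != "cell_lysate") {
      stop(sprintf(
        "context mismatch: expected cell_lysate_protK vs cell_lysate, got %s vs %s",
        cp, cl))
    }
  }
  delta <- protK$norm - lysate$norm
  masked <- !(protK$mask & lysate$mask)
  delta[masked] <- masked_sentinel
  klass <- rep("unchanged", length(delta))
  klass[!is.na(delta) & delta <= -cutoff] <- "loss_on_deproteinization"
  klass[!is.na(delta) & delta >= cutoff] <- "gain_on_deproteinization"
  klass[masked] <- "masked"
  structure(
    data.frame(position = protK$position, base = protK$base,
               delta = delta, klass = klass, stringsAsFactors = FALSE),
    class = c("delta_tb_profile", "data.frame"),
    transcript = attr(protK, "transcript"),
    cutoff = cutoff
  )
}

#' @export
print.delta_tb_profile <- function(x, ...) {
  tab <- table(factor(x$klass, levels = c("loss_on_deproteinization",
                                          "gain_on_deproteinization",
                                          "unchanged", "masked")))
  cat(sprintf(
    "<delta_tb_profile> %s | cutoff %.2g | loss %d, gain %d, unchanged %d, masked %d\n",
    attr(x, "transcript"), attr(x, "cutoff"),
    tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Export a delta-Tb profile as bedGraph and class intervals as BED
#'
#' The bedGraph carries per-nucleotide delta values (masked positions
#' omitted); the BED merges runs of adjacent same-class positions into
#' intervals named by class.
#'
#' @param delta a `delta_tb_profile`.
#' @param bedgraph_path,bed_path output paths (`NULL` skips either).
#' @return Invisibly, the paths written.
#' @export
write_delta_tracks <- function(delta, bedgraph_path = NULL,
                               bed_path = NULL) {
  stopifnot(inherits(delta, "delta_tb_profile"))
  tx <- attr(delta, "transcript")
  written <- character()
  if (!is.null(bedgraph_path)) {
    keep <- !is.na(delta$delta)
    gr <- GenomicRanges::GRanges(
      seqnames = tx,
      ranges = IRanges::IRanges(start = delta$position[keep], width = 1L),
      score = round(delta$delta[keep], 4)
    )
    rtracklayer::export.bedGraph(gr, bedgraph_path)
    written <- c(written, bedgraph_path)
  }
  if (!is.null(bed_path)) {
    sel <- delta$klass %in% c("loss_on_deproteinization",
                              "gain_on_deproteinization")
    d <- delta[sel, , drop = FALSE]
    if (nrow(d)) {
      run <- cumsum(c(TRUE, diff(d$position) != 1L |
                        d$klass[-1] != d$klass[-nrow(d)]))
      starts <- tapply(d$position, run, min)
      ends <- tapply(d$position, run, max)
      klass <- tapply(d$klass, run, `[`, 1L)
      gr <- GenomicRanges::GRanges(
        seqnames = tx,
        ranges = IRanges::IRanges(start = as.integer(starts),
                                  end = as.integer(ends))
      )
      names(gr) <- as.character(klass)
    } else {
      gr <- GenomicRanges::GRanges()
    }
    rtracklayer::export.bed(gr, bed_path)
    written <- c(written, bed_path)
  }
  invisible(written)
}
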