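#' Call strong terbium cleavage sites
#'
#' Applies the three-point criteria set that separates specific,
#' site-bound Tb3+ cleavage from spontaneous RT termination:
#' \enumerate{
#'   \item normalized reactivity above `threshold` at the reference
#'     concentration, in every replicate individually (not the mean);
#'   \item reproducibility in at least `min_replicates` independent
#'     replicates;
#'   \item dependence of the signal on Tb3+ concentration: Spearman
#'     rank correlation of the replicate-averaged signal with
#'     concentration `>= min_spearman` when three or more distinct
#'     probe concentrations are available, or a strict increase when
#'     exactly two are.
#' }
#' The concentration statistic is computed on raw (background-
#' subtracted) reactivity by default: per-profile normalization clamps
#' genuine sites to the scale ceiling at every concentration at which
#' they are detectable, which erases the dose response that criterion
#' three exists to test (see the methods vignette). Set
#' `conc_signal = "norm"` to use normalized values instead.
#'
#' @param profiles list of `reactivity_profile` objects covering
#'   replicates and a Tb3+ concentration series on one transcript.
#' @param threshold normalized-reactivity cutoff, exceeded strictly.
#'   Default 0.5.
#' @param min_replicates replicates required to agree. Default 2.
#' @param reference_concentration concentration (mM) at which criteria
#'   1-2 are evaluated. Default: 0.5 for in vitro probing, 1 for
#'   lysate contexts.
#' @param min_spearman Spearman rho cutoff for criterion 3. Default 0.5.
#' @param conc_signal `"raw"` (default) or `"norm"`: which reactivity
#'   feeds the concentration statistic.
#' @param drop_positions positions never evaluated; defaults to
#'   position 1, where full-length cDNAs pile up.
#'
#' @return A data frame of class `strong_site_set` with one row per
#'   evaluated (everywhere-unmasked) position: `position`,
#'   `mean_norm_reactivity` (mean over reference-concentration
#'   replicates), `pass_threshold`, `pass_replicates`,
#'   `pass_concentration`, `called`. Attributes record the transcript
#'   and all parameters.
#' @export
call_strong_sites <- function(profiles, threshold = 0.5,
                              min_replicates = 2L,
                              reference_concentration = NULL,
                              min_spearman = 0.5,
                              conc_signal = c("raw", "norm"),
                              drop_positions = 1L) {
  conc_signal <- match.arg(conc_signal)
  if (!length(profiles)) stop("empty profile set")
  stopifnot(all(vapply(profiles, inherits, TRUE, "reactivity_profile")))
  tx <- vapply(profiles, attr, "", "transcript")
  if (length(unique(tx)) != 1L) {
    stop("profiles span multiple transcripts: ",
         paste(unique(tx), collapse = ", "))
  }
  conds <- lapply(profiles, attr, "condition")
  concs <- vapply(conds, `[[`, 0, "tb_concentration")
  reps <- vapply(conds, `[[`, "", "replicate_id")
  contexts <- unique(vapply(conds, `[[`, "", "context"))
  if (length(contexts) != 1L) {
    stop("profiles mix probing contexts: ",
         paste(contexts, collapse = ", "))
  }
  if (is.null(reference_concentration)) {
    reference_concentration <- if (contexts == "in_vitro") 0.5 else 1
  }
  at_ref <- which(concs == reference_concentration)
  if (length(unique(reps[at_ref])) < min_replicates) {
    stop(sprintf(
      "need >= %d replicates at the reference concentration (%g mM); have %d",
      min_replicates, reference_concentration,
      length(unique(reps[at_ref]))))
  }
  L <- nrow(profiles[[1]])
  if (any(vapply(profiles, nrow, 0L) != L)) {
    stop("profiles have different lengths")
  }

  usable <- Reduce(`&`, lapply(profiles, `[[`, "mask"))
  usable[intersect(drop_positions, seq_len(L))] <- FALSE
  pos <- which(usable)

  # criteria 1-2: per-replicate normalized reactivity at the reference
  # concentration (one profile per replicate expected there)
  norm_ref <- vapply(profiles[at_ref], function(p) p$norm[pos],
                     numeric(length(pos)))
  norm_ref <- matrix(norm_ref, nrow = length(pos))
  n_pass <- rowSums(norm_ref > threshold)
  pass_threshold <- n_pass == ncol(norm_ref)
  pass_replicates <- n_pass >= min_replicates
  mean_norm <- rowMeans(norm_ref)

  # criterion 3: replicate-averaged signal across the ordered series
  nonzero <- sort(unique(concs[concs > 0]))
  if (length(nonzero) < 2L) {
    warning("fewer than 2 distinct probe concentrations: concentration ",
            "dependence is not evaluable and no site can be called")
    pass_conc <- rep(FALSE, length(pos))
  } else {
    series <- vapply(nonzero, function(cc) {
      m <- vapply(profiles[concs == cc],
                  function(p) p[[conc_signal]][pos],
                  numeric(length(pos)))
      rowMeans(matrix(m, nrow = length(pos)))
    }, numeric(length(pos)))
    series <- matrix(series, nrow = length(pos))
    if (length(nonzero) == 2L) {
      pass_conc <- series[, 2] > series[, 1]
    } else {
      rho <- apply(series, 1L, function(v) {
        if (anyNA(v) || stats::sd(v) == 0) return(NA_real_)
        suppressWarnings(cor(v, nonzero, method = "spearman"))
      })
      pass_conc <- !is.na(rho) & rho >= min_spearman
    }
  }

  out <- data.frame(position = pos,
                    mean_norm_reactivity = mean_norm,
                    pass_threshold = pass_threshold,
                    pass_replicates = pass_replicates,
                    pass_concentration = pass_conc)
  out$called <- out$pass_threshold & out$pass_replicates &
    out$pass_concentration
  structure(out,
            class = c("strong_site_set", "data.frame"),
            transcript = tx[1],
            context = contexts,
            threshold = threshold,
            min_replicates = min_replicates,
            reference_concentration = reference_concentration,
            min_spearman = min_spearman,
            conc_signal = conc_signal,
            concentrations = sort(unique(concs)))
}

#' Called positions of a strong-site set
#'
#' @param sites a `strong_site_set`.
#' @return Integer vector of positions passing all three criteria.
#' @export
called_positions <- function(sites) {
  stopifnot(inherits(sites, "strong_site_set"))
  sites$position[sites$called]
}

#' @export
print.strong_site_set <- function(x, ...) {
  cat(sprintf(
    "<strong_site_set> %s (%s): %d/%d evaluated positions called at %g mM\n",
    attr(x, "transcript"), attr(x, "context"), sum(x$called), nrow(x),
    attr(x, "reference_concentration")))
  invisible(x)
}

#' Write called sites as BED and the full criteria table as TSV
#'
#' BED intervals are 0-based half-open, one per called nucleotide, with
#' the mean normalized reactivity as score.
#'
#' @param sites a `strong_site_set`.
#' @param bed_path,tsv_path output paths (`NULL` skips either).
#' @return Invisibly, the paths written.
#' @export
write_strong_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(sites, "strong_site_set"))
  written <- character()
  if (!is.null(bed_path)) {
    called <- sites[sites$called, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = attr(sites, "transcript"),
      ranges = IRanges::IRanges(start = called$position, width = 1L),
      score = round(called$mean_norm_reactivity, 4)
    )
    names(gr) <- sprintf("site_%d", called$position)
    rtracklayer::export.bed(gr, bed_path)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(sites), tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
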