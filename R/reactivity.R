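#' Probing condition metadata
#'
#' @param tb_concentration TbCl3 concentration in mM; 0 means the
#'   untreated (no-probe) control.
#' @param replicate_id identifier of the biological replicate.
#' @param context one of `"in_vitro"`, `"cell_lysate"`,
#'   `"cell_lysate_protK"`.
#' @return A list of class `probing_condition` with a derived `treated`
#'   flag (`tb_concentration > 0`).
#' @export
probing_condition <- function(tb_concentration, replicate_id,
                              context = c("in_vitro", "cell_lysate",
                                          "cell_lysate_protK")) {
  context <- match.arg(context)
  tb_concentration <- as.numeric(tb_concentration)
  if (is.na(tb_concentration) || tb_concentration < 0) {
    stop("tb_concentration must be a non-negative number (mM)")
  }
  structure(
    list(tb_concentration = tb_concentration,
         replicate_id = as.character(replicate_id),
         context = context,
         treated = tb_concentration > 0),
    class = "probing_condition"
  )
}

#' Per-nucleotide stop probability
#'
#' The probability that reverse transcription terminates at a position,
#' conditioned on a read having reached it: stops divided by stops plus
#' read-throughs.
#'
#' @param coverage an `nt_coverage` from [count_rt_events()].
#' @param mask logical usable-position mask, typically from
#'   [mask_low_coverage()]. Masked positions yield `NA`.
#' @return Numeric vector of stop probabilities in `[0, 1]`, `NA` where
#'   masked or where no events were observed.
#' @examples
#' ref <- transcript_reference("t", "AAAA")
#' cov <- count_rt_events(aligned_reads("t", c(2, 2, 3), 4), ref)
#' stop_probability(cov, mask = rep(TRUE, 4))
#' @export
stop_probability <- function(coverage, mask = NULL) {
  stopifnot(inherits(coverage, "nt_coverage"))
  if (is.null(mask)) mask <- rep(TRUE, nrow(coverage))
  stopifnot(is.logical(mask), length(mask) == nrow(coverage))
  denom <- coverage$n_stop + coverage$n_readthrough
  p <- ifelse(denom > 0, coverage$n_stop / denom, masked_sentinel)
  p[!mask] <- masked_sentinel
  p
}

#' Background-subtracted reactivity
#'
#' Subtracts the untreated (no-probe) stop probability from the treated
#' one, removing intrinsic RT drop-off and spontaneous degradation.
#' Negative values are kept (clamping happens only at normalization);
#' a position is defined only where both inputs are.
#'
#' @param treated,untreated numeric stop-probability vectors of equal
#'   length (from [stop_probability()]).
#' @return Numeric raw reactivity vector; `NA` where either input is
#'   masked.
#' @export
background_subtract <- function(treated, untreated) {
  if (length(treated) != length(untreated)) {
    stop("treated and untreated profiles have different lengths (",
         length(treated), " vs ", length(untreated), ")")
  }
  treated - untreated
}

#' Normalize raw reactivities to the 0-8 scale
#'
#' Probing efficiency differs between contexts (in vitro, lysate), so
#' raw reactivities are placed on a common scale: each profile is
#' divided by its own top-decile statistic and scaled so the ceiling is
#' 8. With `norm_stat = "mean"` (default) the normalization factor F is
#' the mean of defined raw values at or above their 90th percentile;
#' `"p90"` uses the 90th percentile itself. Values are clamped into
#' `[0, 1]` before scaling, so negatives map to 0 and values above F to
#' 8.
#'
#' @param raw numeric raw reactivity vector (`NA` = masked).
#' @param norm_stat `"mean"` or `"p90"`.
#' @return Numeric vector in `[0, 8]` (`NA` preserved), with the factor
#'   F in attribute `norm_factor`.
#' @examples
#' raw <- c(runif(17, 0, 0.5), 0.8, 0.9, 1.1)
#' norm <- normalize_reactivity(raw)
#' range(norm)
#' @export
normalize_reactivity <- function(raw, norm_stat = c("mean", "p90")) {
  norm_stat <- match.arg(norm_stat)
  defined <- !is.na(raw)
  if (sum(defined) < 10L) {
    stop("need at least 10 defined positions to normalize (have ",
         sum(defined), ")")
  }
  v <- raw[defined]
  q90 <- quantile(v, 0.9, names = FALSE)
  f <- switch(norm_stat,
              mean = mean(v[v >= q90]),
              p90 = q90)
  if (!is.finite(f) || f <= 0) {
    stop("non-positive normalization factor (degenerate profile): F = ", f)
  }
  out <- 8 * pmin(pmax(raw / f, 0), 1)
  attr(out, "norm_factor") <- f
  out
}

#' Build a reactivity profile from treated and untreated coverage
#'
#' Runs the core chain -- coverage mask (intersection of both arms),
#' stop probabilities, background subtraction, normalization -- and
#' packages the result with its probing condition.
#'
#' @param treated,untreated `nt_coverage` objects for the probed and
#'   no-probe libraries of one sample.
#' @param condition the [probing_condition()] of the treated library.
#' @param min_readthrough coverage filter passed to
#'   [mask_low_coverage()] for both arms.
#' @param norm_stat passed to [normalize_reactivity()].
#' @return A data frame of class `reactivity_profile` with columns
#'   `position`, `base`, `n_stop_treated`, `n_readthrough_treated`,
#'   `n_stop_untreated`, `n_readthrough_untreated`, `p_stop_treated`,
#'   `p_stop_untreated`, `raw`, `norm`, `mask`; attributes
#'   `transcript`, `condition`, `norm_factor`.
#' @export
reactivity_profile <- function(treated, untreated, condition,
                               min_readthrough = 10000L,
                               norm_stat = "mean") {
  stopifnot(inherits(treated, "nt_coverage"),
            inherits(untreated, "nt_coverage"),
            inherits(condition, "probing_condition"))
  if (attr(treated, "transcript") != attr(untreated, "transcript")) {
    stop("treated and untreated coverage are on different transcripts")
  }
  if (nrow(treated) != nrow(untreated)) {
    stop("treated and untreated coverage have different lengths")
  }
  if (!condition$treated) {
    stop("condition has tb_concentration = 0; ",
         "the treated arm must be a probed library")
  }
  mask <- mask_low_coverage(treated, min_readthrough) &
    mask_low_coverage(untreated, min_readthrough)
  p_t <- stop_probability(treated, mask)
  p_u <- stop_probability(untreated, mask)
  raw <- background_subtract(p_t, p_u)
  mean_bg <- mean(p_u, na.rm = TRUE)
  if (is.finite(mean_bg) && mean_bg > 0.05) {
    warning(sprintf(
      "mean untreated stop probability %.3f > 0.05: heavy intrinsic RT %s",
      mean_bg, "drop-off; no drop-off correction is applied"))
  }
  norm <- normalize_reactivity(raw, norm_stat = norm_stat)
  structure(
    data.frame(position = treated$position, base = treated$base,
               n_stop_treated = treated$n_stop,
               n_readthrough_treated = treated$n_readthrough,
               n_stop_untreated = untreated$n_stop,
               n_readthrough_untreated = untreated$n_readthrough,
               p_stop_treated = p_t, p_stop_untreated = p_u,
               raw = raw, norm = as.numeric(norm),
               mask = mask, stringsAsFactors = FALSE),
    class = c("reactivity_profile", "data.frame"),
    transcript = attr(treated, "transcript"),
    condition = condition,
    norm_factor = attr(norm, "norm_factor")
  )
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf(
    "<reactivity_profile> %s | %s rep %s, %.3g mM Tb | %d/%d usable, F = %.4g\n",
    attr(x, "transcript"), cond$context, cond$replicate_id,
    cond$tb_concentration, sum(x$mask), nrow(x), attr(x, "norm_factor")))
  invisible(x)
}

#' Write a reactivity profile as TSV
#'
#' Header comments carry the probing condition so the profile can be
#' round-tripped through [read_reactivity_tsv()].
#'
#' @param profile a `reactivity_profile`.
#' @param path output file.
#' @param comments extra provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_reactivity_tsv <- function(profile, path, comments = character()) {
  stopifnot(inherits(profile, "reactivity_profile"))
  cond <- attr(profile, "condition")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tbseq %s reactivity", as.character(packageVersion("tbseq"))),
    sprintf("# transcript=%s", attr(profile, "transcript")),
    sprintf("# tb_concentration=%g", cond$tb_concentration),
    sprintf("# replicate_id=%s", cond$replicate_id),
    sprintf("# context=%s", cond$context),
    sprintf("# norm_factor=%.10g", attr(profile, "norm_factor")),
    paste0("# ", comments)
  ), con)
  write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a reactivity profile from TSV
#'
#' @param path file written by [write_reactivity_tsv()].
#' @return A `reactivity_profile`.
#' @export
read_reactivity_tsv <- function(path) {
  hdr <- readLines(path, n = 50L)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- function(key, default = NA_character_) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^# ", key, "="), "", m[1]) else default
  }
  x <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  x$mask <- as.logical(x$mask)
  cond <- probing_condition(as.numeric(meta("tb_concentration", "1")),
                            meta("replicate_id", "r1"),
                            meta("context", "in_vitro"))
  structure(
    x,
    class = c("reactivity_profile", "data.frame"),
    transcript = meta("transcript", "transcript"),
    condition = cond,
    norm_factor = as.numeric(meta("norm_factor", "NA"))
  )
}

#' Write a SHAPE-style .map reactivity file
#'
#' Four whitespace-separated columns: position, reactivity, standard
#' error placeholder, base. Masked positions carry -999, the
#' conventional no-data sentinel of structure-prediction tools.
#'
#' @param profile a `reactivity_profile`.
#' @param path output file.
#' @param which `"norm"` (default) or `"raw"` column to emit.
#' @return `path`, invisibly.
#' @export
write_shape_map <- function(profile, path, which = c("norm", "raw")) {
  which <- match.arg(which)
  v <- profile[[which]]
  v[is.na(v)] <- -999
  err <- ifelse(is.na(profile[[which]]), -999, 0)
  out <- data.frame(profile$position, v, err,
                    chartr("T", "U", profile$base))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
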