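#' Configuration for the RT-truncation read simulator
#'
#' Describes one gene-specific-primed probing library generatively:
#' reverse transcription starts at the primer's first templated base
#' (`primer_start`) and walks toward position 1; at each position it
#' terminates with the true stop propensity
#' `s[p] = b + (1 - b) * kappa_eff[p]`, where `b` is the
#' concentration-independent background drop-off and
#' `kappa_eff[p] = kappa[p] * multiplier(concentration)` is the
#' cleavage propensity of a seeded site at the probed Tb3+
#' concentration. cDNAs that run off the 5' end are the full-length
#' class, represented as stops at position 1.
#'
#' @param sequence transcript sequence string or a
#'   [transcript_reference()].
#' @param cleavage_sites named numeric vector: names are 1-based
#'   positions, values the cleavage propensity kappa in `[0, 1)` at
#'   full saturation. All positions must be `< primer_start`.
#' @param background_stop per-nucleotide background termination
#'   probability `b` in `[0, 1)`.
#' @param n_reads RT attempts per library.
#' @param primer_start 1-based position of the primer's 5'-most
#'   templated base; defaults to the transcript 3' end.
#' @param min_read_length reads shorter than this are discarded (and
#'   counted), mimicking size selection during library preparation.
#' @param k_half concentration (mM) of half-maximal cleavage for the
#'   Hill-type response; the default 0.5 puts the in vitro reference
#'   concentration at half saturation.
#' @param concentration_response `"hill"` (multiplier
#'   `c / (c + k_half)`, saturating) or `"linear"` (multiplier
#'   `min(c / (2 k_half), 1)`; equals the Hill response at 0 and at
#'   `k_half`).
#' @param name transcript name used when `sequence` is a bare string.
#' @param seed default RNG seed for [simulate_reads()].
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(sequence, cleavage_sites = numeric(),
                              background_stop = 0.01, n_reads = 100000L,
                              primer_start = NULL, min_read_length = 20L,
                              k_half = 0.5,
                              concentration_response = c("hill", "linear"),
                              name = "sim_transcript", seed = 1L) {
  concentration_response <- match.arg(concentration_response)
  ref <- if (inherits(sequence, "transcript_reference")) sequence
         else transcript_reference(name, sequence)
  primer_start <- as.integer(primer_start %||% ref$length)
  if (primer_start < 2L || primer_start > ref$length) {
    stop("primer_start must lie in [2, transcript length]")
  }
  kappa <- as.numeric(cleavage_sites)
  kpos <- as.integer(names(cleavage_sites) %||% integer())
  if (length(kappa) && (is.null(names(cleavage_sites)) || anyNA(kpos))) {
    stop("cleavage_sites must be a named vector (names = positions)")
  }
  if (any(kappa < 0 | kappa >= 1)) stop("kappa values must lie in [0, 1)")
  if (any(kpos < 1L | kpos >= primer_start)) {
    stop("cleavage positions must satisfy 1 <= position < primer_start")
  }
  if (anyDuplicated(kpos)) stop("duplicated cleavage positions")
  if (background_stop < 0 || background_stop >= 1) {
    stop("background_stop must lie in [0, 1)")
  }
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be positive")
  min_read_length <- as.integer(min_read_length)
  if (min_read_length < 1L) stop("min_read_length must be positive")
  if (min_read_length > primer_start) {
    stop("min_read_length exceeds the longest possible read")
  }
  structure(
    list(reference = ref, cleavage_positions = kpos, kappa = kappa,
         background_stop = background_stop, n_reads = n_reads,
         primer_start = primer_start, min_read_length = min_read_length,
         k_half = k_half, concentration_response = concentration_response,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Hill-type concentration response
#'
#' Saturating multiplier `c / (c + k_half)` applied to site cleavage
#' propensities: 0 when untreated, 1/2 at `c = k_half`, approaching 1
#' at saturating Tb3+.
#'
#' @param tb_concentration concentration in mM (vectorized).
#' @param k_half half-saturation concentration in mM.
#' @return Multiplier in `[0, 1)`.
#' @export
hill_multiplier <- function(tb_concentration, k_half = 0.5) {
  stopifnot(all(tb_concentration >= 0), k_half > 0)
  tb_concentration / (tb_concentration + k_half)
}

concentration_multiplier <- function(config, tb_concentration) {
  switch(config$concentration_response,
         hill = hill_multiplier(tb_concentration, config$k_half),
         linear = pmin(tb_concentration / (2 * config$k_half), 1))
}

#' True per-position stop propensity at a given concentration
#'
#' Closed-form companion of the simulator:
#' `s[p] = b + (1 - b) * kappa[p] * multiplier(c)`, the probability
#' that an RT attempt reaching position p terminates there. This is
#' exactly the quantity the stop-probability estimator targets.
#'
#' @param config a [simulation_config()].
#' @param tb_concentration probed concentration in mM (0 = untreated).
#' @return A list of class `sim_truth`: per-position `s` and
#'   `kappa_eff`, plus the multiplier and condition metadata.
#' @export
true_stop_propensity <- function(config, tb_concentration) {
  stopifnot(inherits(config, "simulation_config"))
  m <- concentration_multiplier(config, tb_concentration)
  L <- config$reference$length
  kap <- numeric(L)
  kap[config$cleavage_positions] <- config$kappa * m
  b <- config$background_stop
  structure(
    list(transcript = config$reference$name,
         tb_concentration = tb_concentration,
         multiplier = m,
         background = b,
         primer_start = config$primer_start,
         kappa_eff = kap,
         s = b + (1 - b) * kap,
         stop_counts = NULL,
         n_discarded = NA_integer_),
    class = "sim_truth"
  )
}

#' Simulate one RT-truncation probing library
#'
#' Draws each read's stop position from the exact distribution of the
#' positionwise termination walk: an attempt starting at
#' `primer_start` stops at position p (for `primer_start >= p >= 2`)
#' with probability `s[p] * prod(1 - s[q], q = p+1 .. primer_start)`,
#' and runs off the 5' end (stop recorded at position 1) with the
#' remaining survival mass. Reads shorter than `min_read_length` are
#' discarded and counted. Deterministic for a given `seed`.
#'
#' @param config a [simulation_config()].
#' @param tb_concentration probed Tb3+ concentration (mM); 0 simulates
#'   the untreated control (sites switched off, background only).
#' @param seed RNG seed; defaults to `config$seed`. The seed is
#'   consumed via `set.seed()` at entry.
#' @return A list with `reads` (an [aligned_reads()] data frame,
#'   spans `[stop, primer_start]`), `truth` (a `sim_truth` with
#'   realized `stop_counts` over kept reads) and `n_discarded`.
#' @examples
#' cfg <- simulation_config(strrep("ACGU", 25), c("50" = 0.5),
#'                          background_stop = 0, n_reads = 2000,
#'                          min_read_length = 10)
#' sim <- simulate_reads(cfg, tb_concentration = 1e9, seed = 7)
#' table(sim$reads$start)[c("1", "50")]
#' @export
simulate_reads <- function(config, tb_concentration, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  truth <- true_stop_propensity(config, tb_concentration)
  ps <- config$primer_start
  s <- truth$s
  # exact stop-position distribution of the 3'->5' termination walk
  v <- 1 - s[2:ps]                      # survival at positions 2..ps
  suffix_excl <- rev(cumprod(rev(c(v[-1], 1))))  # prod over q > p
  prob <- numeric(ps)
  prob[2:ps] <- s[2:ps] * suffix_excl
  prob[1] <- prod(v)
  set.seed(seed %||% config$seed)
  stops <- sample.int(ps, size = config$n_reads, replace = TRUE,
                      prob = prob)
  keep <- (ps - stops + 1L) >= config$min_read_length
  n_discarded <- sum(!keep)
  stops <- stops[keep]
  reads <- aligned_reads(config$reference$name, start = stops, end = ps)
  truth$stop_counts <- tabulate(stops, nbins = config$reference$length)
  truth$n_discarded <- n_discarded
  list(reads = reads, truth = truth, n_discarded = n_discarded)
}

#' Expected raw reactivity implied by two ground truths
#'
#' The background-subtracted stop-probability estimator converges to
#' the difference of conditional stop propensities; this returns that
#' limit, `s_treated - s_untreated`, per position.
#'
#' @param truth a `sim_truth` from the treated library.
#' @param untreated_truth a `sim_truth` from the untreated library of
#'   the same configuration.
#' @return Numeric vector of expected raw reactivities.
#' @export
truth_reactivity <- function(truth, untreated_truth) {
  stopifnot(inherits(truth, "sim_truth"),
            inherits(untreated_truth, "sim_truth"))
  if (truth$transcript != untreated_truth$transcript ||
      length(truth$s) != length(untreated_truth$s)) {
    stop("ground truths describe different transcripts")
  }
  truth$s - untreated_truth$s
}

#' Write simulator ground truth as TSV
#'
#' @param truth a `sim_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- data.frame(position = seq_along(truth$s),
                    kappa_eff = truth$kappa_eff, s = truth$s,
                    stop_count = truth$stop_counts %||%
                      rep(NA_integer_, length(truth$s)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# transcript=%s tb_concentration=%g multiplier=%g background=%g",
                     truth$transcript, truth$tb_concentration,
                     truth$multiplier, truth$background), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a full multi-replicate concentration-series experiment
#'
#' Runs the generator and the analysis front end together: for each
#' replicate it simulates one untreated control plus one library per
#' probe concentration (each with its own derived seed), counts RT
#' events, and builds background-subtracted normalized reactivity
#' profiles. This is the standard harness for validating the calling
#' criteria against known ground truth.
#'
#' @param config a [simulation_config()].
#' @param concentrations nonzero Tb3+ concentrations (mM) to probe.
#' @param replicates replicate identifiers.
#' @param context probing context stored in the conditions.
#' @param seed base seed; library k of the experiment uses
#'   `seed * 100 + k`, so experiments with different base seeds are
#'   independent.
#' @param min_readthrough coverage filter for the profiles.
#' @param norm_stat passed to [normalize_reactivity()].
#' @return A list with `profiles` (named `reactivity_profile` list,
#'   names like `"r1_0.5mM"`), `truths` (matching `sim_truth` list
#'   plus one `"<rep>_untreated"` entry per replicate) and
#'   `coverages` (matching `nt_coverage` list, untreated included).
#' @export
simulate_probing_experiment <- function(config, concentrations,
                                        replicates = c("r1", "r2"),
                                        context = "in_vitro", seed = 1L,
                                        min_readthrough = 10000L,
                                        norm_stat = "mean") {
  stopifnot(inherits(config, "simulation_config"),
            all(concentrations > 0))
  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    as.integer((as.numeric(seed) %% 2e7) * 100 + k)
  }
  profiles <- list()
  truths <- list()
  coverages <- list()
  for (r in replicates) {
    untr <- simulate_reads(config, 0, seed = next_seed())
    cov_u <- count_rt_events(untr$reads, config$reference)
    truths[[paste0(r, "_untreated")]] <- untr$truth
    coverages[[paste0(r, "_untreated")]] <- cov_u
    for (cc in concentrations) {
      tag <- sprintf("%s_%gmM", r, cc)
      trt <- simulate_reads(config, cc, seed = next_seed())
      cov_t <- count_rt_events(trt$reads, config$reference)
      profiles[[tag]] <- reactivity_profile(
        cov_t, cov_u, probing_condition(cc, r, context),
        min_readthrough = min_readthrough, norm_stat = norm_stat)
      truths[[tag]] <- trt$truth
      coverages[[tag]] <- cov_t
    }
  }
  list(profiles = profiles, truths = truths, coverages = coverages)
}
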