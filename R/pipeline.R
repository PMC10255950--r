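#' Read and validate an experiment manifest
#'
#' The manifest is a YAML file describing one probing experiment:
#'
#' ```yaml
#' transcript: my_rna
#' reference_fasta: ref.fa
#' settings:                 # all optional, defaults shown
#'   min_readthrough: 10000
#'   threshold: 0.5
#'   delta_cutoff: 0.5
#'   stop_offset: 0
#'   exclude_region: [291, 300]
#'   reference_concentration: 0.5
#' samples:
#'   - path: r1_0.5mM.sam
#'     context: in_vitro     # in_vitro | cell_lysate | cell_lysate_protK
#'     replicate: r1
#'     tb_concentration: 0.5
#'   - path: r1_untreated.sam
#'     context: in_vitro
#'     replicate: r1
#'     tb_concentration: 0
#' ```
#'
#' Thresholds live in the manifest, not in flags, so a manifest plus
#' alignments fully determines the run. Validation is strict: every
#' treated sample must have an untreated (0 mM) control in the same
#' context and replicate, and schema violations are reported with
#' their field path.
#'
#' @param path YAML manifest file.
#' @return A list of class `experiment_manifest` with resolved file
#'   paths and filled-in default settings.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  fail <- function(field, msg) stop("manifest ", field, ": ", msg)
  if (is.null(m$transcript) || !nzchar(m$transcript)) {
    fail("transcript", "missing or empty")
  }
  if (is.null(m$reference_fasta)) fail("reference_fasta", "missing")
  m$reference_fasta <- resolve(m$reference_fasta)
  if (!file.exists(m$reference_fasta)) {
    fail("reference_fasta", paste("file not found:", m$reference_fasta))
  }
  defaults <- list(min_readthrough = 10000L, threshold = 0.5,
                   delta_cutoff = 0.5, stop_offset = 0L,
                   exclude_region = NULL, reference_concentration = NULL,
                   min_replicates = 2L, norm_stat = "mean",
                   conc_signal = "raw")
  s <- m$settings %||% list()
  unknown <- setdiff(names(s), names(defaults))
  if (length(unknown)) {
    fail(paste0("settings.", unknown[1]), "unknown setting")
  }
  m$settings <- utils::modifyList(defaults, s)
  if (is.null(m$samples) || !length(m$samples)) fail("samples", "empty")
  for (i in seq_along(m$samples)) {
    smp <- m$samples[[i]]
    at <- function(f) paste0("samples[", i, "].", f)
    for (f in c("path", "context", "replicate", "tb_concentration")) {
      if (is.null(smp[[f]])) fail(at(f), "missing")
    }
    if (!smp$context %in% c("in_vitro", "cell_lysate",
                            "cell_lysate_protK")) {
      fail(at("context"), paste("invalid context:", smp$context))
    }
    if (!is.numeric(smp$tb_concentration) || smp$tb_concentration < 0) {
      fail(at("tb_concentration"), "must be a non-negative number (mM)")
    }
    if (!is.null(smp$transcript) && smp$transcript != m$transcript) {
      fail(at("transcript"), "differs from manifest transcript")
    }
    m$samples[[i]]$path <- resolve(smp$path)
    if (!file.exists(m$samples[[i]]$path)) {
      fail(at("path"), paste("file not found:", m$samples[[i]]$path))
    }
  }
  key <- vapply(m$samples, function(s)
    paste(s$context, s$replicate, sep = "/"), "")
  conc <- vapply(m$samples, `[[`, 0, "tb_concentration")
  for (i in which(conc > 0)) {
    if (!any(conc == 0 & key == key[i])) {
      stop("manifest samples[", i, "] (", basename(m$samples[[i]]$path),
           ", ", key[i], ", ", conc[i], " mM): no untreated (0 mM) ",
           "control in the same context and replicate")
    }
  }
  m$path <- normalizePath(path)
  class(m) <- "experiment_manifest"
  m
}

#' Run the full Tb-seq analysis pipeline
#'
#' Executes the stages in dependency order: per-sample stop counting,
#' per-treated-sample reactivity (paired with its matched untreated
#' control), strong-site calling per probing context with enough
#' replication, and -- when both intact-lysate and deproteinized arms
#' are present at the lysate reference concentration -- per-replicate
#' delta-Tb profiles. All outputs are written under `outdir` with a
#' structured run log and a provenance file (package version, input
#' checksums, settings).
#'
#' @param manifest an `experiment_manifest` from [read_manifest()], or
#'   a path to one.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list of class `tbseq_run` with elements
#'   `profiles` (named list of `reactivity_profile`), `sites` (named
#'   list of `strong_site_set` per context), `deltas` (named list of
#'   `delta_tb_profile`), `log` (character vector), `outdir`.
#' @export
run_pipeline <- function(manifest, outdir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "experiment_manifest"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logs <- character()
  say <- function(...) {
    line <- sprintf(...)
    logs <<- c(logs, line)
    message("[tbseq] ", line)
  }
  st <- manifest$settings
  ref <- read_transcript_fasta(manifest$reference_fasta,
                               name = manifest$transcript)
  say("reference %s: %d nt", ref$name, ref$length)

  samples <- manifest$samples
  key <- vapply(samples, function(s)
    paste(s$context, s$replicate, sep = "/"), "")
  conc <- vapply(samples, `[[`, 0, "tb_concentration")

  coverages <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    smp <- samples[[i]]
    reads <- read_alignments(smp$path, transcript = ref$name)
    cov <- count_rt_events(reads, ref, stop_offset = st$stop_offset,
                           exclude_region = st$exclude_region)
    coverages[[i]] <- cov
    tag <- sprintf("%s_%s_%gmM", smp$context, smp$replicate,
                   smp$tb_concentration)
    write_coverage_tsv(cov, file.path(outdir, paste0(tag, ".counts.tsv")),
                       comments = sprintf("source=%s", basename(smp$path)))
    say("counted %s: %d reads used, %d rejected, %d stops", tag,
        attr(cov, "n_reads_used"), attr(cov, "n_rejected"),
        sum(cov$n_stop))
  }

  profiles <- list()
  for (i in which(conc > 0)) {
    j <- which(conc == 0 & key == key[i])[1]
    smp <- samples[[i]]
    condition <- probing_condition(smp$tb_concentration, smp$replicate,
                                   smp$context)
    prof <- reactivity_profile(coverages[[i]], coverages[[j]], condition,
                               min_readthrough = st$min_readthrough,
                               norm_stat = st$norm_stat)
    tag <- sprintf("%s_%s_%gmM", smp$context, smp$replicate,
                   smp$tb_concentration)
    profiles[[tag]] <- prof
    write_reactivity_tsv(prof,
                         file.path(outdir, paste0(tag, ".reactivity.tsv")))
    say("reactivity %s: %d/%d usable positions, F = %.4g", tag,
        sum(prof$mask), nrow(prof), attr(prof, "norm_factor"))
  }

  contexts <- unique(vapply(samples, `[[`, "", "context"))
  sites <- list()
  for (ctx in contexts) {
    ctx_prof <- Filter(function(p)
      attr(p, "condition")$context == ctx, profiles)
    if (!length(ctx_prof)) next
    res <- tryCatch(
      call_strong_sites(ctx_prof, threshold = st$threshold,
                        min_replicates = st$min_replicates,
                        reference_concentration = st$reference_concentration,
                        conc_signal = st$conc_signal),
      error = function(e) e, warning = function(w) w)
    if (inherits(res, "condition")) {
      say("site calling skipped for %s: %s", ctx, conditionMessage(res))
      next
    }
    sites[[ctx]] <- res
    write_strong_sites(res,
                       bed_path = file.path(outdir,
                                            paste0("sites_", ctx, ".bed")),
                       tsv_path = file.path(outdir,
                                            paste0("sites_", ctx, ".tsv")))
    say("sites %s: %d called of %d evaluated", ctx, sum(res$called),
        nrow(res))
  }

  deltas <- list()
  lys <- Filter(function(p) {
    cd <- attr(p, "condition")
    cd$context == "cell_lysate"
  }, profiles)
  prk <- Filter(function(p) {
    cd <- attr(p, "condition")
    cd$context == "cell_lysate_protK"
  }, profiles)
  if (length(lys) && length(prk)) {
    ref_conc <- st$reference_concentration %||% 1
    pick <- function(set, rep_id) {
      hits <- Filter(function(p) {
        cd <- attr(p, "condition")
        cd$replicate_id == rep_id && cd$tb_concentration == ref_conc
      }, set)
      if (length(hits)) hits[[1]] else NULL
    }
    reps <- intersect(
      vapply(lys, function(p) attr(p, "condition")$replicate_id, ""),
      vapply(prk, function(p) attr(p, "condition")$replicate_id, ""))
    for (r in reps) {
      pl <- pick(lys, r); pp <- pick(prk, r)
      if (is.null(pl) || is.null(pp)) next
      d <- compute_delta(pp, pl, cutoff = st$delta_cutoff)
      deltas[[r]] <- d
      write_delta_tracks(
        d,
        bedgraph_path = file.path(outdir,
                                  sprintf("delta_tb_%s.bedGraph", r)),
        bed_path = file.path(outdir, sprintf("delta_tb_%s.bed", r)))
      tab <- table(d$klass)
      say("delta-Tb %s: %d loss, %d gain", r,
          sum(d$klass == "loss_on_deproteinization"),
          sum(d$klass == "gain_on_deproteinization"))
    }
  } else {
    say("delta-Tb skipped: need both cell_lysate and cell_lysate_protK arms")
  }

  prov <- c(
    sprintf("tbseq_version\t%s", as.character(packageVersion("tbseq"))),
    sprintf("manifest\t%s", manifest$path),
    sprintf("manifest_md5\t%s", unname(tools::md5sum(manifest$path))),
    sprintf("reference_md5\t%s",
            unname(tools::md5sum(manifest$reference_fasta))),
    vapply(samples, function(s)
      sprintf("input_md5\t%s\t%s", basename(s$path),
              unname(tools::md5sum(s$path))), ""),
    sprintf("setting\t%s\t%s", names(st),
            vapply(st, function(v)
              paste(format(v %||% "default"), collapse = ","), ""))
  )
  writeLines(prov, file.path(outdir, "provenance.tsv"))
  writeLines(logs, file.path(outdir, "run.log"))
  invisible(structure(
    list(profiles = profiles, sites = sites, deltas = deltas,
         log = logs, outdir = outdir),
    class = "tbseq_run"
  ))
}

#' @export
print.tbseq_run <- function(x, ...) {
  cat(sprintf(
    "<tbseq_run> %d profiles, %d site set(s), %d delta profile(s) -> %s\n",
    length(x$profiles), length(x$sites), length(x$deltas), x$outdir))
  invisible(x)
}
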