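base_config <- function(...) {
  simulation_config(strrep("ACGT", 30), name = "sim", ...)
}

test_that("config validation enforces the generative invariants", {
  expect_error(base_config(cleavage_sites = c("50" = 1)), "\\[0, 1\\)")
  expect_error(base_config(cleavage_sites = c("120" = 0.5)),
               "< primer_start")
  expect_error(base_config(cleavage_sites = setNames(0.2, NA)), "named")
  expect_error(base_config(background_stop = 1), "\\[0, 1\\)")
  expect_error(base_config(n_reads = 0), "positive")
  expect_error(base_config(min_read_length = 500), "longest possible")
  expect_error(base_config(primer_start = 1), "primer_start")
})

test_that("with no stops every read is full length and piles up at position 1", {
  cfg <- base_config(background_stop = 0, n_reads = 500,
                     min_read_length = 10)
  sim <- simulate_reads(cfg, tb_concentration = 2, seed = 4)
  expect_true(all(sim$reads$start == 1L))
  expect_true(all(sim$reads$end == 120L))
  cov <- count_rt_events(sim$reads, cfg$reference)
  expect_equal(cov$n_stop[1], 500L)
  expect_equal(sum(cov$n_stop), 500L)
  expect_equal(cov$n_readthrough[2], 500L)
})

test_that("a single seeded site is recovered within binomial error", {
  # linear response at >= 2 * k_half gives multiplier exactly 1
  cfg <- base_config(cleavage_sites = c("50" = 0.5),
                     background_stop = 0, n_reads = 20000,
                     min_read_length = 10,
                     concentration_response = "linear")
  sim <- simulate_reads(cfg, tb_concentration = 1, seed = 12)
  expect_equal(sim$truth$multiplier, 1)
  expect_equal(sim$truth$s[50], 0.5)
  cov <- count_rt_events(sim$reads, cfg$reference)
  p <- stop_probability(cov)
  n_reached <- cov$n_stop[50] + cov$n_readthrough[50]
  expect_equal(n_reached, 20000L)  # nothing can stop 3' of the site
  se <- sqrt(0.5 * 0.5 / n_reached)
  expect_lt(abs(p[50] - 0.5), 3 * se)
})

test_that("the same seed reproduces a library byte for byte", {
  cfg <- base_config(cleavage_sites = c("30" = 0.1, "70" = 0.2),
                     n_reads = 5000)
  a <- simulate_reads(cfg, 0.5, seed = 99)
  b <- simulate_reads(cfg, 0.5, seed = 99)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$stop_counts, b$truth$stop_counts)
  ref <- cfg$reference
  fa <- tempfile(fileext = ".sam"); fb <- tempfile(fileext = ".sam")
  write_sam(a$reads, ref, fa); write_sam(b$reads, ref, fb)
  expect_identical(readLines(fa), readLines(fb))
  c_ <- simulate_reads(cfg, 0.5, seed = 100)
  expect_false(identical(a$truth$stop_counts, c_$truth$stop_counts))
})

test_that("simulated SAM round-trips through the alignment reader", {
  cfg <- base_config(cleavage_sites = c("40" = 0.3), n_reads = 400,
                     min_read_length = 15)
  sim <- simulate_reads(cfg, 1, seed = 6)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$reads, cfg$reference, sam)
  back <- read_alignments(sam, transcript = "sim")
  expect_equal(nrow(back), nrow(sim$reads))
  expect_equal(sort(back$start), sort(sim$reads$start))
  expect_true(all(back$end == 120L))
  cov1 <- count_rt_events(sim$reads, cfg$reference)
  cov2 <- count_rt_events(back, cfg$reference)
  expect_equal(cov1$n_stop, cov2$n_stop)
  expect_equal(cov1$n_readthrough, cov2$n_readthrough)
})

test_that("short reads are discarded and counted", {
  cfg <- base_config(background_stop = 0.05, n_reads = 4000,
                     min_read_length = 60)
  sim <- simulate_reads(cfg, 0, seed = 2)
  expect_true(all(sim$reads$end - sim$reads$start + 1L >= 60L))
  expect_gt(sim$n_discarded, 0)
  expect_equal(nrow(sim$reads) + sim$n_discarded, 4000L)
})

test_that("closed-form truth matches hand arithmetic and the Hill response", {
  cfg <- base_config(cleavage_sites = c("50" = 0.2),
                     background_stop = 0.01)
  tr_sat <- true_stop_propensity(cfg, 1e9)  # multiplier -> 1
  tr_0 <- true_stop_propensity(cfg, 0)
  raw <- truth_reactivity(tr_sat, tr_0)
  expect_equal(raw[50], (0.01 + 0.99 * 0.2) - 0.01, tolerance = 1e-6)
  expect_true(all(raw[-50] == 0))
  # at c = k_half the effective propensity is half-saturated
  tr_half <- true_stop_propensity(cfg, cfg$k_half)
  expect_equal(tr_half$kappa_eff[50], 0.1)
  expect_equal(hill_multiplier(0.5, 0.5), 0.5)
  # no-site config: zero reactivity everywhere
  cfg0 <- base_config()
  expect_true(all(truth_reactivity(true_stop_propensity(cfg0, 2),
                                   true_stop_propensity(cfg0, 0)) == 0))
})

test_that("read-through coverage decreases from the primer toward the 5' end", {
  cfg <- base_config(cleavage_sites = c("40" = 0.2, "80" = 0.2),
                     background_stop = 0.02, n_reads = 30000,
                     min_read_length = 10)
  sim <- simulate_reads(cfg, 2, seed = 21)
  cov <- count_rt_events(sim$reads, cfg$reference)
  # all reads share the primer end, so the counts are exactly monotone
  expect_true(all(diff(cov$n_readthrough[2:120]) >= 0))
})

test_that("expected reactivity is monotone over the probed concentration range", {
  cfg <- base_config(cleavage_sites = c("40" = 0.15, "80" = 0.3))
  tr0 <- true_stop_propensity(cfg, 0)
  series <- vapply(c(0.01, 0.1, 0.5, 1, 2), function(cc)
    truth_reactivity(true_stop_propensity(cfg, cc), tr0)[c(40, 80)],
    numeric(2))
  expect_true(all(diff(series[1, ]) > 0))
  expect_true(all(diff(series[2, ]) > 0))
})

test_that("the estimation pipeline recovers truth within binomial error", {
  # moderate-depth recovery check across three seeds
  sites <- setNames(rep(0.15, 4), c("30", "55", "80", "105"))
  cfg <- simulation_config(strrep("ACGT", 38), sites,
                           background_stop = 0.01, n_reads = 150000,
                           min_read_length = 15, name = "sim")
  frac_ok <- vapply(1:3, function(sd_) {
    trt <- simulate_reads(cfg, 0.5, seed = 1000 + sd_)
    unt <- simulate_reads(cfg, 0, seed = 2000 + sd_)
    cov_t <- count_rt_events(trt$reads, cfg$reference)
    cov_u <- count_rt_events(unt$reads, cfg$reference)
    mask <- mask_low_coverage(cov_t, 10000) &
      mask_low_coverage(cov_u, 10000)
    est <- background_subtract(stop_probability(cov_t, mask),
                               stop_probability(cov_u, mask))
    truth <- truth_reactivity(trt$truth, unt$truth)
    s_t <- trt$truth$s; s_u <- unt$truth$s
    n_t <- cov_t$n_stop + cov_t$n_readthrough
    n_u <- cov_u$n_stop + cov_u$n_readthrough
    se <- sqrt(s_t * (1 - s_t) / pmax(n_t, 1) +
                 s_u * (1 - s_u) / pmax(n_u, 1))
    idx <- which(mask)
    mean(abs(est[idx] - truth[idx]) < 4 * se[idx])
  }, 0)
  expect_true(all(frac_ok >= 0.99))
})

test_that("experiment harness produces one profile per replicate and concentration", {
  sites <- setNames(rep(0.2, 2), c("40", "80"))
  cfg <- simulation_config(strrep("ACGT", 30), sites, n_reads = 40000,
                           background_stop = 0.01, min_read_length = 15)
  exp_ <- simulate_probing_experiment(cfg, concentrations = c(0.5, 2),
                                      replicates = c("r1", "r2"),
                                      seed = 5, min_readthrough = 1000)
  expect_length(exp_$profiles, 4)
  expect_named(exp_$profiles,
               c("r1_0.5mM", "r1_2mM", "r2_0.5mM", "r2_2mM"))
  cond <- attr(exp_$profiles[["r2_2mM"]], "condition")
  expect_equal(cond$tb_concentration, 2)
  expect_equal(cond$replicate_id, "r2")
  # seeded sites dominate their profiles
  expect_equal(exp_$profiles[["r1_2mM"]]$norm[40], 8)
})
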