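# Build a replicate x concentration profile grid where `site_norm` and
# `site_raw` prescribe one position of interest (position 5 of 20);
# background positions sit at 0.1 normalized / 0.01 raw.
profile_grid <- function(site_norm_by_conc, site_raw_by_conc,
                         replicates = c("r1", "r2"),
                         concentrations = as.numeric(names(site_norm_by_conc)),
                         jitter = 0) {
  profs <- list()
  k <- 0
  for (r in replicates) {
    for (i in seq_along(concentrations)) {
      k <- k + 1
      norm <- rep(0.1, 20)
      raw <- rep(0.01, 20)
      v <- site_norm_by_conc[[i]]
      ri <- match(r, replicates)
      norm[5] <- if (length(v) >= ri) v[ri] else v[1]
      raw[5] <- site_raw_by_conc[[i]] + jitter * k * 1e-6
      profs[[paste0(r, "_", concentrations[i])]] <-
        fake_profile(norm, raw, tb_concentration = concentrations[i],
                     replicate_id = r)
    }
  }
  profs
}

test_that("a site below threshold in one replicate is not called", {
  profs <- list(
    fake_profile(c(rep(0.1, 4), 0.4, rep(0.1, 15)), replicate_id = "r1"),
    fake_profile(c(rep(0.1, 4), 0.6, rep(0.1, 15)), replicate_id = "r2"),
    fake_profile(c(rep(0.1, 4), 0.4, rep(0.1, 15)),
                 tb_concentration = 2, replicate_id = "r1"),
    fake_profile(c(rep(0.1, 4), 0.7, rep(0.1, 15)),
                 tb_concentration = 2, replicate_id = "r2"))
  sites <- call_strong_sites(profs)
  row5 <- sites[sites$position == 5, ]
  expect_false(row5$pass_threshold)
  expect_false(row5$called)
  expect_length(called_positions(sites), 0)
})

test_that("a reproducible concentration-dependent site is called", {
  profs <- profile_grid(
    site_norm_by_conc = list(`0.1` = c(0.3, 0.3), `0.5` = c(0.8, 0.9),
                             `2` = c(1.5, 1.5)),
    site_raw_by_conc = list(`0.1` = 0.2, `0.5` = 0.5, `2` = 0.9))
  sites <- call_strong_sites(profs)
  row5 <- sites[sites$position == 5, ]
  expect_true(row5$pass_threshold)
  expect_true(row5$pass_replicates)
  expect_true(row5$pass_concentration)  # Spearman rho = 1
  expect_equal(called_positions(sites), 5L)
  expect_equal(row5$mean_norm_reactivity, mean(c(0.8, 0.9)))
})

test_that("an anticorrelated concentration series fails criterion three", {
  profs <- profile_grid(
    site_norm_by_conc = list(`0.1` = c(0.9, 0.9), `0.5` = c(0.9, 0.9),
                             `2` = c(0.9, 0.9)),
    site_raw_by_conc = list(`0.1` = 0.9, `0.5` = 0.5, `2` = 0.2))
  sites <- call_strong_sites(profs)
  row5 <- sites[sites$position == 5, ]
  expect_true(row5$pass_threshold)
  expect_false(row5$pass_concentration)  # rho = -1
  expect_length(called_positions(sites), 0)
})

test_that("two-concentration series require a strict increase", {
  up <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(0.9, 0.9), `2` = c(1, 1)),
    site_raw_by_conc = list(`0.5` = 0.3, `2` = 0.6))
  expect_equal(called_positions(call_strong_sites(up)), 5L)
  flat <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(0.9, 0.9), `2` = c(1, 1)),
    site_raw_by_conc = list(`0.5` = 0.6, `2` = 0.6))
  expect_length(called_positions(call_strong_sites(flat)), 0)
})

test_that("a single probe concentration makes criterion three non-evaluable", {
  profs <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(0.9, 0.9)),
    site_raw_by_conc = list(`0.5` = 0.5))
  expect_warning(sites <- call_strong_sites(profs),
                 "fewer than 2 distinct probe concentrations")
  expect_length(called_positions(sites), 0)
})

test_that("raising the threshold never adds sites", {
  set.seed(19)
  concs <- c(0.1, 0.5, 2)
  profs <- list()
  for (r in c("r1", "r2")) for (cc in concs) {
    raw <- runif(20, 0, 0.2) + 0.3 * cc / (cc + 0.5) * (runif(20) > 0.5)
    profs[[paste0(r, cc)]] <- fake_profile(pmin(8 * raw, 8), raw,
                                           tb_concentration = cc,
                                           replicate_id = r)
  }
  called <- lapply(c(0.2, 0.5, 1, 2), function(th)
    called_positions(call_strong_sites(profs, threshold = th)))
  for (i in seq_len(length(called) - 1)) {
    expect_true(all(called[[i + 1]] %in% called[[i]]))
  }
})

test_that("called sites are confined to everywhere-unmasked positions", {
  mask <- rep(TRUE, 20); mask[c(1, 5, 12)] <- FALSE
  profs <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(2, 2), `2` = c(3, 3)),
    site_raw_by_conc = list(`0.5` = 0.3, `2` = 0.6))
  profs[[1]]$mask <- mask
  sites <- call_strong_sites(profs)
  expect_false(any(c(1, 5, 12) %in% sites$position))
  expect_length(called_positions(sites), 0)  # site position is masked
})

test_that("position 1 (full-length pileup) is never evaluated by default", {
  profs <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(2, 2), `2` = c(3, 3)),
    site_raw_by_conc = list(`0.5` = 0.3, `2` = 0.6))
  for (i in seq_along(profs)) {
    profs[[i]]$norm[1] <- 8
    profs[[i]]$raw[1] <- 0.9
  }
  sites <- call_strong_sites(profs)
  expect_false(1L %in% sites$position)
})

test_that("degenerate inputs are rejected", {
  expect_error(call_strong_sites(list()), "empty")
  profs <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(2, 2), `2` = c(3, 3)),
    site_raw_by_conc = list(`0.5` = 0.3, `2` = 0.6))
  attr(profs[[2]], "transcript") <- "other"
  expect_error(call_strong_sites(profs), "multiple transcripts")
  one_rep <- profile_grid(
    site_norm_by_conc = list(`0.5` = 2, `2` = 3),
    site_raw_by_conc = list(`0.5` = 0.3, `2` = 0.6),
    replicates = "r1")
  expect_error(call_strong_sites(one_rep), "replicates")
})

test_that("site BED export is 0-based half-open with one-nt intervals", {
  profs <- profile_grid(
    site_norm_by_conc = list(`0.5` = c(2, 2), `2` = c(3, 3)),
    site_raw_by_conc = list(`0.5` = 0.3, `2` = 0.6))
  sites <- call_strong_sites(profs)
  expect_equal(called_positions(sites), 5L)
  bed <- tempfile(fileext = ".bed")
  tsv <- tempfile(fileext = ".tsv")
  write_strong_sites(sites, bed_path = bed, tsv_path = tsv)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(b$V2, 4)   # 1-based position 5 -> 0-based start 4
  expect_equal(b$V3, 5)
  tt <- utils::read.delim(tsv)
  expect_equal(nrow(tt), nrow(sites))
})
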