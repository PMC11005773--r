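noise_free_sim <- function(composition = "AAB", beta = 0, u = 2,
                           n_chrom = 2, len = 1e6, segments = NULL, seed = 1,
                           ploidy = nchar(composition)) {
  sc <- sim_scenario(n_chromosomes = n_chrom, chromosome_length = len,
                     ploidy = ploidy, base_composition = composition,
                     segments = segments, per_copy_depth = u, beta = beta,
                     noise = "none", conserved_fraction = 1, seed = seed)
  simulate_depths(sc)
}

test_that("normalization reproduces closed-form Relative Coverage levels", {
  # balanced diploid: both tracks flat at 1
  sim <- noise_free_sim("AB", u = 4)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  expect_equal(unique(rc$r_anchor), 1)
  expect_equal(unique(rc$r_partner), 1)

  # 2:1 dosage: M_c = 1.5u, so r = 4/3 vs 2/3
  sim2 <- noise_free_sim("AAB", u = 3)
  rc2 <- relative_coverage(sim2$depth1, sim2$depth2, sim2$map)
  rcA <- rc2[rc2$anchor == "A", ]
  expect_equal(unique(rcA$r_anchor), 4 / 3)
  expect_equal(unique(rcA$r_partner), 2 / 3)
  expect_equal(unique(rc2$r_anchor[rc2$anchor == "B"]), 2 / 3)

  # full trisomy of the partner: r hits the extremes of the 0-2 range
  sim3 <- noise_free_sim("BBB", u = 2, ploidy = 3)
  rc3 <- relative_coverage(sim3$depth1, sim3$depth2, sim3$map)
  expect_equal(unique(rc3$r_anchor[rc3$anchor == "A"]), 0)
  expect_equal(unique(rc3$r_partner[rc3$anchor == "A"]), 2)
  expect_true(all(rc3$r_anchor <= 2) && all(rc3$r_partner <= 2))
})

test_that("the chromosome mean of (r_anchor + r_partner)/2 is 1 by construction", {
  sc <- sim_preset("bluggoe_abb", n_chromosomes = 5, per_copy_depth = 3,
                   beta = 0.05, seed = 21)
  sim <- simulate_depths(sc)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  means <- rc |>
    dplyr::group_by(anchor, chrom) |>
    dplyr::summarise(m = mean((r_anchor + r_partner) / 2), .groups = "drop")
  expect_equal(means$m, rep(1, nrow(means)), tolerance = 1e-12)
})

test_that("combined window depth is conserved across dosage splits", {
  # E[d_anchor + d_partner] = u * p regardless of the split and of beta
  totals <- purrr::map_dbl(c("AAA", "AAB", "ABB", "BBB"), function(comp) {
    sc <- sim_scenario(n_chromosomes = 1, chromosome_length = 5e7,
                       base_composition = comp, per_copy_depth = 4,
                       beta = 0.08, seed = 31)
    sim <- simulate_depths(sc)
    mean(sim$depth1$median_depth + sim$depth2$median_depth)
  })
  expect_true(all(abs(totals - 12) / 12 < 0.05))
  expect_lt(diff(range(totals)) / 12, 0.05)
})

test_that("background estimation recovers the injected cross-mapping rate", {
  # null case: no cross-mapping injected
  sc0 <- sim_preset("plantain_aab", n_chromosomes = 6, per_copy_depth = 30,
                    beta = 0, seed = 41)
  rc0 <- relative_coverage(simulate_depths(sc0)$depth1,
                           simulate_depths(sc0)$depth2,
                           simulate_depths(sc0)$map)
  bg0 <- estimate_background(rc0, p = 3)
  expect_lt(bg0$beta, 0.01)

  # beta = 0.05 with several pure segments planted (plantain has AAA and BBB-free
  # pure stretches via its AAA introgressions)
  sc <- sim_preset("plantain_aab", n_chromosomes = 6, per_copy_depth = 50,
                   beta = 0.05, seed = 42)
  sim <- simulate_depths(sc)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  bg <- estimate_background(rc, p = 3)
  expect_lt(abs(bg$beta - 0.05), 0.01)
  expect_true(bg$converged)

  # no pure windows anywhere: fall back to the configured rate with a warning
  simu <- noise_free_sim("AAB", beta = 0.02, u = 10)
  rcu <- relative_coverage(simu$depth1, simu$depth2, simu$map)
  expect_warning(bgu <- estimate_background(rcu, p = 3, fallback = 0.03),
                 "fallback")
  expect_equal(bgu$beta, 0.03)
  expect_true(bgu$from_fallback)
})

test_that("tidy and glance summarize the background model", {
  sim <- noise_free_sim("AAB", beta = 0,
                        segments = tibble::tibble(
                          chrom = 1L, start_window = 1L, end_window = 3L,
                          composition = "AAA"))
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  bg <- estimate_background(rc, p = 3)
  td <- tidy(bg)
  expect_equal(td$term, c("beta", "minor_relative_coverage"))
  expect_equal(td$estimate[2], 2 * td$estimate[1])
  gl <- glance(bg)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("beta", "iterations", "converged") %in% names(gl)))
})

test_that("dosage classification hits the printed ratio levels", {
  rc <- tibble::tibble(
    track_id = "t", anchor = "A", partner = "B", chrom = "c1",
    start = c(0, 1e5, 2e5), end = c(1e5, 2e5, 3e5),
    partner_chrom = "c1", partner_start = c(0, 1e5, 2e5),
    partner_end = c(1e5, 2e5, 3e5),
    r_anchor = c(1.33, 0.67, 0), r_partner = c(0.67, 1.33, 2), m_c = 3)
  calls <- classify_dosage(rc, p = 3, background = 0)
  expect_equal(calls$a_hat, c(2L, 1L, 0L))
  expect_equal(calls$composition, c("AAB", "ABB", "BBB"))
  expect_equal(calls$b_hat, c(1L, 2L, 3L))

  # ties break toward the smaller copy number: r exactly between levels
  tie <- rc[1, ] |> dplyr::mutate(r_anchor = 1)  # halfway between 2/3 and 4/3
  expect_equal(classify_dosage(tie, p = 3)$a_hat, 1L)

  # values far above 2 are flagged anomalous but still classified
  wild <- rc[1, ] |> dplyr::mutate(r_anchor = 2.6)
  cw <- classify_dosage(wild, p = 3)
  expect_true(cw$anomalous)
  expect_equal(cw$a_hat, 3L)
})

test_that("window dosage accuracy exceeds 99% under per-base median noise", {
  # per-base Poisson piles with the median taken over positions: the regime
  # where per-window medians are tight at low (>= 2x per copy) depth
  sc <- sim_scenario(n_chromosomes = 2, chromosome_length = 1e5,
                     window_size = 1000, base_composition = "AAB",
                     segments = tibble::tibble(
                       chrom = 2L, start_window = 10L, end_window = 60L,
                       composition = "ABB"),
                     per_copy_depth = 2.5, beta = 0.1, noise = "poisson",
                     depth_mode = "perbase", conserved_fraction = 1, seed = 51)
  sim <- simulate_depths(sc)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  calls <- classify_dosage(rc[rc$anchor == "A", ], p = 3, background = 0.1)
  cmp <- dplyr::inner_join(
    calls, sim$truth_windows |> dplyr::select(chrom, start, a),
    by = c("chrom", "start"))
  expect_gte(mean(cmp$a_hat == cmp$a), 0.99)
})

test_that("background correction inverts the cross-mapping mixture", {
  sim <- noise_free_sim("BBB", beta = 0.06, u = 5, ploidy = 3)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  rcA <- rc[rc$anchor == "A", ]
  expect_equal(unique(round(rcA$r_anchor, 10)), 2 * 0.06)
  corr <- correct_background(rcA, 0.06)
  expect_equal(unique(round(corr$r_anchor, 10)), 0)
  expect_equal(unique(round(corr$r_partner, 10)), 2)
})

test_that("segmentation recovers planted runs, smooths flips, respects minima", {
  segs <- tibble::tibble(chrom = 1L, start_window = 30L, end_window = 69L,
                         composition = "AAA")
  sim <- noise_free_sim("AAB", u = 3, n_chrom = 2, len = 1e7, segments = segs)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  calls <- classify_dosage(rc[rc$anchor == "A", ], p = 3)
  # flip two isolated windows to the wrong call; smoothing must absorb them
  flip <- which(calls$chrom == "chr01" & calls$start %in% c(10e5, 80e5))
  calls$a_hat[flip] <- 3L
  got <- segment_calls(calls, min_windows = 5, smooth_k = 5)
  expect_equal(nrow(got), 1)
  expect_equal(got$chrom, "chr01")
  expect_equal(got$composition, "AAA")
  truth_start <- 29 * 1e5
  truth_end <- 69 * 1e5
  expect_lte(abs(got$start - truth_start), 5 * 1e5)
  expect_lte(abs(got$end - truth_end), 5 * 1e5)
  expect_false(got$whole_chromosome)

  # uniform composition: no segments at all
  unif <- classify_dosage(rc[rc$anchor == "A", ] |>
                            dplyr::filter(chrom == "chr02"), p = 3)
  expect_equal(nrow(segment_calls(unif)), 0)

  # segments shorter than min_windows are never reported
  for (mw in c(3, 5, 10)) {
    out <- segment_calls(calls, min_windows = mw)
    expect_true(all(out$n_windows >= mw))
  }
})

test_that("whole-chromosome exchanges are flagged as such", {
  segs <- tibble::tibble(chrom = 2L, start_window = 1L, end_window = 100L,
                         composition = "BBB")
  sim <- noise_free_sim("ABB", u = 3, n_chrom = 3, len = 1e7, segments = segs)
  rc <- relative_coverage(sim$depth1, sim$depth2, sim$map)
  calls <- classify_dosage(rc[rc$anchor == "A", ], p = 3)
  got <- segment_calls(calls)
  expect_equal(nrow(got), 1)
  expect_equal(got$chrom, "chr02")
  expect_equal(got$composition, "BBB")
  expect_true(got$whole_chromosome)
})

test_that("chromosome ratio tables summarize dosage and locate introgressions", {
  balanced <- noise_free_sim("AB", u = 4)
  rcb <- relative_coverage(balanced$depth1, balanced$depth2, balanced$map)
  rt <- chromosome_ratio_table(rcb[rcb$anchor == "A", ])
  expect_equal(rt$ratio, rep(1, nrow(rt)))

  aab <- noise_free_sim("AAB", u = 3, n_chrom = 4, len = 1e7,
                        segments = tibble::tibble(
                          chrom = 2L, start_window = 1L, end_window = 50L,
                          composition = "ABB"))
  rc <- relative_coverage(aab$depth1, aab$depth2, aab$map)
  rt2 <- chromosome_ratio_table(rc[rc$anchor == "A", ])
  unmod <- rt2[rt2$chrom != "chr02", ]
  expect_equal(unmod$ratio, rep(2, nrow(unmod)))
  # the introgressed chromosome has the minimum anchor/partner ratio
  expect_equal(rt2$chrom[which.min(rt2$ratio)], "chr02")

  # a pure anchor chromosome yields the infinite sentinel
  pure <- noise_free_sim("AA", u = 4, ploidy = 2)
  rcp <- relative_coverage(pure$depth1, pure$depth2, pure$map)
  rtp <- chromosome_ratio_table(rcp[rcp$anchor == "A", ])
  expect_true(all(is.infinite(rtp$ratio)))
})
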