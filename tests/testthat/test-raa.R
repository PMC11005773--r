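make_stats <- function(pp, total = 1000) {
  # pp: tibble(sample_id, reference_id, pp_percent)
  pp |>
    dplyr::mutate(scope = "genome", total_reads = total,
                  properly_paired = round(total * pp_percent / 100),
                  pp_percent = 100 * properly_paired / total_reads) |>
    dplyr::select(sample_id, reference_id, scope, total_reads,
                  properly_paired, pp_percent)
}

trio_stats <- function() {
  make_stats(tidyr::expand_grid(
    sample_id = c("s1", "s2", "s3"), reference_id = "A") |>
      dplyr::mutate(pp_percent = c(80, 82, 84)))
}
trio_clusters <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                                cluster_label = "c1")

test_that("cluster profiles are arithmetic means of member percentages", {
  prof <- cluster_profile(trio_stats(), trio_clusters)
  expect_equal(prof$profile_pp, 82)
  expect_equal(prof$n_members, 3)

  # a single-reference table yields a profile for that reference alone
  expect_equal(unique(prof$reference_id), "A")

  # clusters below the minimum size are excluded with a warning
  small <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                          cluster_label = c("c1", "c1", "lonely"))
  expect_warning(p2 <- cluster_profile(trio_stats(), small, min_members = 2),
                 "lonely")
  expect_false("lonely" %in% p2$cluster_label)
})

test_that("weight factors average per-reference sample-to-profile ratios", {
  stats <- make_stats(tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 2),
    reference_id = rep(c("A", "B"), 2),
    pp_percent = c(84, 73.5,   # s1: 1.05x the profile on both references
                   76, 66.5))) # s2 fills the cluster
  clusters <- tibble::tibble(sample_id = c("s1", "s2"), cluster_label = "c1")
  profiles <- tibble::tibble(cluster_label = "c1", reference_id = c("A", "B"),
                             scope = "genome", n_members = 2,
                             profile_pp = c(80, 70))
  w <- weight_factors(stats, clusters, profiles = profiles, min_members = 2)
  expect_equal(w$weight_factor[w$sample_id == "s1"], 1.05)

  # a sample equal to its profile gets weight exactly 1
  stats_eq <- make_stats(tibble::tibble(
    sample_id = "s3", reference_id = c("A", "B"), pp_percent = c(80, 70)))
  w3 <- weight_factors(stats_eq,
                       tibble::tibble(sample_id = "s3", cluster_label = "c1"),
                       profiles = profiles, min_members = 2)
  expect_equal(w3$weight_factor, 1)
})

test_that("samples missing one reference drop it from the weight mean", {
  stats <- make_stats(tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    reference_id = c("A", "B", "A"),
    pp_percent = c(84, 73.5, 84)))
  clusters <- tibble::tibble(sample_id = c("s1", "s2"), cluster_label = "c1")
  profiles <- tibble::tibble(cluster_label = "c1", reference_id = c("A", "B"),
                             scope = "genome", n_members = 2,
                             profile_pp = c(80, 70))
  expect_warning(
    w <- weight_factors(stats, clusters, profiles = profiles, min_members = 2),
    "lacks statistics")
  expect_equal(w$weight_factor[w$sample_id == "s2"], 84 / 80)
})

test_that("unclustered samples get weight 1 and are flagged", {
  stats <- trio_stats() |>
    dplyr::bind_rows(make_stats(tibble::tibble(
      sample_id = "lone", reference_id = "A", pp_percent = 90)))
  clusters <- dplyr::bind_rows(trio_clusters,
                               tibble::tibble(sample_id = "lone",
                                              cluster_label = "unclustered"))
  expect_warning(w <- weight_factors(stats, clusters), "weight 1")
  lone <- w[w$sample_id == "lone", ]
  expect_equal(lone$weight_factor, 1)
  expect_false(lone$normalized)
})

test_that("RAA divides percentages by weights; unit weights are the identity", {
  stats <- trio_stats()
  w <- tibble::tibble(sample_id = c("s1", "s2", "s3"), scope = "genome",
                      cluster_label = "c1",
                      weight_factor = c(1.05, 1, 1), n_references = 1,
                      normalized = TRUE)
  raa <- compute_raa(stats, trio_clusters, weights = w)
  expect_equal(raa$raa[raa$sample_id == "s1"], 80 / 1.05)
  expect_equal(raa$raa[raa$sample_id %in% c("s2", "s3")],
               stats$pp_percent[stats$sample_id %in% c("s2", "s3")])
  expect_error(compute_raa(trio_stats(), trio_clusters, weights = w[-1, ]),
               "s1")
})

test_that("multiplicative sample effects cancel exactly when they average to 1", {
  # property: pp = profile x q_s with mean(q) = 1 implies RAA == profile for
  # every sample, to machine precision, across random panels
  for (seed in 1:5) {
    withr::with_seed(seed, {
      profile <- runif(3, 60, 95)
      q <- runif(5, 0.9, 1.1)
      q <- q / mean(q)
      stats <- tidyr::expand_grid(s = 1:5, r = 1:3) |>
        dplyr::mutate(sample_id = paste0("s", s),
                      reference_id = LETTERS[r], scope = "genome",
                      pp_percent = profile[r] * q[s],
                      total_reads = 0, properly_paired = 0) |>
        dplyr::mutate(total_reads = 1, properly_paired = pp_percent / 100) |>
        dplyr::select(sample_id, reference_id, scope, total_reads,
                      properly_paired, pp_percent)
      clusters <- tibble::tibble(sample_id = paste0("s", 1:5),
                                 cluster_label = "c")
      raa <- compute_raa(stats, clusters)
      for (r in 1:3) {
        expect_equal(raa$raa[raa$reference_id == LETTERS[r]],
                     rep(profile[r], 5), tolerance = 1e-12)
      }
      # cluster mean of weight factors is exactly 1 (profiles include self)
      w <- weight_factors(stats, clusters)
      expect_equal(mean(w$weight_factor), 1, tolerance = 1e-12)
    })
  }
})

test_that("RAA is invariant when one sample's statistics are rescaled", {
  stats <- make_stats(tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    reference_id = rep(c("A", "B"), 3),
    pp_percent = c(80, 70, 82, 71, 84, 73)))
  clusters <- trio_clusters
  profiles <- cluster_profile(stats, clusters)
  raa1 <- compute_raa(stats, clusters,
                      weights = weight_factors(stats, clusters, profiles))
  scaled <- stats |>
    dplyr::mutate(pp_percent = ifelse(sample_id == "s2", pp_percent * 0.9,
                                      pp_percent),
                  properly_paired = total_reads * pp_percent / 100)
  raa2 <- compute_raa(scaled, clusters,
                      weights = weight_factors(scaled, clusters, profiles))
  expect_equal(raa2$raa[raa2$sample_id == "s2"],
               raa1$raa[raa1$sample_id == "s2"], tolerance = 1e-12)
})

test_that("RAA is strictly increasing in pp_percent at fixed weights", {
  w <- tibble::tibble(sample_id = "s1", scope = "genome", cluster_label = "c",
                      weight_factor = 1.02, n_references = 2, normalized = TRUE)
  pps <- seq(10, 90, by = 10)
  raas <- vapply(pps, function(pp) {
    stats <- make_stats(tibble::tibble(sample_id = "s1", reference_id = "A",
                                       pp_percent = pp))
    compute_raa(stats, tibble::tibble(sample_id = "s1", cluster_label = "c"),
                weights = w)$raa
  }, numeric(1))
  expect_true(all(diff(raas) > 0))
})

test_that("reference ranking identifies the dominant subgenome and flags ties", {
  raa <- tibble::tibble(
    sample_id = "aab", reference_id = c("A", "B"), scope = "genome",
    pp_percent = c(82, 74), weight_factor = 1, raa = c(82, 74))
  rk <- rank_references(raa)
  expect_equal(rk$reference_id[rk$rank == 1], "A")
  expect_false(rk$tied_with_next[1])

  abb <- raa |> dplyr::mutate(sample_id = "abb", raa = c(74, 82))
  rk2 <- rank_references(abb)
  expect_equal(rk2$reference_id[rk2$rank == 1], "B")

  tie <- raa |> dplyr::mutate(raa = c(80, 80))
  expect_true(rank_references(tie)$tied_with_next[1])

  expect_error(rank_references(raa[1, ]), "at least two")
})

test_that("simulated panels recover weights inside the injected range", {
  pan <- panel_scenario(
    clusters = tibble::tibble(cluster_label = c("c1", "c2"),
                              n_samples = c(15, 15)),
    q_half_width = 0.05, noise_sd = 0.3, seed = 7)
  sim <- simulate_stats_panel(pan)
  w <- weight_factors(sim$stats, sim$clusters)
  expect_true(all(w$weight_factor > 0.95 * 0.98))
  expect_true(all(w$weight_factor < 1.05 * 1.02))
  # recovered weights track the injected multipliers closely
  cmp <- dplyr::inner_join(w, sim$truth, by = c("sample_id", "cluster_label")) |>
    dplyr::group_by(cluster_label) |>
    dplyr::mutate(q_rel = q / mean(q)) |>
    dplyr::ungroup()
  expect_true(all(abs(cmp$weight_factor - cmp$q_rel) < 0.02))
})
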