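#' Per-cluster alignment profiles
#'
#' Averages the properly-paired percentage over the members of each varietal
#' cluster, per reference genome (and per scope when chromosome-level rows
#' are used). These profiles are the denominator of the per-sample weight
#' factor: they capture how well a typical member of the cluster aligns to
#' each reference, so that deviations of an individual sample are attributable
#' to sample quality rather than ancestry.
#'
#' @param stats Alignment-statistics tibble (see [parse_flagstat()]).
#' @param clusters Tibble with columns `sample_id`, `cluster_label`. Samples
#'   labelled `unclustered` (the sentinel) are ignored for profiling.
#' @param scope `"genome"` (default) to profile whole-genome rows,
#'   `"chromosome"` for all per-chromosome rows, or a specific scope value.
#' @param min_members Minimum cluster size for a usable profile (default 3).
#'   Smaller clusters are dropped with a warning.
#'
#' @return Tibble with columns `cluster_label`, `reference_id`, `scope`,
#'   `n_members`, `profile_pp`.
#' @export
cluster_profile <- function(stats, clusters, scope = "genome", min_members = 3) {
  validate_stats(stats)
  stats <- filter_scope(stats, scope)
  known <- stats |>
    inner_join(clusters, by = "sample_id") |>
    filter(.data$cluster_label != "unclustered")
  missing <- setdiff(unique(stats$sample_id), clusters$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("samples missing from cluster assignment: %s",
                  paste(missing, collapse = ", ")))
  }
  sizes <- known |> distinct(.data$sample_id, .data$cluster_label) |>
    dplyr::count(.data$cluster_label, name = "n_members")
  small <- sizes |> filter(.data$n_members < min_members)
  if (nrow(small) > 0) {
    warn(sprintf("cluster(s) below the minimum size of %d excluded: %s",
                 min_members, paste(small$cluster_label, collapse = ", ")))
  }
  known |>
    inner_join(sizes, by = "cluster_label") |>
    filter(.data$n_members >= min_members) |>
    group_by(.data$cluster_label, .data$reference_id, .data$scope, .data$n_members) |>
    summarise(profile_pp = mean(.data$pp_percent), .groups = "drop")
}

#' Per-sample weight factors
#'
#' For each sample, the weight factor is the mean over reference genomes of
#' the ratio between the sample's properly-paired percentage and its
#' cluster's profile on that reference. It absorbs multiplicative sample
#' quality effects (DNA quality, PCR duplication, ...): a sample that aligns
#' 5% better than its cluster on every reference gets a weight of 1.05.
#' Samples without a usable cluster profile receive weight 1.0 and are
#' flagged in the `normalized` column.
#'
#' @inheritParams cluster_profile
#' @param profiles Output of [cluster_profile()]; computed from `stats` and
#'   `clusters` when omitted.
#' @param warn_range Observed plausible range for weight factors; values
#'   outside it trigger a warning but are kept (default `c(0.95, 1.05)`).
#'
#' @return Tibble with columns `sample_id`, `scope`, `cluster_label`,
#'   `weight_factor`, `n_references`, `normalized`. The weight is constant
#'   across references for a given sample and scope.
#' @export
weight_factors <- function(stats, clusters, profiles = NULL, scope = "genome",
                           min_members = 3, warn_range = c(0.95, 1.05)) {
  validate_stats(stats)
  stats <- filter_scope(stats, scope)
  if (is.null(profiles)) {
    profiles <- withCallingHandlers(
      cluster_profile(stats, clusters, scope = scope, min_members = min_members),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  if (any(profiles$profile_pp == 0)) {
    abort("cluster profile contains a zero pp_percent; cannot form ratios")
  }
  joined <- stats |>
    left_join(clusters, by = "sample_id") |>
    left_join(profiles |> rename(profile_scope = "scope"),
              by = c("reference_id", "cluster_label", "scope" = "profile_scope"))
  refs_per_cluster <- profiles |> distinct(.data$cluster_label, .data$reference_id)
  dropped <- joined |>
    filter(!is.na(.data$profile_pp)) |>
    group_by(.data$sample_id, .data$scope, .data$cluster_label) |>
    summarise(n_refs = dplyr::n_distinct(.data$reference_id), .groups = "drop") |>
    left_join(refs_per_cluster |> dplyr::count(.data$cluster_label, name = "n_expected"),
              by = "cluster_label") |>
    filter(.data$n_refs < .data$n_expected)
  if (nrow(dropped) > 0) {
    warn(sprintf("sample %s lacks statistics for some reference(s); those are dropped from its weight mean",
                 dropped$sample_id[1]))
  }
  weights <- joined |>
    group_by(.data$sample_id, .data$scope, .data$cluster_label) |>
    summarise(
      weight_factor = if (all(is.na(.data$profile_pp))) 1.0 else
        mean(.data$pp_percent[!is.na(.data$profile_pp)] /
               .data$profile_pp[!is.na(.data$profile_pp)]),
      n_references = sum(!is.na(.data$profile_pp)),
      .groups = "drop"
    ) |>
    mutate(normalized = .data$n_references > 0)
  if (any(!weights$normalized)) {
    warn(sprintf("%d sample(s) without a usable cluster profile were assigned weight 1.0",
                 sum(!weights$normalized)))
  }
  out_of_range <- weights$normalized &
    (weights$weight_factor < warn_range[1] | weights$weight_factor > warn_range[2])
  if (any(out_of_range)) {
    warn(sprintf("weight factor outside [%g, %g] for sample(s): %s",
                 warn_range[1], warn_range[2],
                 paste(weights$sample_id[out_of_range], collapse = ", ")))
  }
  weights
}

#' Relative Averaged Alignment (RAA)
#'
#' Divides each sample's properly-paired alignment percentage by its weight
#' factor, per reference genome. The result is comparable across samples of
#' different technical quality: within a clonal cluster, RAA differences
#' between references reflect ancestry (subgenome composition and reference
#' bias), not library quality. Per-chromosome RAA repeats the whole
#' procedure on chromosome-scope statistics with chromosome-specific weights;
#' no chromosome-length normalization is applied.
#'
#' @inheritParams cluster_profile
#' @param weights Output of [weight_factors()]; computed when omitted.
#'
#' @return Tibble with columns `sample_id`, `reference_id`, `scope`,
#'   `pp_percent`, `weight_factor`, `raa`, carrying class `"raa_tbl"` for
#'   plotting.
#' @export
#' @examples
#' stats <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2", "s3"), each = 2),
#'   reference_id = rep(c("A", "B"), 3), scope = "genome",
#'   total_reads = 1000,
#'   properly_paired = c(800, 700, 820, 717, 840, 735),
#'   pp_percent = c(80, 70, 82, 71.7, 84, 73.5))
#' clusters <- tibble::tibble(sample_id = c("s1", "s2", "s3"), cluster_label = "c1")
#' compute_raa(stats, clusters)
compute_raa <- function(stats, clusters, weights = NULL, scope = "genome",
                        min_members = 3) {
  validate_stats(stats)
  stats <- filter_scope(stats, scope)
  if (is.null(weights)) {
    weights <- weight_factors(stats, clusters, scope = scope,
                              min_members = min_members)
  }
  missing <- setdiff(unique(stats$sample_id), unique(weights$sample_id))
  if (length(missing) > 0) {
    abort(sprintf("no weight factor available for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- stats |>
    inner_join(weights |> select("sample_id", "scope", "weight_factor"),
               by = c("sample_id", "scope")) |>
    mutate(raa = .data$pp_percent / .data$weight_factor) |>
    select("sample_id", "reference_id", "scope", "pp_percent",
           "weight_factor", "raa")
  class(out) <- c("raa_tbl", class(out))
  out
}

#' Rank reference genomes by RAA
#'
#' Orders the references for each sample (or each cluster, averaging over
#' members) by decreasing RAA. The top-ranked reference indicates the
#' dominant subgenome. Near-ties, where two references differ by less than a
#' relative margin, are flagged rather than silently ordered.
#'
#' @param raa Output of [compute_raa()].
#' @param by `"sample"` or `"cluster"`.
#' @param clusters Required when `by = "cluster"`.
#' @param tie_margin Relative RAA difference below which consecutive ranks
#'   are flagged as tied (default 0.005, i.e. 0.5%).
#'
#' @return Tibble with columns the grouping id, `scope`, `reference_id`,
#'   `raa`, `rank`, `tied_with_next`.
#' @export
rank_references <- function(raa, by = c("sample", "cluster"), clusters = NULL,
                            tie_margin = 0.005) {
  by <- match.arg(by)
  if (dplyr::n_distinct(raa$reference_id) < 2) {
    abort("ranking requires at least two reference genomes")
  }
  if (by == "cluster") {
    if (is.null(clusters)) abort("`clusters` is required when by = \"cluster\"")
    raa <- raa |>
      inner_join(clusters, by = "sample_id") |>
      group_by(.data$cluster_label, .data$reference_id, .data$scope) |>
      summarise(raa = mean(.data$raa), .groups = "drop") |>
      rename(id = "cluster_label")
  } else {
    raa <- raa |> select(id = "sample_id", "reference_id", "scope", "raa")
  }
  raa |>
    group_by(.data$id, .data$scope) |>
    arrange(dplyr::desc(.data$raa), .data$reference_id, .by_group = TRUE) |>
    mutate(
      rank = dplyr::row_number(),
      tied_with_next = dplyr::coalesce(
        (.data$raa - dplyr::lead(.data$raa)) /
          pmax(.data$raa, .Machine$double.eps) < tie_margin, FALSE)
    ) |>
    ungroup()
}

filter_scope <- function(stats, scope) {
  if (identical(scope, "genome")) {
    stats |> filter(.data$scope == "genome")
  } else if (identical(scope, "chromosome")) {
    stats |> filter(.data$scope != "genome")
  } else {
    stats |> filter(.data$scope %in% !!scope)
  }
}
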