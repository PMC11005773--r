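#' Relative Coverage of paired depth tracks
#'
#' Normalizes the per-window depths of two subgenome tracks into the 0--2
#' Relative Coverage scale over homologous windows. For each chromosome of
#' the anchor reference, the normalizer \eqn{M_c} is the mean over mapped
#' windows of the combined per-copy depth \eqn{(d_{anchor}+d_{partner})/2};
#' each window's depths are divided by \eqn{M_c}. At total ploidy \eqn{p},
#' a window with \eqn{a} copies on the anchor then sits near
#' \eqn{r_{anchor} = 2a/p}: 2:1 dosage (AAB) gives \eqn{4/3} vs \eqn{2/3},
#' a full exchange gives 2 vs 0, and a balanced diploid gives 1 vs 1.
#' The track is produced for both anchor directions of the window map, so
#' that only windows conserved between the references are compared and the
#' differing chromosome lengths of the two references are both represented.
#'
#' @param depth1,depth2 Depth tracks ([window_median_depth()]) of the two
#'   references named in the window map's `ref1`/`ref2` grids.
#' @param map Window map from [build_window_map()] (or the simulator).
#' @param baseline `"chromosome"` (default) normalizes each chromosome by its
#'   own mean, which reads dosage within the chromosome and masks
#'   whole-chromosome total aneuploidy; `"genome"` uses one genome-wide mean.
#'
#' @return An `rc_tbl` tibble with columns `track_id`, `anchor`, `partner`,
#'   `chrom`, `start`, `end`, `partner_chrom`, `partner_start`, `partner_end`,
#'   `r_anchor`, `r_partner`, `m_c`; one row per mapped anchor window and
#'   direction.
#' @export
relative_coverage <- function(depth1, depth2, map,
                              baseline = c("chromosome", "genome")) {
  baseline <- match.arg(baseline)
  ref1 <- unique(depth1$reference_id)
  ref2 <- unique(depth2$reference_id)
  stopifnot(length(ref1) == 1L, length(ref2) == 1L)
  one <- rc_one_anchor(depth1, depth2,
                       map |> filter(.data$direction == "ref1_to_ref2"),
                       ref1, ref2, baseline)
  two <- rc_one_anchor(depth2, depth1,
                       map |> filter(.data$direction == "ref2_to_ref1") |>
                         rename(ref1_chrom = "ref2_chrom", ref1_start = "ref2_start",
                                ref1_end = "ref2_end", ref2_chrom = "ref1_chrom",
                                ref2_start = "ref1_start", ref2_end = "ref1_end") |>
                         mutate(direction = "ref1_to_ref2"),
                       ref2, ref1, baseline)
  out <- bind_rows(one, two)
  class(out) <- c("rc_tbl", class(out))
  out
}

rc_one_anchor <- function(depth_anchor, depth_partner, dirmap,
                          anchor, partner, baseline) {
  track <- unique(depth_anchor$track_id)
  paired <- dirmap |>
    filter(!is.na(.data$ref2_chrom)) |>
    inner_join(depth_anchor |>
                 select(chrom = "chrom", start = "start", end = "end",
                        d_anchor = "median_depth"),
               by = c("ref1_chrom" = "chrom", "ref1_start" = "start",
                      "ref1_end" = "end")) |>
    inner_join(depth_partner |>
                 select(chrom = "chrom", start = "start", end = "end",
                        d_partner = "median_depth"),
               by = c("ref2_chrom" = "chrom", "ref2_start" = "start",
                      "ref2_end" = "end"))
  empty_chroms <- setdiff(setdiff(unique(dirmap$ref1_chrom), NA),
                          unique(paired$ref1_chrom))
  if (length(empty_chroms) > 0) {
    warn(sprintf("chromosome(s) with no mapped windows skipped (anchor %s): %s",
                 anchor, paste(empty_chroms, collapse = ", ")))
  }
  grouped <- if (baseline == "chromosome") {
    paired |> group_by(.data$ref1_chrom)
  } else {
    paired |> group_by(grp = 1L)
  }
  out <- grouped |>
    mutate(m_c = mean((.data$d_anchor + .data$d_partner) / 2)) |>
    ungroup()
  if (any(out$m_c == 0)) {
    abort(sprintf("zero mean coverage on chromosome %s (anchor %s)",
                  out$ref1_chrom[which(out$m_c == 0)[1]], anchor))
  }
  out |>
    mutate(
      track_id = track, anchor = anchor, partner = partner,
      r_anchor = .data$d_anchor / .data$m_c,
      r_partner = .data$d_partner / .data$m_c
    ) |>
    select("track_id", "anchor", "partner", chrom = "ref1_chrom",
           start = "ref1_start", end = "ref1_end",
           partner_chrom = "ref2_chrom", partner_start = "ref2_start",
           partner_end = "ref2_end", "r_anchor", "r_partner", "m_c") |>
    arrange(.data$chrom, .data$start)
}

#' Estimate the cross-mapping background rate
#'
#' In regions conserved between the two references, aligners place a read's
#' copies arbitrarily, so a low "background" depth appears on the subgenome
#' a region does not belong to. This estimates that rate \eqn{\beta} from
#' windows of pure composition (all copies on one subgenome), where the
#' expected Relative Coverage of the minor side is exactly \eqn{2\beta}:
#' starting from \eqn{\beta = 0}, windows are dosage-classified, \eqn{\beta}
#' is re-estimated as half the median minor-side Relative Coverage over pure
#' windows, and the two steps alternate until convergence.
#'
#' @param rc Relative Coverage track from [relative_coverage()] (one anchor
#'   direction is sufficient; the anchor appearing first is used).
#' @param p Total ploidy.
#' @param fallback Background rate returned (with a warning) when no pure
#'   windows are found.
#' @param tol,max_iter Convergence tolerance on \eqn{\beta} (default 1e-4)
#'   and iteration cap (default 10).
#'
#' @return An object of class `subgenome_background` with elements `beta`,
#'   `iterations`, `converged`, `n_pure_windows`, `from_fallback`.
#'   Supports [generics::tidy()] and [generics::glance()].
#' @export
estimate_background <- function(rc, p, fallback = 0, tol = 1e-4, max_iter = 10) {
  rc1 <- rc |> filter(.data$anchor == .data$anchor[1])
  beta <- 0
  iter <- 0L
  converged <- FALSE
  n_pure <- 0L
  repeat {
    iter <- iter + 1L
    calls <- classify_dosage(rc1, p = p, background = beta)
    pure <- calls |> filter(.data$a_hat %in% c(0L, p))
    n_pure <- nrow(pure)
    if (n_pure == 0L) {
      warn("no pure-composition windows found; returning the fallback background rate")
      return(new_background(fallback, iter, FALSE, 0L, TRUE))
    }
    minor <- ifelse(pure$a_hat == p, pure$r_partner, pure$r_anchor)
    beta_new <- min(max(median(minor) / 2, 0), 0.499)
    if (abs(beta_new - beta) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (iter >= max_iter) break
  }
  new_background(beta, iter, converged, n_pure, FALSE)
}

new_background <- function(beta, iterations, converged, n_pure, from_fallback) {
  structure(
    list(beta = beta, iterations = iterations, converged = converged,
         n_pure_windows = n_pure, from_fallback = from_fallback),
    class = "subgenome_background"
  )
}

#' @export
print.subgenome_background <- function(x, ...) {
  cat(sprintf(
    "Cross-mapping background model\n  beta: %.4f\n  iterations: %d (%s)\n  pure windows used: %d%s\n",
    x$beta, x$iterations, if (x$converged) "converged" else "not converged",
    x$n_pure_windows, if (x$from_fallback) " [fallback value]" else ""))
  invisible(x)
}

beta_value <- function(background) {
  if (inherits(background, "subgenome_background")) background$beta
  else as.numeric(background)
}

#' Classify per-window subgenome dosage
#'
#' Assigns each window the anchor-subgenome copy number \eqn{\hat a} whose
#' expected Relative Coverage under the background model,
#' \eqn{E[r_{anchor}] = 2(a(1-\beta) + (p-a)\beta)/p}, is nearest the
#' observed value; ties break toward the smaller copy number. Windows with
#' `r_anchor` beyond \eqn{2(1+tol)} are flagged anomalous but still
#' classified.
#'
#' @param rc Relative Coverage track.
#' @param p Total ploidy (e.g. 3 for a triploid AAB/ABB accession).
#' @param background A `subgenome_background` object or a numeric
#'   cross-mapping rate (default 0).
#' @param anomaly_tol Relative excess over 2 that flags a window (default 0.2).
#'
#' @return The input with added columns `p`, `a_hat`, `b_hat`, `composition`
#'   (anchor letter first, e.g. `"AAB"` for 2 anchor copies of 3),
#'   `residual`, `anomalous`.
#' @export
classify_dosage <- function(rc, p, background = 0, anomaly_tol = 0.2) {
  stopifnot(p >= 1)
  beta <- beta_value(background)
  levels <- 2 * ((0:p) * (1 - beta) + (p - (0:p)) * beta) / p
  a_hat <- vapply(rc$r_anchor, function(r) {
    d <- abs(r - levels)
    # ties (to within fp noise) break toward the smaller copy number
    which(d <= min(d) + 1e-9)[1] - 1L
  }, integer(1))
  out <- rc |>
    mutate(
      p = p,
      a_hat = a_hat,
      b_hat = p - a_hat,
      composition = composition_label(a_hat, p, first_letter(.data$anchor),
                                      first_letter(.data$partner)),
      residual = .data$r_anchor - levels[a_hat + 1L],
      anomalous = .data$r_anchor > 2 * (1 + anomaly_tol)
    )
  class(out) <- unique(c("dosage_tbl", class(out)))
  out
}

#' Background-correct a Relative Coverage track
#'
#' Inverts the cross-mapping mixture: observed values are
#' \eqn{r_{anchor} = (1-\beta) t_{anchor} + \beta t_{partner}} (and
#' symmetrically), so the underlying signals are recovered as
#' \eqn{t_{anchor} = ((1-\beta) r_{anchor} - \beta r_{partner})/(1-2\beta)}.
#' On a pure partner chromosome this subtracts exactly the expected
#' background \eqn{2\beta} from the anchor side.
#'
#' @inheritParams classify_dosage
#' @return The input with `r_anchor`/`r_partner` replaced by corrected values.
#' @export
correct_background <- function(rc, background) {
  beta <- beta_value(background)
  stopifnot(beta >= 0, beta < 0.5)
  ra <- rc$r_anchor
  rp <- rc$r_partner
  rc |>
    mutate(
      r_anchor = ((1 - beta) * ra - beta * rp) / (1 - 2 * beta),
      r_partner = ((1 - beta) * rp - beta * ra) / (1 - 2 * beta)
    )
}

#' Segment dosage calls into introgression segments
#'
#' Smooths per-window copy-number calls with a centred rolling majority
#' vote, run-length encodes the smoothed calls along each chromosome, and
#' reports contiguous runs whose composition differs from the accession's
#' modal (genome-wide most common) composition. Runs covering at least
#' `whole_frac` of a chromosome's mapped windows are flagged as
#' whole-chromosome exchanges.
#'
#' @param calls Output of [classify_dosage()] (one anchor direction).
#' @param min_windows Minimum run length reported (default 5 windows).
#' @param smooth_k Rolling-majority width in windows (default 5).
#' @param modal_a Copy number regarded as the accession's baseline. The
#'   default estimates it from the genome-wide mean Relative Coverage,
#'   `round(p * mean(r_anchor) / 2)`, which is robust to per-window
#'   classification noise at low depth; set it explicitly (e.g. to the
#'   per-window modal call) for heavily rearranged genomes where no single
#'   composition dominates the mean.
#' @param whole_frac Fraction of a chromosome's mapped windows above which a
#'   segment is a whole-chromosome exchange (default 0.95).
#'
#' @return Tibble of segments: `track_id`, `anchor`, `chrom`, `start`, `end`
#'   (bp on the anchor reference, 0-based half-open), `composition`,
#'   `n_windows`, `mean_r_anchor`, `whole_chromosome`.
#' @export
segment_calls <- function(calls, min_windows = 5, smooth_k = 5,
                          modal_a = NULL, whole_frac = 0.95) {
  stopifnot(length(unique(calls$anchor)) == 1L)
  p <- calls$p[1]
  if (is.null(modal_a)) {
    modal_a <- max(0L, min(p, as.integer(round(p * mean(calls$r_anchor) / 2))))
  }
  empty <- tibble(
    track_id = character(), anchor = character(), chrom = character(),
    start = numeric(), end = numeric(), composition = character(),
    n_windows = integer(), mean_r_anchor = numeric(),
    whole_chromosome = logical()
  )
  out <- calls |>
    group_by(.data$track_id, .data$anchor, .data$partner, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      sm <- as.integer(rolling_mode(g$a_hat, smooth_k))
      runs <- rle(sm)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      seg <- tibble(
        a = runs$values, first = starts, last = ends,
        n_windows = runs$lengths
      ) |>
        filter(.data$a != modal_a, .data$n_windows >= min_windows)
      if (nrow(seg) == 0L) return(tibble())
      tibble(
        start = g$start[seg$first],
        end = g$end[seg$last],
        composition = composition_label(seg$a, p, first_letter(key$anchor),
                                        first_letter(key$partner)),
        n_windows = seg$n_windows,
        mean_r_anchor = vapply(seq_len(nrow(seg)), function(i) {
          mean(g$r_anchor[seg$first[i]:seg$last[i]])
        }, numeric(1)),
        whole_chromosome = seg$n_windows >= whole_frac * nrow(g)
      )
    }) |>
    ungroup()
  if (nrow(out) == 0L) return(empty)
  out |>
    select("track_id", "anchor", "chrom", "start", "end", "composition",
           "n_windows", "mean_r_anchor", "whole_chromosome")
}

#' Per-chromosome coverage ratio summary
#'
#' Summarizes each chromosome of a Relative Coverage track as the ratio of
#' mean anchor to mean partner Relative Coverage over mapped windows. A
#' chromosome carrying an introgression from the partner genome shows a
#' depressed ratio relative to the other chromosomes.
#'
#' @param rc Relative Coverage track.
#' @return Tibble: `track_id`, `anchor`, `partner`, `chrom`,
#'   `mean_r_anchor`, `mean_r_partner`, `ratio` (`Inf` when the partner mean
#'   is zero).
#' @export
chromosome_ratio_table <- function(rc) {
  rc |>
    group_by(.data$track_id, .data$anchor, .data$partner, .data$chrom) |>
    summarise(
      mean_r_anchor = mean(.data$r_anchor),
      mean_r_partner = mean(.data$r_partner),
      .groups = "drop"
    ) |>
    mutate(ratio = ifelse(.data$mean_r_partner == 0, Inf,
                          .data$mean_r_anchor / .data$mean_r_partner))
}

#' Write introgression segments as BED6
#'
#' Emits segments in BED6 (0-based half-open; name = composition,
#' score = window count, strand = ".").
#'
#' @param segments Output of [segment_calls()].
#' @param path File path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- segments |>
    mutate(score = pmin(.data$n_windows, 1000), strand = ".") |>
    select("chrom", "start", "end", name = "composition", "score", "strand")
  writeLines("# introgression segments; BED6, 0-based half-open", path)
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE, progress = FALSE)
  invisible(path)
}
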