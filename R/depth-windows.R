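#' Extract uniquely-mapped, properly-paired primary alignments from a BAM
#'
#' Applies the read filters used before depth computation on a concatenated
#' subgenome reference: keep primary (not secondary/supplementary),
#' properly-paired, non-duplicate, mapped records, and drop any record
#' carrying an `XA` (alternative hit) or `SA` (chimeric/supplementary) tag,
#' so that only uniquely mapped reads contribute to coverage.
#'
#' @param bam Path to a BAM file aligned to the concatenated reference pair.
#' @return Tibble of retained records with columns `chrom`, `start`, `end`
#'   (0-based half-open reference span of the alignment, CIGAR-aware).
#' @export
filter_alignments <- function(bam) {
  flag <- Rsamtools::scanBamFlag(
    isProperPair = TRUE, isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE, isSupplementaryAlignment = FALSE,
    isDuplicate = FALSE
  )
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar"), tag = c("XA", "SA"), flag = flag))[[1]]
  keep <- is.na(res$tag$XA %||% rep(NA, length(res$pos))) &
    is.na(res$tag$SA %||% rep(NA, length(res$pos)))
  width <- cigar_ref_width(res$cigar[keep])
  tibble(
    chrom = as.character(res$rname)[keep],
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + width
  )
}

#' Per-window median read depth
#'
#' Computes, for every window of a grid, the median of per-position read
#' depth. Positions with zero coverage are included in the median, so a
#' deleted or absent region scores 0 rather than being skipped; the median
#' (rather than the mean) makes the track robust to coverage peaks over
#' repetitive sequence.
#'
#' @param x One of: a BAM path (filtered with [filter_alignments()]); a
#'   tibble of read spans with columns `chrom`, `start`, `end` (0-based
#'   half-open); or a BEDGraph-style tibble with columns `chrom`, `start`,
#'   `end`, `depth` giving per-interval depth (gaps are taken as depth 0).
#' @param grid Window grid from [window_grid()]; must cover every chromosome
#'   present in `x`.
#' @param track_id Identifier recorded on the output rows.
#'
#' @return A depth-track tibble: `track_id`, `reference_id`, `chrom`,
#'   `start`, `end`, `median_depth`, one row per grid window.
#' @export
window_median_depth <- function(x, grid, track_id = "sample") {
  validate_grid(grid)
  if (is.character(x) && length(x) == 1L) {
    x <- filter_alignments(x)
  }
  stopifnot(is.data.frame(x))
  is_bedgraph <- "depth" %in% names(x)
  extra <- setdiff(unique(x$chrom), unique(grid$chrom))
  if (length(extra) > 0) {
    abort(sprintf("chromosome(s) absent from the window grid: %s",
                  paste(extra, collapse = ", ")))
  }
  grid |>
    group_by(.data$reference_id, .data$chrom) |>
    dplyr::group_modify(function(g, key) {
      chrom_len <- max(g$end)
      on_ch <- x |> filter(.data$chrom == key$chrom)
      if (is_bedgraph) {
        runs <- bedgraph_runs(on_ch, chrom_len)
      } else {
        runs <- coverage_runs(on_ch, chrom_len)
      }
      g$median_depth <- vapply(seq_len(nrow(g)), function(i) {
        window_median_from_runs(runs, g$start[i], g$end[i])
      }, numeric(1))
      g
    }) |>
    ungroup() |>
    mutate(track_id = track_id) |>
    select("track_id", "reference_id", "chrom", "start", "end", "median_depth")
}

# Depth runs (0-based half-open tibble start/end/depth covering [0, len))
# from read spans, via an IRanges coverage pile.
coverage_runs <- function(reads, chrom_len) {
  if (nrow(reads) == 0L) {
    return(tibble(start = 0, end = chrom_len, depth = 0))
  }
  ir <- IRanges::IRanges(start = reads$start + 1L,
                         end = pmin(reads$end, chrom_len))
  cov <- IRanges::coverage(ir, width = chrom_len)
  tibble(
    start = cumsum(c(0, S4Vectors::runLength(cov)))[seq_along(S4Vectors::runLength(cov))],
    end = cumsum(S4Vectors::runLength(cov)),
    depth = as.numeric(S4Vectors::runValue(cov))
  )
}

# Fill gaps in a BEDGraph with zero-depth runs.
bedgraph_runs <- function(bg, chrom_len) {
  bg <- bg |> arrange(.data$start)
  if (nrow(bg) > 1 && any(bg$start[-1] < bg$end[-nrow(bg)])) {
    abort("BEDGraph intervals overlap")
  }
  starts <- c(bg$start, chrom_len)
  gap_start <- c(0, bg$end)
  gaps <- tibble(start = gap_start, end = starts, depth = 0) |>
    filter(.data$end > .data$start)
  bind_rows(bg |> select("start", "end", "depth"), gaps) |>
    arrange(.data$start)
}

window_median_from_runs <- function(runs, wstart, wend) {
  ov_start <- pmax(runs$start, wstart)
  ov_end <- pmin(runs$end, wend)
  w <- ov_end - ov_start
  weighted_median(runs$depth, pmax(w, 0))
}

#' Pool depth tracks window-wise
#'
#' Sums the per-window depths of several tracks sharing one grid. This is the
#' track-level analogue of merging the BAM files of a clonal group's
#' accessions before computing depth: summed medians approximate the merged
#' pile's depth and boost the signal-to-noise of low-coverage accessions.
#'
#' @param tracks List of depth-track tibbles on identical grids.
#' @param pool_id Identifier for the pooled track.
#' @return A depth-track tibble with `track_id = pool_id`.
#' @export
pool_tracks <- function(tracks, pool_id = "pool") {
  stopifnot(length(tracks) >= 1)
  key <- function(t) t |> select("reference_id", "chrom", "start", "end") |>
    arrange(.data$reference_id, .data$chrom, .data$start)
  ref <- key(tracks[[1]])
  for (t in tracks[-1]) {
    if (!identical(as.data.frame(key(t)), as.data.frame(ref))) {
      abort("depth tracks are on different window grids; cannot pool")
    }
  }
  bind_rows(tracks) |>
    group_by(.data$reference_id, .data$chrom, .data$start, .data$end) |>
    summarise(median_depth = sum(.data$median_depth), .groups = "drop") |>
    mutate(track_id = pool_id) |>
    select("track_id", "reference_id", "chrom", "start", "end", "median_depth") |>
    arrange(.data$reference_id, .data$chrom, .data$start)
}

#' Read or write a depth track TSV
#'
#' @param track Depth-track tibble.
#' @param path File path.
#' @export
write_depth_track <- function(track, path) {
  writeLines("# per-window median depth; coordinates 0-based half-open", path)
  readr::write_tsv(track, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_depth_track
#' @export
read_depth_track <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
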