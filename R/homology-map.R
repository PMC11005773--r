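#' Parse a PAF whole-genome alignment file
#'
#' Reads the 12 mandatory PAF columns produced by whole-genome aligners.
#' Coordinates are 0-based half-open; on the `-` strand the query interval
#' aligns to the reverse complement of the target interval.
#'
#' @param path Path to a PAF file.
#' @return Tibble of alignment blocks: `qname`, `qlen`, `qstart`, `qend`,
#'   `strand`, `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`.
#' @export
parse_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 12L)
  if (length(short) > 0) {
    abort(sprintf("malformed PAF line %d in '%s': fewer than 12 fields",
                  short[1], path))
  }
  num <- function(i, line) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), i)))
    if (anyNA(v)) abort(sprintf("malformed PAF line %d in '%s': non-numeric field %d",
                                which(is.na(v))[1], path, i))
    v
  }
  out <- tibble(
    qname = vapply(fields, `[[`, character(1), 1),
    qlen = num(2), qstart = num(3), qend = num(4),
    strand = vapply(fields, `[[`, character(1), 5),
    tname = vapply(fields, `[[`, character(1), 6),
    tlen = num(7), tstart = num(8), tend = num(9),
    nmatch = num(10), alen = num(11), mapq = num(12)
  )
  bad <- which(!out$strand %in% c("+", "-") | out$qend <= out$qstart |
                 out$tend <= out$tstart)
  if (length(bad) > 0) {
    abort(sprintf("malformed PAF line %d in '%s': invalid strand or interval",
                  bad[1], path))
  }
  out
}

#' Pair windows between two references from alignment blocks
#'
#' For every window of the first grid, accumulates the number of aligned
#' bases falling into each candidate window of the second grid over all
#' alignment blocks (assuming linear base correspondence within a block,
#' reversed on `-` strand blocks), assigns the candidate with the largest
#' aligned overlap, and marks windows whose best overlap is below
#' `min_frac` of the window size as unmapped. The procedure is repeated in
#' the opposite direction, so depth comparisons can be restricted to regions
#' conserved between the references from either reference's point of view.
#' Strand is not recorded: read depth is strand-symmetric.
#'
#' @param blocks Alignment blocks from [parse_paf()], with `qname` chromosomes
#'   belonging to `grid1`'s reference and `tname` to `grid2`'s.
#' @param grid1,grid2 Window grids ([window_grid()]) of the two references.
#' @param min_frac Minimum aligned fraction of the window for a mapping to be
#'   retained (default 0.2).
#'
#' @return A window-map tibble: `direction` (`"ref1_to_ref2"` /
#'   `"ref2_to_ref1"`), `ref1_chrom`, `ref1_start`, `ref1_end`, `ref2_chrom`,
#'   `ref2_start`, `ref2_end`, `aligned_bases`. Every grid window of the
#'   direction's anchor appears exactly once; unmapped windows carry `NA`
#'   partner coordinates and `aligned_bases = 0`.
#' @export
build_window_map <- function(blocks, grid1, grid2, min_frac = 0.2) {
  validate_grid(grid1); validate_grid(grid2)
  fwd <- map_one_direction(blocks, grid1, grid2, min_frac, "ref1_to_ref2")
  swapped <- blocks |>
    rename(qname = "tname", qlen = "tlen", qstart = "tstart", qend = "tend",
           tname = "qname", tlen = "qlen", tstart = "qstart", tend = "qend")
  rev <- map_one_direction(swapped, grid2, grid1, min_frac, "ref2_to_ref1") |>
    rename(ref1_chrom = "ref2_chrom", ref1_start = "ref2_start",
           ref1_end = "ref2_end", ref2_chrom = "ref1_chrom",
           ref2_start = "ref1_start", ref2_end = "ref1_end") |>
    select("direction", "ref1_chrom", "ref1_start", "ref1_end",
           "ref2_chrom", "ref2_start", "ref2_end", "aligned_bases")
  bind_rows(fwd, rev)
}

# Overlap accumulation for one direction: anchor grid = query side.
map_one_direction <- function(blocks, anchor_grid, partner_grid, min_frac, label) {
  pieces <- purrr::pmap_dfr(blocks, function(qname, qlen, qstart, qend, strand,
                                             tname, tlen, tstart, tend, ...) {
    qw <- anchor_grid |> filter(.data$chrom == qname)
    tw <- partner_grid |> filter(.data$chrom == tname)
    if (nrow(qw) == 0L || nrow(tw) == 0L) return(NULL)
    s <- (tend - tstart) / (qend - qstart)
    # target coordinate of query position q (continuous, half-open)
    t_of_q <- if (strand == "+") function(q) tstart + (q - qstart) * s
              else function(q) tend - (q - qstart) * s
    q_of_t <- if (strand == "+") function(t) qstart + (t - tstart) / s
              else function(t) qstart + (tend - t) / s
    # breakpoints: window boundaries on both sides, expressed in query space
    qb <- unique(c(qw$start, qw$end))
    tb <- unique(c(tw$start, tw$end))
    breaks <- sort(unique(c(qstart, qend,
                            qb[qb > qstart & qb < qend],
                            q_of_t(tb)[q_of_t(tb) > qstart & q_of_t(tb) < qend])))
    seg_start <- breaks[-length(breaks)]
    seg_end <- breaks[-1]
    mid <- (seg_start + seg_end) / 2
    tmid <- t_of_q(mid)
    qi <- findInterval(mid, qw$start)
    ti <- findInterval(tmid, tw$start)
    ok <- qi >= 1 & qi <= nrow(qw) & ti >= 1 & ti <= nrow(tw) &
      mid < max(qw$end) & tmid >= 0 & tmid < max(tw$end)
    tibble(
      ref1_chrom = qname,
      ref1_start = qw$start[qi[ok]], ref1_end = qw$end[qi[ok]],
      ref2_chrom = tname,
      ref2_start = tw$start[ti[ok]], ref2_end = tw$end[ti[ok]],
      bases = (seg_end - seg_start)[ok]
    )
  })
  votes <- if (nrow(pieces %||% tibble()) > 0) {
    pieces |>
      group_by(.data$ref1_chrom, .data$ref1_start, .data$ref1_end,
               .data$ref2_chrom, .data$ref2_start, .data$ref2_end) |>
      summarise(aligned_bases = sum(.data$bases), .groups = "drop")
  } else {
    tibble(ref1_chrom = character(), ref1_start = numeric(),
           ref1_end = numeric(), ref2_chrom = character(),
           ref2_start = numeric(), ref2_end = numeric(),
           aligned_bases = numeric())
  }
  best <- votes |>
    group_by(.data$ref1_chrom, .data$ref1_start, .data$ref1_end) |>
    arrange(dplyr::desc(.data$aligned_bases), .data$ref2_chrom,
            .data$ref2_start, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  anchor_grid |>
    select(ref1_chrom = "chrom", ref1_start = "start", ref1_end = "end") |>
    left_join(best, by = c("ref1_chrom", "ref1_start", "ref1_end")) |>
    mutate(
      aligned_bases = dplyr::coalesce(.data$aligned_bases, 0),
      unmapped = .data$aligned_bases < min_frac * (.data$ref1_end - .data$ref1_start),
      ref2_chrom = ifelse(.data$unmapped, NA_character_, .data$ref2_chrom),
      ref2_start = ifelse(.data$unmapped, NA_real_, .data$ref2_start),
      ref2_end = ifelse(.data$unmapped, NA_real_, .data$ref2_end),
      aligned_bases = ifelse(.data$unmapped, 0, .data$aligned_bases),
      direction = label
    ) |>
    select("direction", "ref1_chrom", "ref1_start", "ref1_end",
           "ref2_chrom", "ref2_start", "ref2_end", "aligned_bases")
}

#' Write / read a window map TSV
#' @param map Window-map tibble from [build_window_map()].
#' @param path File path.
#' @export
write_window_map <- function(map, path) {
  writeLines("# window homology map; coordinates 0-based half-open", path)
  readr::write_tsv(map, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_window_map
#' @export
read_window_map <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
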