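#' Build a fixed-size window grid over chromosomes
#'
#' Tiles each chromosome of a reference with non-overlapping windows of
#' `window_size` bp. Coordinates are 0-based half-open; the last window of a
#' chromosome is truncated at the chromosome end.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp, or a
#'   data frame with columns `chrom` and `length` (e.g. from [read_fai()]).
#' @param window_size Window width in bp (default 100000, i.e. 100 kb).
#' @param reference_id Label for the reference genome the grid belongs to.
#'
#' @return A tibble with columns `reference_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' window_grid(c(chr1 = 250000, chr2 = 120000), window_size = 1e5, reference_id = "A")
window_grid <- function(chrom_lengths, window_size = 100000, reference_id = "ref") {
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  stopifnot(window_size > 0, all(chrom_lengths > 0))
  purrr::imap_dfr(chrom_lengths, function(len, chrom) {
    starts <- seq(0, len - 1, by = window_size)
    tibble(
      reference_id = reference_id,
      chrom = chrom,
      start = starts,
      end = pmin(starts + window_size, len)
    )
  })
}

#' Read chromosome lengths from a FASTA index (.fai) file
#'
#' @param path Path to a samtools `.fai` index.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_fai <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "length", "offset", "linebases", "linewidth"),
    col_types = "cdddd", progress = FALSE
  ) |>
    select("chrom", "length")
}

validate_grid <- function(grid) {
  stopifnot(all(c("reference_id", "chrom", "start", "end") %in% names(grid)))
  bad <- grid$end <= grid$start | grid$start < 0
  if (any(bad)) abort("window grid contains empty or negative windows")
  invisible(grid)
}
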