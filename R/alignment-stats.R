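#' Parse a samtools flagstat report into alignment-statistics rows
#'
#' Extracts the total and properly-paired read counts from a flagstat-style
#' text report and derives the properly-paired percentage. When the report
#' carries a "primary" line (samtools >= 1.13), primary records are used as
#' the total, matching the convention that secondary and supplementary
#' alignments are excluded from `total_reads`.
#'
#' @param text Character vector of report lines, or a single string with
#'   embedded newlines, or a path to a report file.
#' @param sample_id,reference_id Identifiers recorded on the output row.
#'
#' @return A one-row alignment-statistics tibble with columns `sample_id`,
#'   `reference_id`, `scope` (`"genome"`), `total_reads`, `properly_paired`,
#'   `pp_percent`. `pp_percent` is 0 (with a warning) when the report has
#'   zero reads.
#' @export
#' @examples
#' rpt <- c("1000 + 0 in total (QC-passed reads + QC-failed reads)",
#'          "818 + 0 properly paired (81.80% : N/A)")
#' parse_flagstat(rpt, "S1", "A")
parse_flagstat <- function(text, sample_id, reference_id) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  grab <- function(pattern) {
    hit <- grep(pattern, lines, value = TRUE)
    if (length(hit) == 0L) return(NA_real_)
    as.numeric(sub("^(\\d+) \\+ (\\d+).*$", "\\1", hit[1L])) +
      as.numeric(sub("^(\\d+) \\+ (\\d+).*$", "\\2", hit[1L]))
  }
  total <- grab("\\bprimary$")
  if (is.na(total)) total <- grab("in total")
  pp <- grab("properly paired")
  if (is.na(total)) abort("flagstat report is missing the 'in total' line")
  if (is.na(pp)) abort("flagstat report is missing the 'properly paired' line")
  if (pp > total) abort("properly paired count exceeds total reads")
  if (total == 0) {
    warn(sprintf("sample %s has zero reads against %s; pp_percent set to 0",
                 sample_id, reference_id))
  }
  tibble(
    sample_id = sample_id, reference_id = reference_id, scope = "genome",
    total_reads = total, properly_paired = pp,
    pp_percent = if (total > 0) 100 * pp / total else 0
  )
}

#' Compute alignment statistics from a BAM file
#'
#' Counts primary records and properly-paired primary records for the whole
#' genome and, optionally, per chromosome. Secondary (0x100) and
#' supplementary (0x800) records are excluded from all counts; reads on
#' sequences outside `chromosomes` (e.g. unplaced scaffolds) and unmapped
#' reads contribute to the genome scope only.
#'
#' @param bam Path to a BAM file.
#' @param sample_id,reference_id Identifiers recorded on the output rows.
#' @param chromosomes Chromosome names for per-chromosome rows; defaults to
#'   all sequences in the BAM header. Use `NULL` to emit the genome row only.
#'
#' @return An alignment-statistics tibble with one genome-scope row and one
#'   row per chromosome.
#' @export
stats_from_bam <- function(bam, sample_id, reference_id,
                           chromosomes = names(Rsamtools::scanBamHeader(bam)[[1]]$targets)) {
  res <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("rname", "flag")))[[1]]
  if (length(res$flag) == 0L) abort(sprintf("BAM file '%s' contains no records", bam))
  primary <- bitwAnd(res$flag, 0x100) == 0L & bitwAnd(res$flag, 0x800) == 0L
  flag <- res$flag[primary]
  rname <- as.character(res$rname)[primary]
  pp <- bitwAnd(flag, 0x2) > 0L
  genome <- tibble(
    sample_id = sample_id, reference_id = reference_id, scope = "genome",
    total_reads = length(flag), properly_paired = sum(pp),
    pp_percent = if (length(flag) > 0) 100 * sum(pp) / length(flag) else 0
  )
  per_chrom <- purrr::map_dfr(chromosomes, function(ch) {
    on_ch <- !is.na(rname) & rname == ch
    tot <- sum(on_ch)
    tibble(
      sample_id = sample_id, reference_id = reference_id, scope = ch,
      total_reads = tot, properly_paired = sum(pp[on_ch]),
      pp_percent = if (tot > 0) 100 * sum(pp[on_ch]) / tot else 0
    )
  })
  bind_rows(genome, per_chrom)
}

stats_columns <- c("sample_id", "reference_id", "scope",
                   "total_reads", "properly_paired", "pp_percent")

#' Validate an alignment-statistics table
#'
#' Checks the structural invariants of an alignment-statistics tibble:
#' required columns present, `properly_paired <= total_reads`, unique
#' (sample, reference, scope) keys, and `pp_percent` consistent with the
#' counts (to the 4-decimal internal precision).
#'
#' @param stats An alignment-statistics tibble.
#' @param where Label used in error messages.
#' @return The input, invisibly; errors describe the first violation.
#' @export
validate_stats <- function(stats, where = "alignment statistics") {
  missing <- setdiff(stats_columns, names(stats))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing column(s): %s", where,
                  paste(missing, collapse = ", ")))
  }
  if (any(stats$properly_paired > stats$total_reads)) {
    abort(sprintf("%s: properly_paired exceeds total_reads", where))
  }
  dup <- stats |> dplyr::count(.data$sample_id, .data$reference_id, .data$scope) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (sample, reference, scope) key: %s/%s/%s",
                  dup$sample_id[1], dup$reference_id[1], dup$scope[1]))
  }
  nz <- stats$total_reads > 0
  expected <- 100 * stats$properly_paired[nz] / stats$total_reads[nz]
  off <- abs(stats$pp_percent[nz] - expected) > 5e-4 + 1e-8 * expected
  if (any(off)) {
    i <- which(nz)[which(off)[1]]
    abort(sprintf(
      "%s: pp_percent inconsistent with counts for %s/%s/%s (%.4f vs %.4f)",
      where, stats$sample_id[i], stats$reference_id[i], stats$scope[i],
      stats$pp_percent[i], expected[which(off)[1]]))
  }
  invisible(stats)
}

#' Serialize / read an alignment-statistics table as TSV
#'
#' The writer emits a commented header documenting the counting convention
#' (primary records only) and the coordinate conventions used across the
#' package; the reader skips comment lines, validates the table invariants
#' (counts consistent with `pp_percent`, unique keys) and preserves any extra
#' columns untouched.
#'
#' @param stats An alignment-statistics tibble (see [parse_flagstat()]).
#' @param path File path.
#' @return `write_stats()` returns `path` invisibly; `read_stats()` returns
#'   the validated tibble.
#' @export
write_stats <- function(stats, path) {
  validate_stats(stats)
  header <- c(
    "# alignment statistics: total_reads counts primary records only",
    "# (secondary/supplementary excluded); unplaced reads in genome scope only"
  )
  writeLines(header, path)
  readr::write_tsv(stats, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_stats
#' @export
read_stats <- function(path) {
  stats <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
  probs <- readr::problems(stats)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed stats TSV '%s' at line %d: %s",
                  path, probs$row[1], probs$expected[1]))
  }
  validate_stats(stats, where = sprintf("stats TSV '%s'", path))
  stats
}
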