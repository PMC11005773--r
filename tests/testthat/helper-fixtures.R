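# Fixture builders shared across test files. Everything is generated in code;
# BAMs are written as SAM text and converted with Rsamtools::asBam.

# records: tibble(qname, flag, chrom, pos (1-based), cigar, xa, sa)
# chrom_lengths: named vector
make_test_bam <- function(records, chrom_lengths, dir = tempdir()) {
  sam <- file.path(dir, paste0("test_", as.integer(stats::runif(1, 1, 1e8)), ".sam"))
  ord <- order(match(records$chrom, c(names(chrom_lengths), "*")), records$pos)
  records <- records[ord, ]
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths), as.integer(chrom_lengths))
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    qlen <- sum(as.integer(
      regmatches(r$cigar, gregexpr("\\d+(?=[MIS=X])", r$cigar, perl = TRUE))[[1]]
    ))
    if (is.na(qlen) || qlen == 0) qlen <- 10L
    line <- paste(r$qname, r$flag, r$chrom, r$pos, 60, r$cigar, "*", 0, 0,
                  strrep("A", qlen), strrep("I", qlen), sep = "\t")
    if (!is.na(r$xa)) line <- paste0(line, "\tXA:Z:", r$xa)
    if (!is.na(r$sa)) line <- paste0(line, "\tSA:Z:", r$sa)
    line
  }, character(1))
  # records on "*" (unplaced) must come last and use pos 0
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam),
                          overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

# A default mixed-flag record set with known counts, used by several tests.
default_records <- function() {
  tibble::tibble(
    qname = sprintf("r%02d", 1:11),
    flag = c(
      99L,   # proper pair, mapped, primary
      147L,  # proper pair, mate of above
      99L,   # proper pair + XA tag (set below)
      83L,   # proper pair, reverse
      163L,  # proper pair + SA tag
      97L,   # paired, NOT proper
      99L + 1024L,  # proper pair but duplicate
      355L,  # proper pair but secondary (256)
      2147L, # supplementary (2048) + proper
      65L,   # paired, not proper
      77L    # paired, read + mate unmapped (unplaced)
    ),
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrB", "chrC", "chrC",
              "chrC", "chrA", "*"),
    pos = c(1L, 51L, 101L, 11L, 61L, 111L, 21L, 71L, 121L, 151L, 0L),
    cigar = c(rep("10M", 10), "*"),
    xa = c(NA, NA, "chrB,+100,10M,0;", NA, NA, NA, NA, NA, NA, NA, NA),
    sa = c(NA, NA, NA, NA, "chrA,200,+,10M,60,0;", NA, NA, NA, NA, NA, NA)
  )
}

test_chrom_lengths <- c(chrA = 400L, chrB = 400L, chrC = 400L)

# Per-position depth oracle: expand read spans (0-based half-open) to a
# per-position pile and take stats::median per window.
oracle_window_medians <- function(reads, grid) {
  vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    pos <- seq(g$start, g$end - 1)
    depth <- vapply(pos, function(p) {
      sum(reads$chrom == g$chrom & reads$start <= p & reads$end > p)
    }, numeric(1))
    stats::median(depth)
  }, numeric(1))
}

# Per-base majority-vote oracle for window mapping (equal-length blocks).
oracle_window_map <- function(blocks, grid1, grid2, min_frac = 0.2) {
  votes <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    stopifnot(b$qend - b$qstart == b$tend - b$tstart)
    for (q in seq(b$qstart, b$qend - 1)) {
      t <- if (b$strand == "+") b$tstart + (q - b$qstart) else
        b$tend - 1 - (q - b$qstart)
      w1 <- grid1[grid1$chrom == b$qname & grid1$start <= q & grid1$end > q, ]
      w2 <- grid2[grid2$chrom == b$tname & grid2$start <= t & grid2$end > t, ]
      if (nrow(w1) == 1 && nrow(w2) == 1) {
        key <- paste(w1$chrom, w1$start, w2$chrom, w2$start, sep = "|")
        votes[[key]] <- (votes[[key]] %||% 0) + 1
      }
    }
  }
  if (length(votes) == 0) return(tibble::tibble())
  df <- tibble::tibble(key = names(votes), n = unlist(votes)) |>
    tidyr::separate_wider_delim("key", "|", names = c("ref1_chrom", "ref1_start",
                                                      "ref2_chrom", "ref2_start")) |>
    dplyr::mutate(dplyr::across(c("ref1_start", "ref2_start"), as.numeric))
  df |>
    dplyr::group_by(.data$ref1_chrom, .data$ref1_start) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$ref2_chrom, .data$ref2_start,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

`%||%` <- rlang::`%||%`
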