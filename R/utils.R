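#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows distinct n across rename relocate pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median rpois runif setNames
NULL

# Weighted median of run-length encoded values, matching stats::median() on
# the fully expanded vector (weights are integer position counts).
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  if (length(values) == 0L) return(NA_real_)
  o <- order(values)
  values <- values[o]
  weights <- weights[o]
  n <- sum(weights)
  cw <- cumsum(weights)
  k1 <- floor((n + 1) / 2)
  k2 <- ceiling((n + 1) / 2)
  v1 <- values[which(cw >= k1)[1L]]
  v2 <- values[which(cw >= k2)[1L]]
  (v1 + v2) / 2
}

# Mode of an integer/character vector; ties broken toward `prefer` when it is
# among the tied values, otherwise toward the smallest value.
stat_mode <- function(x, prefer = NULL) {
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if (!is.null(prefer) && as.character(prefer) %in% top) {
    out <- as.character(prefer)
  } else {
    out <- sort(top)[1L]
  }
  if (is.numeric(x)) as.numeric(out) else out
}

# Centred rolling-majority smoother over integer labels.
rolling_mode <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  h <- k %/% 2L
  vapply(seq_len(n), function(i) {
    win <- x[max(1L, i - h):min(n, i + h)]
    as.numeric(stat_mode(win, prefer = x[i]))
  }, numeric(1))
}

# Reference-space width of a CIGAR string (M, D, N, =, X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    type <- sub("^\\d+", "", ops)
    as.integer(sum(lens[type %in% c("M", "D", "N", "=", "X")]))
  }, integer(1), USE.NAMES = FALSE)
}

# Composition label: `a` copies of the anchor letter then `p - a` of the
# partner letter, e.g. a = 2, p = 3, letters A/B -> "AAB".
composition_label <- function(a, p, anchor_letter, partner_letter) {
  paste0(strrep(anchor_letter, a), strrep(partner_letter, p - a))
}

first_letter <- function(x) toupper(substr(x, 1L, 1L))
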