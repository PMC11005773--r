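#' Define a hybrid-genome depth simulation scenario
#'
#' Describes a clonal hybrid accession as a per-chromosome dosage mosaic over
#' two subgenomes, plus the sequencing model used to realize depth tracks:
#' per-copy depth, cross-mapping background rate and Poisson depth noise.
#' Defaults mirror a triploid AAB banana accession sequenced at about 7x
#' total depth over 11 chromosomes in 100-kb windows.
#'
#' @param n_chromosomes Number of chromosomes (default 11).
#' @param chromosome_length Chromosome length in bp (default 1e7, i.e. 100
#'   windows of 100 kb per chromosome).
#' @param window_size Window width in bp (default 100000).
#' @param ploidy Total ploidy `p` (default 3).
#' @param base_composition Genome-wide composition string of length `ploidy`
#'   using the two subgenome letters, e.g. `"AAB"`.
#' @param segments Tibble of dosage overrides with columns `chrom`
#'   (chromosome index), `start_window`, `end_window` (1-based inclusive
#'   window indices) and `composition`; overrides are applied in order.
#' @param per_copy_depth Expected depth contributed by one subgenome copy
#'   (default `7 / ploidy`, i.e. about 7x total accession depth).
#' @param beta Cross-mapping background rate in `[0, 0.5)` (default 0.03).
#' @param noise `"poisson"` (default) or `"none"`.
#' @param depth_mode `"proxy"` (default) draws each window's median-depth
#'   proxy as one Poisson variate; `"perbase"` draws per-position Poisson
#'   depths and takes the within-window median (slow; for cross-validation).
#' @param conserved_fraction Probability that a window is conserved between
#'   the references, hence present in the window map (default 0.95).
#' @param letters Subgenome letters, anchor first (default `c("A", "B")`).
#' @param track_id Track identifier (default `"sim"`).
#' @param seed Mandatory integer seed.
#'
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_chromosomes = 11, chromosome_length = 1e7,
                         window_size = 100000, ploidy = 3,
                         base_composition = "AAB", segments = NULL,
                         per_copy_depth = NULL, beta = 0.03,
                         noise = c("poisson", "none"),
                         depth_mode = c("proxy", "perbase"),
                         conserved_fraction = 0.95,
                         letters = c("A", "B"), track_id = "sim", seed) {
  if (missing(seed)) abort("a seed is mandatory for reproducible simulation")
  noise <- match.arg(noise)
  depth_mode <- match.arg(depth_mode)
  per_copy_depth <- per_copy_depth %||% (7 / ploidy)
  check_composition <- function(comp) {
    if (nchar(comp) != ploidy ||
        !all(strsplit(comp, "")[[1]] %in% letters)) {
      abort(sprintf("composition '%s' must have length %d over letters {%s}",
                    comp, ploidy, paste(letters, collapse = ", ")))
    }
  }
  check_composition(base_composition)
  segments <- segments %||%
    tibble(chrom = integer(), start_window = integer(),
           end_window = integer(), composition = character())
  purrr::walk(segments$composition, check_composition)
  structure(
    list(n_chromosomes = n_chromosomes, chromosome_length = chromosome_length,
         window_size = window_size, ploidy = ploidy,
         base_composition = base_composition, segments = segments,
         per_copy_depth = per_copy_depth, beta = beta, noise = noise,
         depth_mode = depth_mode, conserved_fraction = conserved_fraction,
         letters = letters, track_id = track_id, seed = seed),
    class = "sim_scenario"
  )
}

#' Named scenario presets for characteristic hybrid lineages
#'
#' Ready-made dosage mosaics modelled on well-described triploid banana
#' lineages: `"plantain_aab"` (AAB with a whole-chromosome ABB exchange on
#' chromosome 7 and five telomeric AAA introgressions on chromosomes 4, 6,
#' 8, 9 and 10), `"popoulu_aab"` (AAB with an ABB start of chromosome 7 and
#' a telomeric AAA end of chromosome 10), `"bluggoe_abb"` (ABB with interior
#' BBB and AAB introgressions), `"pelipita_abb"` (ABB with whole-chromosome
#' BBB exchanges on chromosomes 2, 7 and 11 plus interior introgressions)
#' and `"aaab_africa"` (tetraploid AAAB with an AABB chromosome 7).
#' Segment spans are expressed as fractions of the chromosome and scale with
#' the grid.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_scenario()] (e.g. `n_chromosomes`,
#'   `beta`, `per_copy_depth`, `seed`).
#' @return A `sim_scenario`.
#' @export
sim_preset <- function(name = c("plantain_aab", "popoulu_aab", "bluggoe_abb",
                                "pelipita_abb", "aaab_africa"), ...) {
  name <- match.arg(name)
  spec <- switch(name,
    plantain_aab = list(
      ploidy = 3, base = "AAB",
      segs = list(
        list(7, 0, 1, "ABB"),
        list(4, 0, 0.30, "AAA"), list(6, 0.85, 1, "AAA"),
        list(8, 0, 0.12, "AAA"), list(9, 0.82, 1, "AAA"),
        list(10, 0.90, 1, "AAA"))),
    popoulu_aab = list(
      ploidy = 3, base = "AAB",
      segs = list(list(7, 0, 0.25, "ABB"), list(10, 0.85, 1, "AAA"))),
    bluggoe_abb = list(
      ploidy = 3, base = "ABB",
      segs = list(
        list(4, 0.20, 0.35, "BBB"), list(11, 0.05, 0.18, "BBB"),
        list(11, 0.60, 0.75, "BBB"), list(4, 0.80, 0.92, "AAB"),
        list(9, 0.40, 0.52, "AAB"))),
    pelipita_abb = list(
      ploidy = 3, base = "ABB",
      segs = list(
        list(2, 0, 1, "BBB"), list(7, 0, 1, "BBB"), list(11, 0, 1, "BBB"),
        list(9, 0.10, 0.20, "AAB"), list(9, 0.70, 0.80, "AAB"),
        list(6, 0.30, 0.42, "BBB"), list(10, 0.50, 0.62, "BBB"))),
    aaab_africa = list(
      ploidy = 4, base = "AAAB",
      segs = list(list(7, 0, 1, "AABB")))
  )
  args <- list(...)
  args$ploidy <- args$ploidy %||% spec$ploidy
  args$base_composition <- args$base_composition %||% spec$base
  n_chrom <- args$n_chromosomes %||% 11
  chrom_len <- args$chromosome_length %||% 1e7
  wsize <- args$window_size %||% 100000
  n_win <- ceiling(chrom_len / wsize)
  segs <- purrr::map_dfr(spec$segs, function(s) {
    tibble(chrom = s[[1]],
           start_window = floor(s[[2]] * n_win) + 1L,
           end_window = ceiling(s[[3]] * n_win),
           composition = s[[4]])
  }) |>
    filter(.data$chrom <= n_chrom)
  args$segments <- args$segments %||% segs
  args$track_id <- args$track_id %||% name
  do.call(sim_scenario, args)
}

sim_chrom_names <- function(n) sprintf("chr%02d", seq_len(n))

# Per-window truth table (anchor copy number a) for a scenario.
scenario_truth <- function(scenario) {
  n_win <- ceiling(scenario$chromosome_length / scenario$window_size)
  anchor <- scenario$letters[1]
  count_a <- function(comp) sum(strsplit(comp, "")[[1]] == anchor)
  base_a <- count_a(scenario$base_composition)
  truth <- tidyr::expand_grid(
    chrom_idx = seq_len(scenario$n_chromosomes),
    window = seq_len(n_win)
  ) |>
    mutate(chrom = sim_chrom_names(scenario$n_chromosomes)[.data$chrom_idx],
           a = base_a, composition = scenario$base_composition)
  if (nrow(scenario$segments) > 0) {
    for (i in seq_len(nrow(scenario$segments))) {
      s <- scenario$segments[i, ]
      hit <- truth$chrom_idx == s$chrom &
        truth$window >= s$start_window & truth$window <= s$end_window
      truth$a[hit] <- count_a(s$composition)
      truth$composition[hit] <- s$composition
    }
  }
  truth |>
    mutate(
      start = (.data$window - 1) * scenario$window_size,
      end = pmin(.data$window * scenario$window_size,
                 scenario$chromosome_length),
      b = scenario$ploidy - .data$a
    ) |>
    select("chrom", "window", "start", "end", "a", "b", "composition")
}

#' Simulate a paired depth track for a hybrid accession
#'
#' Realizes per-window median depth tracks on both subgenome references for
#' a dosage-mosaic scenario. A window with `a` anchor copies of `p` total at
#' per-copy depth `u` has expected depths
#' \eqn{E[d_1] = u(a(1-\beta) + (p-a)\beta)} and symmetrically for the
#' partner: the background rate \eqn{\beta} moves reads from the subgenome
#' that owns them onto the homoeologous one without changing their sum.
#' Noise is Poisson on the window median proxy (or on per-position depths in
#' `"perbase"` mode). Also returns an identity-like window map in which a
#' `conserved_fraction` of windows are mapped, and the per-window and
#' per-segment truth tables used by recovery tests.
#'
#' @param scenario A [sim_scenario()] or [sim_preset()].
#' @return List with elements `depth1`, `depth2` (depth-track tibbles for
#'   the anchor and partner references), `map` (window map), `truth_windows`,
#'   `truth_segments`, `scenario`.
#' @export
simulate_depths <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::with_seed(scenario$seed, {
    truth <- scenario_truth(scenario)
    u <- scenario$per_copy_depth
    beta <- scenario$beta
    p <- scenario$ploidy
    e1 <- u * (truth$a * (1 - beta) + truth$b * beta)
    e2 <- u * (truth$b * (1 - beta) + truth$a * beta)
    draw <- function(e, width) {
      if (scenario$noise == "none") return(e)
      if (scenario$depth_mode == "proxy") return(rpois(length(e), e))
      vapply(seq_along(e), function(i) {
        median(rpois(width[i], e[i]))
      }, numeric(1))
    }
    width <- truth$end - truth$start
    d1 <- draw(e1, width)
    d2 <- draw(e2, width)
    conserved <- runif(nrow(truth)) < scenario$conserved_fraction
    mk_track <- function(d, ref) {
      tibble(track_id = scenario$track_id, reference_id = ref,
             chrom = truth$chrom, start = truth$start, end = truth$end,
             median_depth = as.numeric(d))
    }
    # column convention as in build_window_map: ref1_* always holds
    # reference-1 coordinates; the direction's anchor windows are ref1_* for
    # ref1_to_ref2 and ref2_* for ref2_to_ref1, partner side NA when unmapped
    map_dir <- function(label) {
      partner_na <- !conserved
      tibble(
        direction = label,
        ref1_chrom = if (label == "ref1_to_ref2") truth$chrom else
          ifelse(partner_na, NA_character_, truth$chrom),
        ref1_start = if (label == "ref1_to_ref2") truth$start else
          ifelse(partner_na, NA_real_, truth$start),
        ref1_end = if (label == "ref1_to_ref2") truth$end else
          ifelse(partner_na, NA_real_, truth$end),
        ref2_chrom = if (label == "ref2_to_ref1") truth$chrom else
          ifelse(partner_na, NA_character_, truth$chrom),
        ref2_start = if (label == "ref2_to_ref1") truth$start else
          ifelse(partner_na, NA_real_, truth$start),
        ref2_end = if (label == "ref2_to_ref1") truth$end else
          ifelse(partner_na, NA_real_, truth$end),
        aligned_bases = ifelse(conserved, truth$end - truth$start, 0)
      )
    }
    truth_segments <- truth |>
      group_by(.data$chrom) |>
      dplyr::group_modify(function(g, key) {
        runs <- rle(g$composition)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        tibble(start = g$start[starts], end = g$end[ends],
               composition = runs$values, n_windows = runs$lengths)
      }) |>
      ungroup() |>
      filter(.data$composition != scenario$base_composition)
    list(
      depth1 = mk_track(d1, scenario$letters[1]),
      depth2 = mk_track(d2, scenario$letters[2]),
      map = bind_rows(map_dir("ref1_to_ref2"), map_dir("ref2_to_ref1")),
      truth_windows = truth,
      truth_segments = truth_segments,
      scenario = scenario
    )
  })
}

#' Define a clustered alignment-statistics panel scenario
#'
#' Describes a panel of accessions grouped into varietal clusters, each
#' cluster with a characteristic properly-paired alignment profile per
#' reference genome, and each sample with a multiplicative quality effect.
#' Default profiles follow typical short-read alignment rates of an
#' A/B-hybrid banana panel against the A, B and S references (81.8, 70.9
#' and 76.0 percent).
#'
#' @param clusters Tibble with columns `cluster_label`, `n_samples`.
#' @param profiles Tibble with columns `cluster_label`, `reference_id`,
#'   `profile_pp` (percent in (0, 100]).
#' @param q_half_width Half-width of the sample quality multiplier spread
#'   around 1 (default 0.05, i.e. multipliers in 0.95--1.05).
#' @param q_dist `"uniform"` draws multipliers uniformly; `"even"` places
#'   them on an evenly spaced symmetric grid (mean exactly 1, deterministic).
#' @param noise_sd Additive noise on pp_percent, in percentage points
#'   (default 0).
#' @param total_reads Total read count used to back-fill integer counts from
#'   percentages (default 1e7).
#' @param seed Mandatory integer seed.
#' @return A `panel_scenario` list.
#' @export
panel_scenario <- function(clusters = tibble(cluster_label = "c1", n_samples = 5),
                           profiles = NULL, q_half_width = 0.05,
                           q_dist = c("uniform", "even"), noise_sd = 0,
                           total_reads = 1e7, seed) {
  if (missing(seed)) abort("a seed is mandatory for reproducible simulation")
  q_dist <- match.arg(q_dist)
  profiles <- profiles %||% tidyr::expand_grid(
    cluster_label = clusters$cluster_label,
    tibble(reference_id = c("A", "B", "S"),
           profile_pp = c(81.8, 70.9, 76.0))
  )
  stopifnot(all(profiles$profile_pp > 0), all(profiles$profile_pp <= 100))
  structure(
    list(clusters = clusters, profiles = profiles,
         q_half_width = q_half_width, q_dist = q_dist, noise_sd = noise_sd,
         total_reads = total_reads, seed = seed),
    class = "panel_scenario"
  )
}

#' Simulate an alignment-statistics panel
#'
#' Generates per-sample alignment statistics whose properly-paired
#' percentage is the sample's cluster profile times a per-sample quality
#' multiplier, plus optional additive noise; integer read counts are
#' back-filled from the percentages at the scenario's total read count.
#' Percentages that exceed 100 after perturbation are clipped with a
#' warning.
#'
#' @param panel A [panel_scenario()].
#' @return List with elements `stats` (alignment-statistics tibble),
#'   `clusters` (sample-to-cluster assignment) and `truth` (tibble of the
#'   injected quality multipliers `q` per sample).
#' @export
simulate_stats_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_scenario"))
  withr::with_seed(panel$seed, {
    samples <- purrr::pmap_dfr(panel$clusters, function(cluster_label, n_samples, ...) {
      tibble(cluster_label = cluster_label, member = seq_len(n_samples))
    }) |>
      mutate(sample_id = sprintf("%s_s%02d", .data$cluster_label, .data$member)) |>
      group_by(.data$cluster_label) |>
      mutate(q = if (panel$q_dist == "even") {
        if (n() == 1) 1 else seq(1 - panel$q_half_width, 1 + panel$q_half_width,
                                 length.out = n())
      } else {
        runif(n(), 1 - panel$q_half_width, 1 + panel$q_half_width)
      }) |>
      ungroup()
    stats <- samples |>
      inner_join(panel$profiles, by = "cluster_label",
                 relationship = "many-to-many") |>
      mutate(
        pp_raw = .data$q * .data$profile_pp +
          if (panel$noise_sd > 0) stats::rnorm(dplyr::n(), 0, panel$noise_sd) else 0
      )
    if (any(stats$pp_raw > 100)) {
      warn(sprintf("%d simulated pp_percent value(s) exceeded 100 and were clipped",
                   sum(stats$pp_raw > 100)))
    }
    stats <- stats |>
      mutate(
        pp_raw = pmin(pmax(.data$pp_raw, 0), 100),
        total_reads = panel$total_reads,
        properly_paired = round(panel$total_reads * .data$pp_raw / 100),
        pp_percent = 100 * .data$properly_paired / .data$total_reads,
        scope = "genome"
      ) |>
      select("sample_id", "reference_id", "scope", "total_reads",
             "properly_paired", "pp_percent")
    list(
      stats = stats,
      clusters = samples |> select("sample_id", "cluster_label"),
      truth = samples |> select("sample_id", "cluster_label", "q")
    )
  })
}

#' Simulate divergent subgenome sequences (and optional reads)
#'
#' Mutates one random ancestor sequence independently into two subgenomes at
#' a fixed substitution rate, enabling optional end-to-end runs through an
#' external aligner. With `n_read_pairs > 0`, single-position read pairs are
#' drawn from the hybrid's subgenome copies in proportion to the scenario's
#' base composition.
#'
#' @param scenario A [sim_scenario()]; `n_chromosomes` and
#'   `chromosome_length` define the sequences (use short chromosomes).
#' @param divergence Substitution rate per bp in `[0, 0.3]` applied
#'   independently to each subgenome branch.
#' @param n_read_pairs Number of read pairs to draw (default 0: none).
#' @param read_length,insert_size Read geometry for drawn pairs.
#' @param error_rate Per-base sequencing error rate on reads.
#' @param fasta_dir If non-`NULL`, FASTA files (and FASTQ when reads are
#'   drawn) are written there.
#' @return List with `genome1`, `genome2`
#'   ([Biostrings::DNAStringSet] objects) and, when requested, `reads` (a
#'   tibble with read sequences and their subgenome of origin).
#' @export
simulate_sequences <- function(scenario, divergence, n_read_pairs = 0,
                               read_length = 150, insert_size = 350,
                               error_rate = 0.001, fasta_dir = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.3)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(scenario$seed, {
    mutate_seq <- function(x, rate) {
      if (rate == 0) return(x)
      hit <- which(runif(length(x)) < rate)
      if (length(hit) > 0) {
        x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1),
                         character(1))
      }
      x
    }
    chroms <- sim_chrom_names(scenario$n_chromosomes)
    anc <- lapply(chroms, function(ch) {
      sample(bases, scenario$chromosome_length, replace = TRUE)
    })
    g1 <- lapply(anc, mutate_seq, rate = divergence)
    g2 <- lapply(anc, mutate_seq, rate = divergence)
    set1 <- Biostrings::DNAStringSet(vapply(g1, paste, character(1), collapse = ""))
    set2 <- Biostrings::DNAStringSet(vapply(g2, paste, character(1), collapse = ""))
    names(set1) <- names(set2) <- chroms
    out <- list(genome1 = set1, genome2 = set2)
    if (n_read_pairs > 0) {
      anchor <- scenario$letters[1]
      a <- sum(strsplit(scenario$base_composition, "")[[1]] == anchor)
      origin <- sample(scenario$letters, n_read_pairs, replace = TRUE,
                       prob = c(a, scenario$ploidy - a) / scenario$ploidy)
      chrom_pick <- sample(chroms, n_read_pairs, replace = TRUE)
      max_start <- scenario$chromosome_length - insert_size
      starts <- sample(seq_len(max(max_start, 1)), n_read_pairs, replace = TRUE)
      read_seq <- function(genome, ch, from, len) {
        raw <- strsplit(as.character(genome[[ch]]), "")[[1]][from:(from + len - 1)]
        paste(mutate_seq(raw, error_rate), collapse = "")
      }
      genome_of <- function(o) if (o == anchor) set1 else set2
      reads <- tibble(
        read_id = sprintf("read%06d", seq_len(n_read_pairs)),
        origin = origin, chrom = chrom_pick, start = starts,
        seq1 = mapply(function(o, ch, s) read_seq(genome_of(o), ch, s, read_length),
                      origin, chrom_pick, starts),
        seq2 = mapply(function(o, ch, s) {
          read_seq(genome_of(o), ch, s + insert_size - read_length, read_length)
        }, origin, chrom_pick, starts)
      )
      out$reads <- reads
    }
    if (!is.null(fasta_dir)) {
      dir.create(fasta_dir, showWarnings = FALSE, recursive = TRUE)
      Biostrings::writeXStringSet(set1, file.path(
        fasta_dir, sprintf("subgenome_%s.fasta", scenario$letters[1])))
      Biostrings::writeXStringSet(set2, file.path(
        fasta_dir, sprintf("subgenome_%s.fasta", scenario$letters[2])))
      if (!is.null(out$reads)) {
        fq <- function(seqs, ids, path) {
          writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                                     strrep("I", nchar(seqs)))), path)
        }
        fq(out$reads$seq1, out$reads$read_id, file.path(fasta_dir, "reads_1.fastq"))
        fq(out$reads$seq2, out$reads$read_id, file.path(fasta_dir, "reads_2.fastq"))
      }
    }
    out
  })
}
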