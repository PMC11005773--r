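---
title: "Alignment-based subgenome dosage inference: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-based subgenome dosage inference: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgenome)
library(dplyr)
```

This vignette is the package's own account of the two statistics it
implements — Relative Averaged Alignment (RAA) and Relative Coverage — the
assumptions behind them, the tunable parameters and their defaults, what the
simulator does and does not emulate, and the design decisions taken where
the methodology left genuine choices open.

## The problem

Hybrid crops such as cultivated banana carry chromosome sets from two or
more donor species (subgenomes). Within a clonal lineage the per-locus
dosage — how many copies come from each donor, e.g. AAB versus ABB — and any
homoeologous exchanges (segments of one subgenome replaced by the
homologous segment of another) are fixed, heritable copy-number variation.
Classical approaches paint ancestry with donor-private SNPs, which requires
sequencing a donor panel and breaks down between recently diverged pools.
Both methods here need only alignment-level summaries against the candidate
donor references, so they scale to new panels and new references
immediately.

## Relative Averaged Alignment

For sample $s$ and reference $r$, let $PP(s,r)$ be the percentage of
properly paired reads. Samples differ multiplicatively in overall alignment
quality (DNA degradation, PCR duplication, library artefacts), which
confounds the comparison of $PP$ across references. With samples grouped
into varietal clusters (clonal lineages, identified upstream by admixture or
PCA — out of scope here), the cluster profile
$P(c,r) = \mathrm{mean}_{s \in c} PP(s,r)$ captures the lineage-typical
alignment rate, and the per-sample weight factor

$$w_s = \frac{1}{|R|} \sum_{r \in R} \frac{PP(s,r)}{P(c(s),r)}$$

captures how much better or worse than its lineage this particular sample
aligns, averaged over all references so that ancestry differences cancel.
RAA is then $PP(s,r) / w_s$. Two exact properties follow, both enforced by
tests:

* if every sample's percentages are its cluster profile times a constant
  $q_s$ with $\bar q = 1$, then $w_s = q_s$ and RAA equals the profile to
  machine precision (multiplicative cancellation);
* because the profile is the arithmetic mean including the sample itself,
  the cluster mean of weight factors is exactly 1.

Design choices (the method description leaves these open):

* **A sample is included in its own cluster mean.** This keeps the
  cluster-mean-of-weights identity exact and matches the use of the whole
  varietal cluster as the baseline.
* **Per-chromosome RAA recomputes profiles and weights from per-chromosome
  statistics** rather than reusing genome-wide weights: chromosome-scale
  technical effects (e.g. reference assembly quality) would otherwise leak
  into the chromosome signal. No normalization by chromosome length is
  applied; values are interpreted jointly across chromosomes as-is.
* **Unclustered samples get weight 1.0 and are flagged** — no defensible
  baseline exists for them.
* **Weights outside 0.95–1.05 warn but do not error.** That interval is an
  empirical observation about well-behaved short-read panels, not a
  constraint of the model.
* Clusters need `min_members` samples (default 3) to contribute a profile.

## Relative Coverage

Reads are aligned competitively to the two candidate subgenome references
concatenated into one target, so each read pair settles on the subgenome it
matches best. After removing duplicates, secondary/supplementary records,
non-proper pairs and any record with an `XA`/`SA` tag (multi-mappers), depth
is summarized as the **median** of per-position depth in fixed windows
(default 100 kb). The median, not the mean, because repeat-driven coverage
peaks would otherwise dominate windows; a narrow 500× spike inside an
otherwise 7× window leaves the median at 7. Zero-coverage positions are
included, so absent regions score 0 rather than being skipped.

Windows are compared only where the two references are homologous: a
whole-genome alignment (PAF) is converted into a window map by accumulating
aligned bases per candidate partner window and assigning the majority
partner, in both directions, so both references' coordinate systems and
chromosome lengths are represented. Windows with less than `min_frac`
(default 20%) of their length aligned are excluded.

For each chromosome $c$ of the anchor reference the normalizer is the mean
per-copy depth over its mapped windows, $M_c = \mathrm{mean}((d_A + d_B)/2)$,
and the Relative Coverage pair is $r_A = d_A / M_c$, $r_B = d_B / M_c$. By
construction the chromosome mean of $(r_A + r_B)/2$ is exactly 1, and at
ploidy $p$ a window with $a$ anchor copies is expected at

$$E[r_A \mid a] = \frac{2\,(a(1-\beta) + (p-a)\beta)}{p},$$

spanning the 0–2 range: 1 for balanced dosage, $4/3$ vs $2/3$ for 2:1 (AAB),
2 vs 0 for a full exchange. $\beta$ is the cross-mapping background: in
regions still conserved between the references the aligner places copies
arbitrarily, so a pure window of the other subgenome retains
$E[r_{minor}] = 2\beta$ of signal. The model treats $\beta$ as a uniform
rate over mapped (conserved) windows; in real data the background scales
with local conservation density, so per-window deviations are expected.

* **Background estimation** alternates classification and re-estimation:
  $\hat\beta \leftarrow \mathrm{median}(r_{minor})/2$ over windows currently
  classified pure ($a = 0$ or $a = p$), until the change is below $10^{-4}$
  (at most 10 iterations). Without pure windows it returns a configurable
  fallback with a warning — an AAB genome with no planted pure segment
  simply has no internal calibrator.
* **Classification** assigns the nearest expected level, with ties (to
  within $10^{-9}$) broken toward the smaller copy number; windows beyond
  $2(1 + 0.2)$ are flagged anomalous but still classified. Values are never
  clipped at 2 — the 0–2 range is a statistical property, not a hard bound.
* **Normalizer choice.** "Chromosome average coverage" is ambiguous about
  which track's average; normalizing both tracks by the combined per-copy
  mean $M_c$ is the reading that keeps whole-chromosome exchanges visible
  at $r \approx 2$ vs $r \approx 0$ and yields the 0–2 range. A genome-wide
  baseline option exists for detecting whole-chromosome *total* aneuploidy,
  which a per-chromosome baseline masks by construction.
* **Segmentation** smooths the per-window calls with a centred
  rolling-majority vote over `smooth_k` windows (default 5), run-length
  encodes, and reports runs differing from the accession's modal composition
  with at least `min_windows` windows (default 5). A run covering ≥ 95% of a
  chromosome's mapped windows is flagged as a whole-chromosome exchange.
  Visual inspection was the original practice; these three thresholds are
  this package's formalization and are all configuration-exposed.
* **The modal composition** defaults to $\mathrm{round}(p \cdot
  \mathrm{mean}(r_A)/2)$ rather than the per-window modal call: at low depth
  the per-window mode is vulnerable to asymmetric misclassification (an
  accession with several whole-chromosome exchanges can have its baseline
  outvoted), while the genome-wide mean dosage is stable. For genomes so
  rearranged that no composition dominates, set `modal_a` explicitly.
* Composition labels put the anchor reference's letter first: anchor A,
  $p=3$, $a=1$ is "ABB".

## The simulator

`simulate_depths()` realizes a dosage mosaic directly at the window level:
expected depths $E[d_A] = u(a(1-\beta) + (p-a)\beta)$ (and symmetrically for
$d_B$) with per-copy depth $u$, then one Poisson draw per window as a proxy
for the window median ("proxy" mode). This keeps scenario generation
instant; the per-base path — Poisson depth per position, median within
window — exists as `depth_mode = "perbase"` and is used in tests to
cross-validate the proxy and to exercise the regime real data occupy, where
the median over $10^5$ positions is far tighter than a single Poisson
variate. The default conditions mirror a realistic triploid panel: 11
chromosomes, 100-kb windows, total accession depth ≈ 7× (per-copy depth
$7/p$), background $\beta = 0.03$, 95% of windows conserved. Named presets
encode characteristic lineage mosaics (whole-chromosome ABB on chromosome 7
plus five telomeric AAA introgressions for `plantain_aab`; whole-chromosome
BBB on chromosomes 2, 7 and 11 for `pelipita_abb`; and so on). The exact
segment spans within a preset are package choices made once — only their
qualitative layout (which chromosomes, telomeric vs interior, whole vs
partial) is meaningful; the plantain chromosome-4 introgression occupies the
first 30 of 100 windows.

`simulate_stats_panel()` generates $PP(s,r) = q_s \cdot P(c,r) +
\varepsilon$ with quality multipliers $q_s$ either uniform in $1 \pm 0.05$
or on an evenly spaced symmetric grid (deterministic, mean exactly 1), and
back-fills integer read counts at $10^7$ total reads — large enough that
percentages with up to five decimal digits convert to exact integer counts,
preserving closed-form recoveries exactly.

`simulate_sequences()` mutates one ancestor into two subgenomes at a given
substitution rate (expected divergence $2d(1-d) + \tfrac{2}{3}d^2$) for
optional end-to-end runs through an external aligner; no indels, repeats or
GC bias are modelled.

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: mappability and GC structure along chromosomes,
conservation-density-dependent background, reference assembly errors, and
the read-level artefacts removed upstream (duplicates, trimming). The
proxy noise model is *noisier* per window than a true median pile at equal
depth, so window-level accuracies measured under it are conservative, while
its integer outcomes make the background median degenerate at very low
per-copy depth (the median minor-side count at $u \beta p \ll 1$ is 0, so
$\hat\beta \to 0$); background recovery is therefore validated at higher
depth, where the estimator is informative.

## Numerical conventions and degenerate inputs

All genomic coordinates are 0-based half-open, stated in every file header;
segments are emitted as BED6. `pp_percent` is carried at full precision
internally and validated against counts at a $5 \times 10^{-4}$ absolute
tolerance on reading (4-decimal convention). Zero-read samples get
`pp_percent = 0` with a warning; a zero cluster profile is an error (no
ratio exists). Chromosomes with no mapped windows are skipped with a
warning; a zero normalizer $M_c$ is an error. Window-map ties break toward
the partner window with the smaller start coordinate; strand is ignored for
pairing since depth is strand-symmetric. Total read counts follow flagstat
"primary" semantics (secondary and supplementary records excluded), with
reads on unplaced scaffolds counted in genome scope only — both decisions
recorded in the stats TSV header. Depth spans are taken from the CIGAR
reference width of each record (deletions spanned), a negligible deviation
from per-position counting at 100-kb scale.

## Problem sizes used in validation

The test-suite and acceptance analyses run at desk scale, chosen so the full
suite completes in well under a minute while keeping every estimate's
sampling error far inside its tolerance: dosage-ratio and segmentation
recovery on 10–11 chromosomes × 100 windows (≈ 1000 windows per accession)
at 2.5× per-copy depth; per-base-mode accuracy on 1-kb windows (120
windows × 1000 positions); background recovery on 6 chromosomes at 30–50×
per-copy depth; RAA recoveries on 5–30-sample panels. Determinism is
asserted byte-for-byte on rerun with the same seed.

## Known limitations

* Dosage is read from the anchor side only; compositions over three or more
  simultaneous donors (beyond a reference pair) require running the pipeline
  once per pair, as is standard practice (A+B, then A+S).
* Low-ratio introgressions (e.g. 1 copy of 4) sit half a level from their
  neighbours and need correspondingly more depth or wider windows.
* β is assumed uniform across conserved windows; strongly heterogeneous
  conservation will modulate the background locally and can push individual
  pure windows past the nearest-level midpoint.
* The cluster-based weight factor requires clusters of ≥ `min_members`
  technically comparable samples; singletons are reported unnormalized.
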