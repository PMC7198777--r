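---
title: "Inferring replication origins and replication modes of circular bacterial chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring replication origins and replication modes of circular bacterial chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replimode)
```

## The problem

Most bacteria replicate a single circular chromosome bidirectionally from a
unique origin (*oriC*) to an antipodal terminus (*ter*). That process leaves
two kinds of footprints that this package quantifies:

* **Compositional footprints.** The leading and lagging strands accumulate
  different base compositions, so the GC skew, `(G − C)/(G + C)` computed on
  the published strand, switches sign near *oriC* and *ter*; gene
  orientation is likewise biased toward the leading strand (CDS skew). The
  running (cumulative) sum of windowed skew values traces a V (or Λ) whose
  global extrema mark the two shift points.
* **Population-genomic footprints.** In an exponentially growing culture,
  loci near the origin are present in more copies than loci near the
  terminus, because some chromosomes are caught mid-replication. Marker
  frequency analysis (MFA) reads this gradient out of sequencing depth: the
  depth of the growing sample, normalised by total reads and divided by the
  matching stationary-phase (non-replicating) profile, gives a ratio
  profile `R(x)` that is V-shaped for a unique origin and flat when
  replication initiates asynchronously from many dispersed sites.

Cyanobacteria are the interesting case: many species are polyploid, many
chromosomes have irregular skew profiles, and the replication mode varies
between close relatives — a unique origin with the classic skew V, a unique
origin *without* a skew V, or dispersed asynchronous initiation. The package
therefore reports three lines of evidence per genome — skew regularity, MFA
mode, and ploidy — and combines them into a qualitative profile class.

## Population replication models

A `replication_model()` captures the replication state of a culture, and
`expected_relative_copy_number()` gives the expected marker frequency
`m(δ)`, where `δ = 2·d(x, ori)/L ∈ [0, 1]` is the normalised origin
distance (`d` is circular distance):

* **single_origin** — a fraction `r` of chromosome copies carry one
  bidirectional fork pair, with fork progress uniform on `[0, 1]`; a locus
  at distance δ is already duplicated on a replicating copy iff progress
  ≥ δ, so `m(δ) = 1 + r(1 − δ)` and the ori/ter ratio is `1 + r`. This is
  the polyploid regime: with only one or a few of many copies replicating,
  the ratio stays close to 1 but the profile is still a V.
* **multifork** — overlapping rounds in an exponential steady state with
  fork intensity `k` (replication time over doubling time):
  `m(δ) = 2^{k(1−δ)}`, so the ori/ter ratio `2^k` exceeds 2 once rounds
  overlap (`k > 1`).
* **multi_origin_async** — asynchronous initiation from dispersed sites:
  `m ≡ 1`.

The uniform fork-stage assumption in the single-origin mode is the minimal
model that reproduces a linear V; no fork-age distribution is implied beyond
that. The multifork closed form is the standard exponential-age result; the
test suite cross-checks it against an independent Monte-Carlo sampler of
synchronous re-initiation.

```{r copy-number}
m <- replication_model("multifork", genome_length = 3e6, fork_intensity = 1.5)
expected_relative_copy_number(m, c(0, 1.5e6))  # ori vs ter: ratio 2^1.5
```

## What the simulator emulates — and what it does not

`generate_skewed_genome()` emits bases independently per position: on the
replichore running (ascending) from ori to ter the published strand gets G
with probability `(gc/2)(1 + s)` and C with `(gc/2)(1 − s)`; the bias is
mirrored on the other replichore; A/T split the remainder evenly.
`generate_annotations()` places genes uniformly and orients each with its
replichore's leading strand with probability `p`. `simulate_depth_profiles()`
draws Poisson counts per window around `mean_depth · m(δ)/mean(m)` for the
exponential sample and a flat `mean_depth` for the stationary control.
`simulate_flow_cytometry()` draws lognormal per-cell fluorescence with
median proportional to copies × genome size (the proportionality constant,
1e-9 per bp·copy, cancels in every ratio) and `sdlog = sqrt(log(1 + cv²))`.

Default study conditions, chosen once as field-realistic and used throughout
the analysis scripts and tests: skew strength `s = 0.3` and `gc = 0.5`
(clearly V-shaped clade-like genomes; `s ≥ 0.1` still passes the regularity
threshold), 80% leading-strand gene bias, gene lengths uniform on
300–1500 bp, Poisson depth of 500 reads per 1-kb window (the polyploid
small-`r` analyses use 2000), and `cv = 0.3` with 10,000 cells for
cytometry.

The simulator deliberately omits: read-level simulation and sequencing
error, GC-dependent coverage bias, gene overlap constraints, operon
structure, plasmids, and cell-cycle substructure in fluorescence. Passing
tests therefore demonstrate correctness of the statistical machinery under
the stated generative assumptions, not robustness to mapping artefacts or
compositional coverage bias in real libraries.

## Skew profiling choices

* Windows tile the circle (default 10 kb, non-overlapping, for genomes ≥
  1 Mb); the trailing remainder merges into window 0 when shorter than half
  a window, otherwise it stands as a truncated final window. Coordinates
  are 0-based half-open internally; GFF3 I/O converts to 1-based inclusive
  at the boundary.
* Windows with no G or C (or no genes) score 0 rather than `NA` — this
  keeps cumulative sums total; the count of such degenerate windows is kept
  on the profile.
* Genes are assigned to windows by midpoint, avoiding double counting
  across borders.
* **Rotation adjustment.** The cumulative skew of a circle depends on the
  linearisation point, and deposited sequences often start at a putative
  origin — a convention the method must not rely on. `detect_shift_points()`
  therefore subtracts the genome-wide mean skew per window before
  accumulating, which makes the candidate calls rotation-equivariant to
  machine precision: rotating the input rotates the calls and leaves the
  regularity score unchanged.
* **Regularity score.** `R²_v` is the coefficient of determination of the
  best two-segment piecewise-linear circular fit (the "tent" through the
  two extrema along both arcs). An ideal two-segment profile scores exactly
  1; i.i.d. noise profiles stay well below the `is_v_shaped` threshold of
  0.90 (a configurable knob; in simulation the 95th percentile of the null
  score is ≈ 0.78).
* Sign convention: the leading strand is assumed G-rich, so cumulative GC
  skew has its minimum at ori and maximum at ter. For a genome of opposite
  polarity the two labels swap; the package reports the calls under the
  stated convention rather than guessing polarity.

## MFA choices

* Alignment is out of scope: depth enters as bedGraph, where each
  interval's value is a read count spread pro-rata over its bases. Read
  quality trimming (`trim_reads()`) follows fixed end-clipping (15 nt from
  the 5′ end, 2 nt from the 3′ end) with retention of the longest
  contiguous segment of bases above Phred 30, then discards reads shorter
  than 100 nt. The length rule is an interpretation: the filter is read as
  a minimum post-trim length, the only reading consistent with quality
  control.
* `R(x)` is a ratio of totals-normalised counts computed per fine window
  (default 1 kb), then re-aggregated at the coarse scale (default 100 kb)
  by summing counts before taking the ratio — more stable than averaging
  fine ratios. Stationary-zero windows are masked and tracked in QC.
* `detect_origin()` smooths the coarse profile with a centred circular
  moving average (span 5 coarse windows) and places the origin at the
  smoothed argmax (window midpoint).
* **De-attenuated peak/trough ratio.** A span-w boxcar lowers a
  piecewise-linear apex by `h(h+1)/(2w)` times the sum of the flanking
  slopes (`h = (w−1)/2`), and raises the trough symmetrically. Taking the
  raw smoothed max/min would under-report the replicating fraction by
  ~17–21% under the default geometry, so the package restores the apex and
  trough in closed form from the smoothed amplitude and the two arc lengths
  between the extrema. With the correction, the median bias of
  `peak_trough_ratio − 1` against the true `r` is about −2% across
  `r ∈ {0.1, 0.3, 0.5}` at 500 reads per 1-kb window. The correction is
  skipped when degenerate (tiny grids, non-positive corrected trough) and
  the ratio is floored at 1.
* **Resampling-calibrated interval.** The peak/trough statistic is ≥ 1 by
  construction, so a naive bootstrap interval could never include 1 and
  every flat profile would look significant. Instead, window permutations
  give the null spread of `log(peak/trough)` expected from noise alone
  under no spatial structure, and the reported CI is the observed log-ratio
  offset by the null quantiles (200 replicates, 95% level, seeded). On a
  genuinely flat profile this interval includes 1 with the nominal 95%
  rate.
* Mode call: `single_origin_V` requires both a circular V fit with
  R² ≥ 0.5 on the coarse profile and a CI excluding 1; a CI including 1
  gives `flat_multi_origin`; anything else — including > 20% masked
  windows — is `indeterminate`.

## Ploidy arithmetic

DNA-stain fluorescence per cell is proportional to copy number × genome
size, so a target species' copy-number range follows from its median
fluorescence ratio ρ against a reference of known ploidy range
`[c_lo, c_hi]`:

`k_b = round(ρ · c_b · G_ref / G_target)`, rounding half away from zero.

```{r ploidy}
estimate_ploidy(8, c(3, 6), ref_genome = 2.7e6, target_genome = 4.1e6)
estimate_ploidy(2, c(3, 6), ref_genome = 2.7e6, target_genome = 3.0e6)
```

The median is used for ρ because cytometry distributions are right-skewed.
Rounding half away from zero is a convention; published copy-number ranges
in this area are not always internally consistent about rounding at the
upper bound, and the package does not special-case any of them.

## Profile classification

`classify_species_profile()` maps the two shape calls onto descriptive
classes: V skew + V MFA → `DnaA-oriC-like`; irregular skew + V MFA →
`unique-origin-DnaA-independent-like`; irregular skew + flat MFA →
`multi-origin-like`. The labels describe profile shape only — no genotype
is inferred — and contradictory evidence (e.g. a clean skew V with flat
MFA, which arises when a simulated genome carries a compositional V but the
coverage model is flat) is deliberately left `indeterminate` rather than
forced into a class.

## Problem sizes, determinism and limitations

The bundled analyses and tests run on 1–3 Mb genomes, 1-kb fine / 50–100-kb
coarse windows, depths of 500–2000 reads per fine window and 5,000–10,000
cytometry events — sizes chosen so the full workflow re-runs in seconds
while keeping coarse-window counts (≥ 5 × 10⁴ reads) deep enough that the
closed-form ratio expectations are resolvable against Poisson noise. Every
stochastic step takes an explicit integer seed, and identical config + seed
reproduces reports byte for byte.

Known limitations: origin localisation is quantised to half a coarse window
(50 kb at the defaults), so weak gradients (`r ≈ 0.1`) occasionally place
the origin one window off; the V fit assumes a single global peak and will
call strongly bimodal profiles `indeterminate`; polarity (which label is
ori vs ter) is convention-based for skew; and real-data effects excluded
from the generator (above) are untested by construction.
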