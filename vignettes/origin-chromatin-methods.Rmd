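---
title: "Methods: nucleosome architecture at replication origins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome architecture at replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(orichrom)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the synthetic design used to test
them, and the choices made where the method description left the design open.

## From boundary reads to a positioning profile

MNase digestion of chromatin leaves ~147 bp of DNA protected around each
nucleosome dyad. Single-end sequencing of those fragments yields reads whose
5′ ends mark fragment *boundaries*: plus-strand 5′ ends pile up at left
edges, minus-strand 5′ ends at right edges. Two per-base signals are built
from them:

* **Fragment coverage** (`starts_to_raw_coverage()`): every 5′ end is
  extended one nucleosome footprint (147 bp, the canonical protection size)
  into the fragment, because the 40-nt read length is only evidence of a
  boundary, not of occupancy. Coverage is then divided by the genome-wide
  mean (`normalize_by_genome_mean()`), so all thresholds downstream are in
  units of "fold of average coverage". The NDR rule operates on this track.
* **Positioning profile** (`combined_profile()`): per-strand 5′-end counts
  are wavelet-smoothed; local maxima above a noise floor (mean + 1 sd of the
  smoothed strand signal — the data give no principled floor, so it is a
  config key) are boundary peaks. Each plus peak is paired with the nearest
  downstream minus peak at a separation of 100–200 bp; the mean separation
  estimates the protected fragment length (~147 bp), and pair midpoints are
  the nucleosome calls. For the continuous profile, plus counts are shifted
  downstream by `floor(spacing/2)` and minus counts upstream by
  `ceiling(spacing/2)`, summed, smoothed once and mean-normalized. We shift
  *raw* counts and smooth once rather than summing two smoothed tracks; the
  two orders differ only by a second smoothing pass, and a single pass keeps
  the profile linear in the input reads.

**Wavelet smoothing.** The smoothing is a multilevel 1-D biorthogonal wavelet
decomposition/reconstruction in the stationary (à trous) form: the signal is
split into dyadic detail layers plus a residual smooth using the biorthogonal
B3-spline scaling filter `(1, 4, 6, 4, 1)/16`, the `level` finest layers are
suppressed, and the rest is the reconstruction. The operator is linear,
preserves constants (the filter sums to 1), and never produces negative
values from non-negative input (all filter taps are non-negative). The
default `level = 3` suppresses structure below roughly 20 bp — far below one
footprint — and is a config key; the exact family/depth used to produce the
original maps is not published, so only structural equivalence on synthetic
truth is claimed, never track-level equivalence on real data. Boundaries use
symmetric reflection to avoid ringing at chromosome ends (periodic padding is
available and preserves the mean exactly).

Sub-footprint duplicate calls (pairs closer than 60 bp) are merged to their
score-weighted mean; midpoints of even spans round down. Both are
deterministic tie-breaks for rules the method description does not fix.

## NDR calling

An NDR is a maximal run of **at least 80 consecutive bases** with normalized
coverage **strictly below 0.4**. Both constants are exposed
(`min_len`, `threshold`) but these defaults are the method's definition, and
the tests pin the boundary behaviour: a 79-base run is rejected, a run at
exactly 0.4 is rejected. No gap tolerance is allowed inside a run (a
configurable gap key exists but defaults to 0, the pure rule).

Each origin claims at most one NDR: the one overlapping its ACS or lying
within `max_dist = 150` bp of it (the method does not state this radius; 150
bp is comfortably below typical inter-NDR spacing and is a config key),
nearest to the ACS midpoint, ties broken by larger ACS overlap then lower
coordinate. An origin with no claimed NDR is **closed** — a distinct
sentinel (`closed = TRUE`, width `NA`), never width 0, so averages must
exclude it explicitly. When an origin's NDR extends past the [−600, 600]
analysis window its full width is still reported.

## Origin windows, classes and composition

Profiles over [−600, 600] bp are anchored at the **ACS midpoint** (the
method centers "on the ACS sequence"; the midpoint is the deterministic
reading of that) and oriented so the T-rich strand reads left to right —
reverse-complement-invariant by construction. Edge-truncated origins are
excluded with a warning, never padded.

Classification is Euclidean k-means over the raw window rows. "10,000
iterations" is read as the iteration budget of the clustering function:
implemented as `iter.max = 10000` per run with `restarts` (default 10)
seeded initializations, keeping the best by total within-cluster sum of
squares. Rows are not rescaled before clustering (the window values are
already on a common normalized scale; a config switch exists). Class labels
are then re-assigned so the class-mean NDR width decreases strictly from
class 1 to class k, ties favouring larger classes — the ordering convention
in which class 1 has the widest NDRs (193 bp planted) and class 6 the
narrowest (129 bp).

Early/late composition is the fraction of each timing group per class,
summing to 1 within a group. Small classes (3 and 4 in the six-class design)
can be excluded from box-plot-style summaries by a minimum-size switch.

## Intergenic context

IGRs are built between adjacent genes per chromosome (overlapping genes are
merged into one blocking interval; the flank strands come from the
rightmost-reaching gene on the left and the leftmost-starting gene on the
right). Categories are a pure function of flanking strands: equal strands →
tandem, (−,+) → divergent, (+,−) → convergent. Under independent equiprobable
gene strands the expectation is analytic — 1/2, 1/4, 1/4 — and
`expected_category_frequencies()` returns exactly that; an empirical
estimator on simulated genomes is used in the tests to confirm convergence.
Origin membership uses the ACS midpoint with half-open containment.
Enrichment is reported descriptively (observed fraction, expected, ratio); a
chi-square goodness-of-fit test is provided as an optional statistic because
the frequencies themselves, not a named test, are the result of interest.

## Forkhead motifs

Scanning is strict IUPAC matching of RTAAAYA (R = A/G, Y = C/T) on both
strands; an N in the genome never matches. This deliberately collapses a
permissive PWM scan followed by removal of non-consensus matches into exact
consensus matching — the final hit set is the strict-consensus set either
way. The dual-site detector is true when one hit lies within
`proximal_max = 50` bp of the ACS midpoint ("close proximity" is not
quantified; 50 bp is a config key) and some pair of hits is separated by
60–120 bp **inclusive**, measured between motif start coordinates (the
anchor is not specified; starts are the deterministic choice). An optional
stricter mode additionally requires both sites inside the origin's claimed
NDR, since the observed sites sit at the NDR borders.

## Replication dynamics

The S-minus-G1 differential of two mean-1 positioning tracks is elementwise
and antisymmetric. Copy-number correction rescales **both** the nucleosomal
and the naked-DNA track to genome mean 1, divides base by base (zero-naked
positions are masked as missing, never infinite), and smooths the ratio with
a sliding 1000-bp mean at 1-bp step whose edge windows shrink symmetrically
and whose missing positions propagate as means over available bases. The
1000-bp window deliberately erases nucleosome-scale detail: the corrected
track measures relative copy number, so S-vs-G1 comparisons after correction
are made between the two *corrected* tracks. Correction is applied per base
before any aggregation over origins.

The replicated extent around an origin is the maximal contiguous region
**containing the ACS midpoint** where the window-averaged differential
exceeds a threshold, by default 0.25 × the origin's peak averaged
differential within ±6 kb. Two design choices beyond that relative rule:
the run must contain the ACS (an inactive origin a few kb from an active one
must not inherit its neighbour's elevation), and the peak must exceed an
absolute floor (`min_peak = 0.2` in normalized-signal units) because a
purely relative threshold fires on noise at unreplicated origins.

Per-timing-group shift reports aggregate matched G1/S window matrices, find
the ACS-proximal minimum, and take the nearest flanking local maxima within
300 bp as the −1/+1 nucleosomes; peaks must exceed the depletion threshold
(0.4) so sub-threshold noise inside the NDR is never picked, and the
aggregate is lightly wavelet-smoothed first.

## The synthetic design

`sim_config()` defaults are the study conditions: single-end 40-nt boundary
reads at 85-fold genome coverage (the middle of the reported 76–95× range),
a 147-bp footprint, 165-bp background repeat length, hydroxyurea-arrested S
phase with exactly 2× copy number over ±2250 bp of early origins only, and a
compliant Fkh dual-site configuration planted at 25.6% of early origins
(proximal site 15 bp from the ACS, 90-bp separation — within the observed
80–100 bp spacing). Six architecture classes span NDR widths 193 → 129 bp
with linear interpolation between the stated extremes. Per-class occupancy
(0.95 → 0.52), dyad fuzziness (2 → 12 bp sd) and NDR asymmetry relative to
the ACS (+50 → −50 bp) are free parameters — the source states none of them —
chosen once for clear class separation and fixed; they are what the
class-recovery results are conditional on. Class assignment reproduces the
observed timing association by default (60% of early origins in classes 1–2
with 40% in class 1; 65% of late origins in classes 5–6 with 40% in class 6;
classes 3–4 sparse), with a `"balanced"` option that assigns classes in equal
numbers independently of timing for recovery benchmarks.

Within ±650 bp of every ACS, spurious RTAAAYA matches arising from the random
background are scrubbed (one base mutated to C/G), so planted sites are the
complete motif ground truth near origins and the planted dual-site fraction
is recovered exactly by the deterministic detector.

What the generator does **not** emulate: sequence-dependent MNase bias,
dinucleosome fragments (the mono:di digestion ratio appears only as boundary
noise), GC or mappability artifacts, transcription-coupled nucleosome
dynamics, and any coupling between origin placement and IGR category. Tests
passing on this design therefore demonstrate that the pipeline recovers what
it models — widths, classes, spacing, copy number, motif geometry — not that
real chromatin obeys the model.

Problem sizes in the tests and the acceptance script were chosen as the
smallest at which the recovery questions are statistically meaningful: a
300-kb, 24-origin genome at 85× for width/dyad/correction checks, and a
1.7-Mb, 600-origin genome (100 per class in the balanced design) for
clustering recovery.

## Degenerate inputs and numerical conventions

Coordinates are 0-based half-open everywhere in memory; GFF3 (1-based
inclusive) and bedGraph/BED conversions live only in the io functions.
All-zero coverage refuses to normalize; empty read tracks warn and return
empty peak sets; duplicate profile rows collapse k-means to the number of
distinct rows with a warning; an all-identical matrix yields one populated
class. bedGraph values are written at full precision so write/read round
trips are value-exact. All randomness flows from explicit integer seeds;
`run_pipeline()` is byte-deterministic for a fixed seed, and its JSON
manifest (package version, seed, parameters, output list — no timestamps)
suffices to reproduce a run.

## Known limitations

* The wavelet family/level of the original maps is unpublished; the
  B3-spline stationary scheme matches the stated contract (biorthogonal,
  multilevel, denoising below nucleosome scale) but not necessarily the
  original coefficients.
* Boundary-peak pairing assumes mononucleosome-dominated libraries; heavy
  dinucleosome contamination would bias the spacing estimate upward.
* The NDR rule is a hard threshold on normalized coverage and inherits its
  sensitivity to coverage normalization in highly repetitive or masked
  regions, which the synthetic genome does not contain.
* Replicated-extent measurement assumes a single contiguous replicated
  region per origin, appropriate for HU-arrested forks but not for free-running
  S phase.
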