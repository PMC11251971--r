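---
title: "Structural atlases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural atlases: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structatlas)
```

This vignette is the package's own account of the science behind each
lane, of the parameters that matter, and of the choices made where the
underlying conventions are not fully pinned down in the literature the
scales come from.

## The model: sequence-encoded DNA structure

DNA's local physical behaviour is, to a useful approximation, additive
over short k-mers. The package builds on three published parameter sets,
shipped as plain-text assets under `inst/extdata/scales/` (header lines
carry name, k, units and the citation; tests assert completeness and
strand symmetry against the files themselves):

* **Stacking energy** (dinucleotide, kcal/mol; Ornstein et al. 1978).
  Base-stacking is the dominant stabiliser of the duplex; a window whose
  mean stacking energy is close to zero denatures ("melts") more easily
  than one with strongly negative values. The scale is strand-symmetric —
  a physical necessity, since a dinucleotide step and its reverse
  complement describe the same stacked pair viewed from the two strands —
  and the tests enforce `E(x) == E(revcomp(x))` for all 16 entries.
* **Position preference** (trinucleotide, dimensionless; Satchwell et
  al. 1986). Derived from the periodic occurrence of trinucleotides in
  nucleosome core DNA, it measures anisotropic bendability. The published
  table gives one value per complementary pair; the packaged file expands
  it to all 64 trinucleotides, which makes the symmetry explicit and the
  completeness test trivial. Low windows are the interesting ones: DNA
  with little preference for any bending direction wraps nucleosomes
  poorly and is a candidate for open chromatin.
* **Curvature** (dinucleotide wedge model; Bolshoy et al. 1991, with the
  Kabsch–Sander–Trifonov twist angles). Each step deflects the helix axis
  by a wedge angle at an azimuth set by the accumulated helical twist.
  The sources the atlas lineage cites do not name a single canonical
  parameter set for the zoom curvature lane, so the model is pluggable
  (`curvature_track(model = ...)`): any complete table of
  wedge/direction/twist angles works, and the packaged wedge model is the
  documented default.

Profiles are per-position lookups (`lookup_profile()`); a k-mer
containing `N` yields `NaN`.

## Windowing

All value lanes are running means reported at window centres
(`pos = floor(window/2) + i*step`). Numerical choices:

* `NaN` positions are excluded from the window mean rather than
  propagated; a window with *no* valid position is `NaN`. Assembly gaps
  hundreds of bp long would otherwise blank entire lanes.
* Window sums use cumulative sums, so any window/step combination costs
  O(L). The tests pin the result to a brute-force O(L·w) loop at 1e-9.
* Default step is 1 bp for all property lanes. The atlas lineage speaks
  only of "sliding windows"; computing at full resolution and letting the
  renderer downsample keeps tracks independent of the figure width.
  `step = window` is available where coarser output is wanted, and the
  repeat lanes default to it (below).

Default windows: 101 bp for stacking energy, position preference and
curvature smoothing (odd, so centres are integral; at zoom resolutions of
a few bp/pixel this is the scale of promoter-sized features); 10,000 bp
for GC skew, the convention for replication-strand bias, which is a
long-range signal; AT content uses 0.1% of the plotted region, so a whole
locus and a zoom each get a proportionate window.

**GC skew denominator.** Skew is computed as (G−C)/(G+C), the standard
definition, which makes the value a composition-independent bias in
[−1, 1] and gives the exact antisymmetry
`skew(revcomp(s)) == -rev(skew(s))` that the property tests check.
"Divided by the total" could also be read as window length;
`denominator = "window"` provides that normalisation for comparability,
but it is not the default.

**Curvature.** Per dinucleotide step the model contributes a planar
vector of magnitude `wedge` at angle `direction + cumulative twist`; the
curvature over the model window (21 bp — two helical turns, enough for
phase coherence to express itself, short enough to keep the signal local)
is the magnitude of the vector sum divided by the number of steps,
i.e. mean axis deflection in degrees per step. Only the magnitude is
reported — the lane is single-coloured, and bend *direction* is
meaningless once windows are averaged. In-phase A6 tracts repeated every
~10.5 bp sum coherently and dominate a shuffled control of identical
composition (a property test); an all-zero wedge table gives identically
zero, the degenerate-input control. Steps containing `N` contribute a
zero vector while the mean twist keeps phase advancing across the gap.

## Repeat lanes

Each 100-bp query window is scored with its best match anywhere else in
the sequence (direct) or in the reverse complement (inverted), and the
identity is binned with `min(floor(identity*10), 9)` — bin 9 is >90%
identity, bin 0 <10%. Values are plotted at window centres, from 50 bp to
within 50 bp of the end.

Design choices the published convention leaves open:

* **Ungapped identity** (Hamming over length-w alignments). It admits an
  exact brute-force oracle and an exact seeded search; gapped identity
  would make bins depend on alignment parameters.
* **Self-overlap exclusion**: candidate windows sharing ≥1 bp with the
  query are excluded, otherwise every query matches itself at bin 9. A
  `min_offset` parameter can demand a larger gap. When no non-overlapping
  placement exists (sequence shorter than two windows, or edge effects),
  the identity is reported as 0 with a note.
* **Default step = window** (non-overlapping queries). A whole-locus
  atlas at ~2 kbp/pixel cannot display sub-window steps, and the
  exhaustive verification cost grows linearly in the number of queries;
  `step` goes down to 1 where needed.
* **Search algorithm**: a 12-mer seed index finds all candidates first.
  By the pigeonhole bound, any alignment with at most
  `floor((w - s)/(s + 1))` mismatches (identity ≥ 94% for w = 100,
  s = 12) contains an exact seed, so when the best seeded hit reaches
  that bound it is provably the global optimum; below it the search falls
  back to an exhaustive vectorised scan. Reported identities are
  therefore always exact — the acceptance suite asserts equality with an
  independent oracle (Biostrings' mismatch counter) over dozens of
  fixtures on both strands. `approximate = TRUE` skips the fallback for
  very large inputs, at the documented cost that bins below the seed
  sensitivity may be underestimated. Ties are broken toward the smallest
  match position.
* `N` matches nothing, including another `N` — a gap should not look like
  a repeat of another gap.

## Rendering

Lanes are downsampled to the spec's pixel width (default 2,500) by
averaging the track values whose centres fall in each pixel's bp span;
empty pixels render as background. Colour scaling centres each lane at
its mean and saturates at mean ± 3 SD — the convention of the genome-atlas
lineage this layout follows; it is not dictated by the track definitions,
so `saturation_k` and the colormaps are per-lane configurable, and repeat
bins use a fixed 0–9 range instead. A zero-variance lane renders
uniformly at the midpoint. The resolution printed on every atlas and
written to the sidecar JSON is always computed as
`region_length / width_px` from the actual region, never taken from a
rounded figure.

Gene lanes draw the two strands as separate sub-bands. At whole-locus
scale genes are solid blocks (introns and exons combined — at 2 kbp/pixel
the distinction is invisible); zooms shade introns light and exons solid.
Zoom atlases replace GC skew with curvature, and a minus-strand gene's
region is reverse-complemented *before* track computation so the gene
reads 5′→3′ left to right; repeat lanes are still searched against the
full original sequence, because repeats are a global property, and only
their coordinates are flipped into the zoom frame.

PNG output uses the ragg device and is byte-deterministic for identical
inputs (the acceptance suite renders the same 50-kb fixture twice and
compares raw bytes). SVG output goes through the cairo device; there the
determinism guarantee is content-level, not byte-level.

## Synthetic fixtures

`fixture_recipe()`/`make_sequence()` generate every sequence the tests
use: uniform random background with optional AT/GC-rich blocks, G runs,
exact planted direct/inverted copies, and phased A-tracts (A6 every
10.5 bp, the classic intrinsically curved motif). Fixtures are
deterministic given (recipe, seed), recipes serialise to YAML, and
`make_annotation()` emits matched GFF3 for round-trip tests.

The generator emulates exactly the features the method detects —
composition blocks, exact repeats, phase-coherent curvature — and none of
the things real genomic DNA also has: repeat families with internal
divergence, tandem arrays, isochore-scale composition gradients,
realistic gene density, polymorphism. Passing tests therefore demonstrate
that the implementation computes its definitions correctly and recovers
planted signals, not that the tracks are biologically validated on real
loci.

Problem sizes are chosen to keep the full suite fast while exercising
every code path: property loops run 1,000 cases of 30–150 bp; oracle
equality for the repeat search uses 50 random fixtures of 2–5 kb on both
strands; end-to-end determinism uses a 50-kb atlas at 2,500 px.

## Known limitations

* Repeat identity is ungapped; diverged repeats with indels score lower
  than a gapped aligner would report.
* The curvature lane depends on the chosen wedge model; alternative
  parameter sets change absolute values (the ranking of strongly phased
  regions is robust).
* Melting is approximated by stacking energy alone — no nearest-neighbour
  ΔG/ΔH thermodynamics or salt correction.
* Soft-masked (lower-case) input is uppercased and treated as ordinary
  sequence; masking semantics are out of scope.
* Multi-record FASTA inputs are not concatenated; each record is its own
  atlas, and the CLI processes the first record of a multi-record file.
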