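---
title: "Determining unit-cell parameters from independent zonal ED patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining unit-cell parameters from independent zonal ED patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonecell)
```

## The problem

Electron diffraction patterns of thin crystals are effectively flat central
sections of the reciprocal lattice: the electron wavelength is two orders of
magnitude smaller than typical resolution, so a single zonal pattern carries
essentially no three-dimensional information. When beam-sensitive
nanocrystals only allow one snapshot per crystal (serial electron
diffraction), each pattern comes from a different, randomly oriented
crystal, and no angular relationship between patterns is known. The question
this package answers is: given a handful of such *independent* zonal
patterns — each reduced to two reciprocal basis vectors and the angle
between them, i.e. a triple (d₁, d₂, φ) — what is the 3D unit cell?

## The model

Every zonal pattern is a 2D lattice: the central section of the reciprocal
lattice perpendicular to some zone axis [uvw]. The key premise of the grid
search is that *any* of the N patterns may be declared zone [001] of one
setting of the unknown cell. That fixes three of the six reciprocal
parameters — a\* = g_short, b\* = g_long and γ\* = φ of that pattern — and
leaves only the axis **c**\* unknown. **c**\* is parametrized by its
fractional in-plane components (ξ, η) along the pattern basis and by the
direct-cell volume V, which fixes its out-of-plane component ζ = 1/(A\* V)
(A\* is the reciprocal mesh area of the pattern; V/A is the interlayer
spacing). The scan runs in layers of constant V forming a geometric
progression V₁ = V_min, V_{i+1} = V_i (1 + f); the fractional increment
keeps the relative volume resolution constant across the range.

Each candidate (ξ, η, V) defines a trial cell. The trial is kept only if
every remaining pattern can be indexed against it: for each pattern, all
coprime zone axes up to `max_index` are enumerated once, the Lagrange-reduced
2D net of each zone is computed from an integer basis of the in-zone
sublattice (a constant-time reduction per zone, vectorized over all zones),
and the best-fitting zone is chosen. The mismatch of a pattern against a
zone net has three dimensionless components:

* ε_ratio — relative error of the basis-length ratio ρ = g_long/g_short,
* ε_angle — relative error of the canonical inter-vector angle,
* ε_scale — deviation of the per-pattern scale s_p (the mean of the two
  observed/predicted length ratios) from the dataset mean scale.

The per-pattern score is T_p = (ε_ratio/w₁ + ε_angle/w₂ + ε_scale/(k·w₃))/3
and the reliability index of a candidate is R = mean(T_p) over the N − 1
indexed patterns; the inverse figure of merit F_inv = 1/R is what
`fom_surface()` maps. A pattern is *accepted* when ε_ratio ≤ k·w₁,
ε_angle ≤ k·w₂ and ε_scale ≤ k·w₃.

### Why the scale component is treated separately

Absolute lengths in ED patterns are limited by the camera constant, which in
measured serial datasets jitters by 1–2 % from pattern to pattern, while the
*relative* quantities within one pattern (length ratio, angle) are good to a
few tenths of a percent. Two consequences are built in:

1. **Two-pass matching.** Zone selection happens before the dataset mean
   scale can be known, so the first pass scores only the shape (ratio and
   angle) and admits scales within a wide prior window (`s_window`, default
   ±4 %) around 1. The mean scale of the accepted patterns (the frame
   pattern enters with scale exactly 1) is then computed, and the mismatch
   components of the *kept* zones are re-evaluated against it once.
2. **Window-referenced scale in R.** In T_p the scale deviation is
   normalized by its acceptance window k·w₃ rather than by w₃. With the
   camera-constant scatter of real data, a w₃-normalized scale term would
   dominate R by an order of magnitude and can invert the ranking between
   the true cell and large-volume competitor cells (larger cells offer more
   zones and can absorb scale jitter into zone choice). Referencing the
   scale to its window keeps it informative without letting camera jitter
   outvote the geometry; on the bundled measured datasets this choice
   reproduces the expected rankings and R magnitudes of roughly 0.3–1.

### Symmetry-adapted scan dimensionality

The metric plane symmetry of the initial pattern (judged from lengths and
angle only, never intensities) restricts where **c**\* can lie:

* `p1` — full 3D scan over (ξ, η, V), with η ≥ 0 (Friedel symmetry).
* `pmm` — a true mirror forces **c**\* onto one of four mirror planes
  ξ = 0, ξ = ½, η = 0, η = ½: four 2D scans.
* `cmm` — the centred net restricts the scan to three planes expressed in
  the rectangular frame of the net (along each rectangle axis, plus the
  centring-shifted copy); both settings of cmm are recognized — equal basis
  lengths at any angle, and the centred-rectangular identity
  2 g_long cos φ = g_short.
* `p4`, `p6` — two 1D scans over V through (0,0) and (½,½), or (0,0) and
  (⅓,⅓).

Classification thresholds default to 1 % on lengths and 0.5° on angles,
checked from most to least restrictive (p4 > p6 > cmm > pmm > p1). These
defaults deliberately leave a pattern with a 2.1 % length difference
unassigned (p1) — imposing too much symmetry is the more dangerous error,
and a user label (e.g. `"2mm"`, `"cmm"`) can always override the automatic
class, as can forcing `mode = "3d"`.

### Grid resolution

Within a layer the Cartesian step is `step` (default 1/12) times the layer
resolution scale min(ζ(V), g₁, g₂). A fixed *fractional* step would
undersample badly whenever the pattern basis vectors are much longer than
ζ — exactly the situation of a high-index initial zone with one short
d-spacing — while the adaptive step keeps the sampling commensurate with the
acceptance windows in every geometry. Accuracy beyond the grid comes from
local refinement: each surviving candidate (after merging near-duplicates at
2 %/2° on their Delaunay-reduced cells) is polished by a derivative-free
minimization of R constrained to its scan manifold (V only for 1D scans; the
plane coordinate and V for 2D; ξ, η, V for 3D) and to within one grid step
and one volume increment of its starting point, so refinement cannot tunnel
onto a different solution. R never increases during refinement.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `f` | 0.025 | fractional volume increment between layers |
| `w1, w2, w3` | 0.008, 0.006, 0.003 | mismatch weights (ratio, angle, scale) |
| `k` | 5 | acceptance gate multiplier (windows k·wᵢ) |
| `s_window` | 0.04 | prior scale window of the first matching pass |
| `step` | 1/12 | in-plane grid step (fraction of the resolution scale) |
| `max_index` | 10 | largest zone-axis component enumerated |
| `hkl_max` | 12 | largest reduced Miller index admitted in a net |
| `h_min` | 3.4 Å | minimal interlayer spacing for the default V_min |

The weights are the empirically stable set used for all worked runs. The
gate multiplier was calibrated once, on the bundled measured tables, as the
smallest k for which each dataset's known final cell indexes all of its own
patterns: the per-pattern scale scatter of the lysozyme table (up to 1.4 %
about the dataset mean) requires k·w₃ ≥ 0.015, hence k = 5. A tighter gate
(k = 2–3) is appropriate for clean, well-calibrated data and shrinks the
solution list; the value is a user-facing knob of `match_weights()`.
V_min defaults to the smallest cell compatible with the initial zone — the
direct mesh area of the pattern times `h_min` — and should be overridden
when prior knowledge (e.g. a molecular volume) bounds the cell better.

## Delaunay reduction and conventional settings

Stored cells are reported in the Delaunay-reduced primitive setting: the
classical transformation on {**a**, **b**, **c**, −(**a**+**b**+**c**)} is
iterated until all six pairwise scalar products are non-positive, and the
basis is rebuilt from the three shortest of the seven Delaunay-derived
vectors, sign-normalized to the all-obtuse setting. Conventional (possibly
centred) settings are proposed by testing a catalogue of integer re-basing
transformations (entries up to |2|, L1 norm ≤ 4, determinant 1–4) against
the lattice systems within 2 %/2°; the winner is the highest-symmetry
system, ties broken by smaller conventional volume. Angles are reported as
computed — an 89.8° angle in a C-centred suggestion stays 89.8°, it is never
snapped to 90°. Monoclinic cells are returned b-unique with obtuse β, and an
A-centred monoclinic candidate is permuted to the C-centred setting.
Degenerate re-basings (any angle outside [55°, 125°]) are rejected as
conventional candidates, which bounds how oblique a proposed conventional
cell may be; a pathological lattice would then simply fall back to the
triclinic P reduced setting. Full Bravais-class assignment by the 24
Delaunay characters is out of scope — the centring symbol and lattice-system
guess are metric statements only.

## The synthetic generator

`simulate_patterns()` draws zones (preferring low |u|+|v|+|w|, optionally
resampling until they are non-coplanar), computes each zone's exact reduced
net under the generating cell and centring, and perturbs the descriptors
with independent Gaussian noise: multiplicative on each d-spacing
(`sigma_d`, relative) and additive on the angle (`sigma_phi`, degrees). A
seed fixes the zone draw and the noise. The generator emulates exactly what
the search consumes — (d₁, d₂, φ) triples — and its noise-free output is the
package's core correctness probe: a search over simulated patterns from
non-coplanar zones must return a cell equivalent to the generator at 1 %/1°.

What the generator does **not** emulate: excitation errors and slight
off-zone tilts (patterns are exact central sections), intensity effects,
peak-position noise within a pattern (noise is applied to the reduced
descriptor, not to peaks), or correlated camera-constant drift. Passing the
round-trip therefore validates the search geometry and bookkeeping, not
robustness to every physical artefact of real data; the bundled measured
tables cover part of that gap.

A deliberately degenerate configuration is also exercised: when all zone
axes are coplanar (a Vainshtein tilt series, e.g. patterns sharing one
reciprocal row), the 3D lattice is not determined — several inequivalent
cells index all patterns essentially perfectly. The test suite asserts this
*non-uniqueness* rather than failure, matching the geometry of the problem.

## Numerical choices and degenerate inputs

* Angles are exchanged in degrees and converted to radians internally; all
  pattern descriptors are folded to a canonical form (Lagrange-reduced 2D
  basis, g_short ≤ g_long, φ ∈ (0, 90]) before any comparison, which also
  absorbs the sign ambiguity of diffraction patterns (g and −g are
  indistinguishable).
* Zone in-plane sublattices get an exact integer kernel basis via extended
  gcd; centring reflection conditions are applied as index-2 or index-3
  sublattice restrictions of that basis, so forbidden reflections can never
  appear in a net.
* Ties in zone selection break deterministically (lowest |u|+|v|+|w|, then
  lexicographic); identical inputs give byte-identical ranked output.
* Delaunay iteration uses a relative tolerance of 1e-10 on the scalar
  products with a hard iteration cap; the reduction is volume-preserving to
  1e-9 relative and idempotent up to signed axis permutations.
* Pattern tables are validated row-by-row with line numbers in error
  messages; φ must lie strictly inside (0, 180) and d-spacings must be
  positive.

## Problem sizes

The worked runs on the bundled tables use the defaults above: the
seven-pattern full 3D scan evaluates ≈ 10³ candidates over 12 volume layers,
the pmm- and cmm-restricted 2D scans a few thousand line candidates over
~80 layers, and the 1D tetragonal scan a few hundred; each candidate
evaluation reduces the nets of all ≈ 3.8 × 10³ enumerated zones in a single
vectorized pass. The synthetic round-trip suite uses 20 random triclinic
cells with five zones drawn up to index 2 and a search bound of index 8 —
after re-basing to the initial zone's setting, the other patterns' zone
indices can legitimately exceed their generating bound, which is why the
search bound is larger.

## Known limitations

* The exact aggregation of the three mismatch components into R is a
  design choice of this package (the weights and the separation of camera
  constant from geometry are the load-bearing parts). Rankings of closely
  competing solutions (R within ~10–20 %) should be read together with the
  solution list and the F_inv surface, not as a hard verdict.
* Very anisotropic cells can push reduced net indices beyond `hkl_max`;
  such zones are treated as unmatchable rather than silently extended.
* The cmm scan-plane set is a geometric derivation validated on the worked
  centred-monoclinic runs; exotic centred settings may warrant `mode = "3d"`.
* Pattern exclusion is explicit (the `exclude` argument), never automatic:
  an alien pattern (contaminant, different polymorph) must be removed by
  the user, for reproducibility.

## A worked example

```{r example, eval = FALSE}
pats <- example_patterns("cupccl16")
fit <- cell_search(pats, v_min = 763, v_max = 1000, mode = "3d")
tidy(fit)       # ranked solutions: R, reduced cell, conventional setting
glance(fit)     # run diagnostics: layers, candidates, survivors
index_patterns(pats, solution_cell(fit, setting = "conventional"),
               centring = "C")
```
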