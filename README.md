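# zonecell

Unit-cell determination from a set of **independent, randomly oriented
electron-diffraction (ED) zonal patterns**.

## The problem

Electron wavelengths are so short that a single ED pattern is an
effectively flat central section of the reciprocal lattice: it shows a 2D
net and carries no 3D information. In serial electron diffraction each
beam-sensitive nanocrystal yields one such snapshot, in an unknown
orientation, so none of the angular bookkeeping of tilt-series methods is
available. Yet a handful of zonal patterns — each reduced to two basis
vector lengths and the angle between them, a triple (d₁, d₂, φ) — jointly
over-determine the 3D unit cell. `zonecell` recovers it, for
crystallographers and microscopists processing serial ED / microED data
without prior knowledge of the lattice.

## The method

Any pattern may be declared zone [001] of one setting of the unknown cell,
which fixes a\*, b\* and γ\*. The remaining axis **c**\* is scanned on a
grid: fractional in-plane components (ξ, η) and the cell volume V, swept in
layers V₍ᵢ₊₁₎ = Vᵢ(1 + f). Each candidate cell must index every remaining
pattern: over all coprime zone axes [uvw], the Lagrange-reduced 2D net of
each zone is compared with the pattern through three weighted relative
mismatches — basis-length ratio (w₁ = 0.008), angle (w₂ = 0.006) and
per-pattern scale against the dataset mean (w₃ = 0.003, the camera-constant
term). Candidates that index all patterns get a reliability index R (mean
weighted mismatch; F\_inv = 1/R is the figure-of-merit surface), are locally
refined, Delaunay-reduced, and reported together with a conventional
(possibly centred) setting. The metric plane symmetry of the initial
pattern (p1 / pmm / cmm / p4 / p6, judged from lengths and angle only)
reduces the scan from 3D to 2D mirror planes or 1D volume lines.

The package also provides basis-vector extraction from peak lists
(autocorrelation + least squares), elliptical-distortion correction, a
zonal-pattern "prominence" score, and a synthetic pattern generator for
validation; fitted searches expose `tidy()`, `glance()` and `autoplot()`
methods.

## A worked example

Seven measured zonal patterns of copper perchlorophthalocyanine
(CuPcCl₁₆, known C-centred monoclinic cell, V = 1750.1 Å³) are bundled:

```r
library(zonecell)
pats <- example_patterns("cupccl16")
fit  <- cell_search(pats, v_min = 763, v_max = 1000, mode = "3d")
fit
#> <cell_search> 3d scan, initial pattern 7 (p1)
#>   7 patterns, 12 layers, 1008 candidates, 123 surviving, 8 solutions
#>  rank      R     a     b     c alpha  beta gamma volume centring
#>     1 0.2293 3.761 15.29 15.60 111.7 92.77 93.71  829.3        C
#>     2 0.5956 4.027 15.29 15.59  68.0 90.65 93.31  888.0        P
#>     3 0.7381 3.728 15.34 15.59 111.6 92.00 95.98  822.2        P
#>     4 0.8106 3.926 15.26 15.59 112.0 91.38 91.27  865.9        P
#>     5 1.2032 4.556 15.26 15.61 111.9 93.40 90.28 1004.7        C
```

The rank-1 solution is the primitive reduced cell (3.76, 15.29, 15.60 Å,
111.7°, 92.8°, 93.7°), volume ≈ 829 Å³ — one molecule — and its conventional
setting is a C-centred monoclinic cell of twice that volume (≈ 1659 Å³,
β ≈ 95.3°), matching the reference structure to within the measurement
errors of the input patterns. The found cell then indexes all seven
patterns:

```r
index_patterns(pats, solution_cell(fit, setting = "conventional"),
               centring = "C")
# one row per pattern: zone [u v w], the two hkl, mismatch components,
# per-pattern scale, score T_p, accepted flag
```

`tidy(fit)` returns the full ranked solution table (reduced and
conventional settings), `glance(fit)` the run diagnostics, and with
`trace = TRUE`, `fom_surface(fit, ...)` / `autoplot()` map the inverse
figure of merit over a scan plane.

Two further bundled datasets exercise the symmetry-restricted scans:
`example_patterns("lysozyme")` (a fourfold [001] pattern → 1D scan;
tetragonal 79.1, 79.1, 38.2 Å) and `example_patterns("grgds")` (a cmm
pattern → 2D scan; C-centred monoclinic, conventional V ≈ 2391 Å³).

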