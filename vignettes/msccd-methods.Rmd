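---
title: "Contour shape retrieval with multiscale centroid distances: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour shape retrieval with multiscale centroid distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msccd)
```

## The problem

Silhouettes of leaves, organisms or objects in low-resolution imagery carry
almost no texture: classification and retrieval must work from the closed
outline alone. A practical outline descriptor has to be (i) invariant to
rotation, translation and uniform scale, (ii) insensitive to where along
the contour the tracing happened to start, (iii) cheap enough to match a
query against thousands of database shapes, and (iv) sensitive to *local*
differences — many biologically distinct outlines are globally similar and
differ only in a lobe, a spike or a notch.

`msccd` implements a family of descriptors built on the centroid contour
distance together with cyclic-shift and spectral matching rules and the
standard retrieval evaluation protocols, all exercised end-to-end on a
seeded synthetic shape generator.

## Model

### Sampling

Every contour is resampled to `Np = 2^t0 + 1` points at equal arc-length
spacing by linear interpolation along the closed polygon
(`resample_uniform()`). The power-of-two-plus-one count keeps the
multiscale windows below exact dyadic fractions of the contour. Default
`t0 = 9`, i.e. `Np = 513`; all index arithmetic is modulo `Np`. The first
sample is wherever the tracer started — descriptors must and do tolerate
this, because spatial matching minimizes over all cyclic shifts and
spectral matching uses shift-invariant DFT magnitudes.

### CCD

With centroid `p_m = mean(p_i)` and raw distances `d_uc(i) = |p_i - p_m|`,
the signature is `d_ccd(i) = d_uc(i) / mean_j d_uc(j)`. The mean-1
normalization makes the signature scale-invariant and gives the testable
invariant `mean(ccd) = 1`; a circle yields the constant signature 1 and a
purely DC spectrum. (The source equation for this normalization is printed
in two mutually inconsistent forms differing by a factor `Np^2`; we use the
mean-normalized form. Any global constant cancels in retrieval.)

### Dynamic centroids and MSCCD

At level `h` the *dynamic centroid* of sample `i` is the mean of the
`2^(t0-h)+1` samples with indices `i - 2^(t0-h-1) .. i + 2^(t0-h-1)`
(modulo `Np`). At `h = 0` the window spans the entire contour, so the
dynamic centroid is the global centroid and the level-0 row reduces
exactly to the CCD; each increment of `h` halves the window, turning the
row into a progressively more local curvature-like detector. Levels
`h = 0..H` (default `H = 6`, capped at `t0 - 1` and at 9) form the MSCCD
matrix.

**Per-level normalization (a deliberate design decision).** Each row is
normalized by its own mean: `d_dc(h,i) = d_udc(h,i) / mean_j d_udc(h,j)`.
The printed source formula instead divides every level by the *global*
sum `sum d_uc`. We implemented the printed form first
(`msccd(..., normalize = "global")`, still available) and found it
empirically untenable: fine-level distances are an order of magnitude
smaller than the CCD row under the global scale, so (a) the level-wise
difference between a clean shape and a locally perturbed copy *decreases*
with `h` for every perturbation we tried, directly contradicting the
study's central qualitative claim that local differences grow with `h`,
and (b) fine levels contribute almost nothing to the weighted matching
distance, which would make the reported sensitivity of retrieval scores to
`H` and to the level-weight exponent implausible. Per-level normalization
preserves every other stated property — the `h = 0` row still equals the
CCD exactly (the level-0 raw distances *are* the CCD distances), rows are
scale-invariant with mean 1 — and reproduces the expected behaviour: in
our measurements the level-wise L1 difference between bumped pairs grows
roughly four-fold per level. We read the printed denominator as a typesetting
slip (the source reuses the same index symbol on both sides of that
equation).

```{r bump}
base <- make_shape(shape_spec("ellipse"), t0 = 8)
bumped <- perturb_local(base, center_idx = 77, width = 8, amplitude = 0.08)
rowSums(abs(msccd(base, 4)$levels - msccd(bumped, 4)$levels))
```

### ASD

At interval (scale) `s`, the angle at `p_i` between the fore point
`p_{i+s}` and the rear point `p_{i-s}`, measured counterclockwise from the
fore vector to the rear vector via `atan2`, mapped to `[0, 2*pi)` and
divided by `2*pi`. For a counterclockwise convex polygon at `s = 1` this is
the interior vertex angle (a square corner gives 0.25). The reference
construction this descriptor descends from is not fully specified in the
source, so both the sign convention and the scale set are explicit,
configurable choices here; the default scale set `{2^(t0-h-1) : h = 1..H}`
mirrors the multiscale half-windows.

### Spectra: FCCD, FMSCCD, FASD

Each spatial row is transformed by the normalized DFT magnitude
`F(k) = |sum_i x_i e^(-2*pi*i*j*k/Np)| / Np` and truncated to
`k = 0..K` (default `K = 50`, i.e. 51 coefficients per level). Magnitudes
are invariant under cyclic shifts, so the spectra are start-point
invariant; truncation keeps the coarse-to-medium frequency content that is
stable under resampling noise.

### Matching

* Spatial signatures: exhaustive minimization over all `Np` cyclic shifts
  of the Euclidean distance (one common shift across all MSCCD levels,
  since a start-point offset is a property of the contour, not of a
  level). Exhaustive search is exact and, at `Np <= 513`, cheap; the
  non-convexity that would motivate heuristic solvers is thereby moot.
* Spectra: weighted city-block distance
  `sum_h w_h sum_{k=0..K} |A(h,k) - B(h,k)|` with level weights
  `w_h = alpha_h / sum alpha`, `alpha_h = (1 - 0.1 h)^ew`. The weights
  decrease in `h` because fine levels are noise-sensitive; `ew` (default
  5) sharpens the decay. The exponent reading of the weight rule is forced:
  a multiplicative factor would cancel in the normalization.
* Fusion: `w_fmc d1/S1 + (1 - w_fmc) d2/S2` where `S1, S2` are the sums of
  all `Nd^2` matrix entries (diagonal zeros and both orderings included —
  whether self-pairs are excluded only rescales both terms equally, so we
  follow the printed double sums). Default `w_fmc = 4/6` fuses FMSCCD with
  FASD.

All distances are symmetric, nonnegative and zero on identical inputs, but
the min-over-shifts construction does not guarantee the triangle
inequality, and none is claimed: the matrices are pseudo-distances
consumed only by ranking.

## Evaluation protocols

* **Bulls-eye** (`bulls_eye()`): every shape queried against the full
  database *including itself*; same-class hits in the top `2 n_c` are
  summed and divided by `Nd * n_c`. Self-inclusion is the standard
  convention and is what makes the maximum `Nd * n_c` attainable.
* **Precision at recall** (`precision_at_recall()`): query excluded from
  its own ranking; for a recall fraction `f`, the target hit count is
  `m = round(f * n_c)`, and the per-query precision is `m / r_m` with
  `r_m` the rank of the `m`-th correct hit. With the query excluded only
  `n_c - 1` correct hits exist, so the 100 % recall point is clamped to
  `n_c - 1` and flagged in the output. Note that the raw (uninterpolated)
  precision defined this way is *not* necessarily non-increasing in recall
  for an individual query — hit pattern (miss, hit, hit) gives 1/2 then
  2/3 — so no such monotonicity is asserted; it holds trivially under
  perfect separation.
* **Top-k hits** (`topk_hits()`): query excluded; `c(r)` counts queries
  whose rank-`r` neighbour is a classmate.
* **Class statistics** (`class_stats()`): mean intra-class and inter-class
  dissimilarity over ordered off-diagonal pairs. The printed indicator
  would include self-pairs (forcing zeros into the intra mean); they are
  excluded here, and the "averages" that the source prints as raw double
  sums are implemented as means.

Ties in every ranking are broken by shape id order — stable and
reproducible.

## The synthetic world

`make_database()` generates all test inputs: a fixed palette of radial
(star-shaped) base outlines — ellipses, spiked stars, regular polygons,
superformula (Gielis) leaf/flower curves — with, per instance, a seeded
smooth radial noise field (harmonics 2–8, standard deviation = `noise` ×
mean radius), a random rotation, a uniform scale in `[0.5, 2]` and a
random start-index shift. Instance seeds derive from
`(seed, class, instance)`, so databases are bitwise reproducible and
stable under partial regeneration. Two palette classes are locally-bumped
twins of two others, emulating the regime that motivates the multiscale
construction: pairs that global signatures confuse and local detail must
separate.

Noise defaults were fixed once, before any criterion was run, as what we
consider realistic within-class silhouette variability: `0.05` (5 % of
mean radius, "moderate") for retrieval stress tests, `0.02` ("low") for
invariance-flavoured checks.

What the generator does **not** emulate: non-star-shaped outlines
(occlusions, overhangs — the polar construction cannot self-intersect but
also cannot fold), articulated or part-based variation, segmentation
artifacts, holes, and the long-tailed class structure of real image
databases. A green end-to-end test therefore establishes that the pipeline
ranks synthetic within-class variation above these between-class
differences — not that it matches any published score on MPEG-7, Swedish
Plant Leaf or Kimia 99, which are out of scope.

## Numerical choices and degenerate inputs

* Masks: largest 8-connected component, Moore-neighbour boundary tracing,
  orientation normalized to positive signed area; pixel centers are
  0-based, x rightward, y downward. Supported mask formats are PGM/PBM and
  delimited 0/1 matrices (no PNG/TIFF reader is available in the
  dependency budget). Rasterization for the reverse direction uses
  even-odd scanline filling.
* Resampling is linear on cumulative arc length; the first input vertex is
  kept as the first sample. Already-uniform tables with exactly `Np`
  points are loaded as-is by the CLI (resampling them again would move
  points, because chord gaps are not arc gaps).
* A contour whose points all coincide (zero centroid spread, or a
  zero-length level row) raises "degenerate contour" rather than emitting
  NaNs; empty masks raise "no foreground"; one- and two-pixel components
  raise "contour too small".
* `dft_magnitude()` uses the FFT; the contract is the magnitude values
  (verified against a naive transform to 1e-9), not the algorithm.
* Exhaustive shift search is a direct `O(Np^2)` scan — exact, and at
  `Np = 513` far below any runtime budget that matters here. An
  FFT-cross-correlation formulation was rejected only because exactness
  against the loop oracle is part of the acceptance surface.
* `H` is clamped to `min(H, t0 - 1)` at use sites so small-`t0`
  experiments do not error out under the default configuration.

## Known limitations

* CCD-family descriptors discard the direction of each point relative to
  the centroid; shapes that differ only by such direction information
  remain confusable, which is precisely the weakness the multiscale and
  angular channels mitigate but do not eliminate.
* Per-level normalization amplifies fine-scale noise along with fine-scale
  signal; the decreasing level weights are the counterweight, and `ew`/`H`
  should be lowered for very noisy contours.
* Only outer boundaries are described: holes and inner structure are
  ignored by construction.
* The combined distance's sum-normalizers depend on the database, so
  fused distances are comparable only within one database run.
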