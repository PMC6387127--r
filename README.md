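# msccd — multiscale centroid contour distance descriptors

`msccd` is an R toolkit for describing, matching and retrieving closed 2-D
silhouettes — leaf outlines, segmented organisms, object masks in
remote-sensing imagery — from their contours alone. It is aimed at
morphometrics and image-analysis workflows where objects carry little
texture and shape is the only usable signal.

## The descriptors

A contour is reduced to `Np = 2^t0 + 1` points at uniform arc-length
spacing (513 points at the default `t0 = 9`). From these the package
computes:

* **CCD** (centroid contour distance): the signature
  `d_ccd(i) = d(p_i, p_m) / mean_j d(p_j, p_m)`, the distance of each
  sample to the contour centroid `p_m`, normalized to mean 1 — invariant to
  rotation, translation and scale, but start-point covariant.
* **MSCCD** (multiscale CCD): at level `h = 0..H` each point is referred to
  its *dynamic centroid*, the mean of the `2^(t0-h)+1` neighbouring samples.
  At `h = 0` the window spans the whole contour and the row reduces exactly
  to the CCD; as `h` grows the window shrinks and the row becomes a local
  shape detector. Each row is normalized by its own mean, so local
  differences between two shapes grow with `h` instead of being swamped by
  the global geometry.
* **ASD** (angle-scale descriptor): at interval `s`, the angle at `p_i`
  between `p_{i+s}` and `p_{i-s}`, normalized to `[0, 1)`.
* **FCCD / FMSCCD / FASD**: the DFT magnitude spectra of the rows above,
  truncated to coefficients `k = 0..K` (default `K = 50`). Magnitudes are
  invariant under cyclic shifts, which removes the start-point dependence.

Matching uses either exhaustive cyclic-shift minimization for the spatial
signatures, `min_n || a - shift_n(b) ||`, or the weighted city-block
distance `sum_h w_h sum_k |A(h,k) - B(h,k)|` for the spectra, with level
weights `w_h ∝ (1 - 0.1 h)^ew` (default `ew = 5`). Two feature spaces are
fused as `w_fmc d1/S1 + (1 - w_fmc) d2/S2` with sum-normalizers `S1, S2`
(default `w_fmc = 4/6`, combining FMSCCD with FASD).

Retrieval quality is scored with the standard protocols: the bulls-eye
test (same-class hits in each query's top `2 n_c`), precision at fixed
recall points, per-rank top-k hit counts, and intra/inter-class distance
statistics.

## Worked example

All inputs are generated by the seeded synthetic-shape module (no downloads):
five shape classes × 10 instances with 5 % smooth radial noise, random
rotation, scale in [0.5, 2] and random start point. Two of the classes are
locally-bumped twins of two others, so global signatures genuinely confuse
them.

```r
library(msccd)
db  <- make_database(n_classes = 5, n_per_class = 10, noise = 0.05,
                     seed = 0, t0 = 9)
cfg <- match_config()   # t0=9 (Np=513), H=6, K=50, ew=5, w_fmc=4/6
as.numeric(bulls_eye(shape_distances(db, "fccd", cfg)))
#> [1] 0.994
dm <- shape_distances(db, "fmsccd+fasd", cfg)
as.numeric(bulls_eye(dm))
#> [1] 0.996
retrieve(dm, "c01_s01", top = 5)
#>   rank      id   label  distance   hit
#> 1    1 c02_s10 class02 0.0001436 FALSE
#> 2    2 c02_s04 class02 0.0001501 FALSE
#> 3    3 c01_s04 class01 0.0001516  TRUE
#> 4    4 c02_s06 class02 0.0001552 FALSE
#> 5    5 c02_s02 class02 0.0001623 FALSE
class_stats(dm)
#> <class_stats> intra mean 0.0002 (450 pairs), inter mean 0.0005 (2000 pairs)
```

The bulls-eye score of 0.996 means 498 of the 500 possible same-class hits
appear in the queries' top-20 lists. The retrieval table shows the designed
hard case at work: the nearest neighbours of an ellipse query include its
locally-bumped twin class (`class02`), yet enough classmates rank inside
the top 20 for the bulls-eye to stay near-perfect. The combined
FMSCCD+FASD matrix scores at least as well as FCCD alone (0.996 vs 0.994)
— the multiscale/angular channels recover part of what the global
signature misses.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "msccd", package = "msccd"))')
Rscript $CLI synth    --out db --classes 5 --per-class 10 --noise 0.05 --seed 0
Rscript $CLI match    --contours db --descriptor fmsccd+fasd --out dist.csv
Rscript $CLI evaluate --distances dist.csv --protocol bullseye --out report.json
Rscript $CLI retrieve --distances dist.csv --query c01_s01 --top 5
```

Flags `--t0 --H --K --ew --w_fmc` override a `--config config.json`.

## Documentation

The methods vignette (`vignettes/msccd-methods.Rmd`) describes the model,
the numerical choices, what the synthetic generator does and does not
emulate, and known limitations.
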