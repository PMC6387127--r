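# Spatial contour signatures (CCD, MSCCD, ASD) and their Fourier-magnitude
# spectra (FCCD, FMSCCD, FASD).
#
# Normalization convention: d_ccd(i) = d_uc(i) / mean_j d_uc(j), i.e.
# d_uc(i) * Np / sum(d_uc), so mean(CCD) == 1 and the feature is invariant
# to uniform scaling. All multiscale levels share this single global
# normalizer, so the h = 0 row reduces exactly to the CCD.

#' Global contour centroid
#'
#' Arithmetic mean of the `Np` sample points.
#'
#' @param contour a [sampled_contour()].
#' @return Numeric length-2 vector `(x, y)`.
#' @export
global_centroid <- function(contour) {
  stopifnot(inherits(contour, "sampled_contour"))
  colMeans(contour$points)
}

# unnormalized distances from each sample to the global centroid
centroid_distances <- function(contour) {
  pm <- global_centroid(contour)
  sqrt((contour$points[, 1L] - pm[1L])^2 + (contour$points[, 2L] - pm[2L])^2)
}

#' Centroid contour distance (CCD) signature
#'
#' Euclidean distance from each sample point to the global centroid,
#' normalized by the mean distance so that the signature has mean 1 and is
#' invariant to rotation, translation and uniform scaling. A cyclic shift of
#' the contour start cyclically shifts the signature.
#'
#' @param contour a [sampled_contour()].
#' @return An object of class `ccd_feature`: list with `values` (length `Np`)
#'   and `t0`.
#' @export
ccd <- function(contour) {
  duc <- centroid_distances(contour)
  s <- sum(duc)
  if (s <= 0) stopf("degenerate contour")
  structure(
    list(values = duc * contour$np / s, t0 = contour$t0),
    class = "ccd_feature"
  )
}

#' @export
print.ccd_feature <- function(x, ...) {
  cat(sprintf("<ccd_feature> Np = %d, range [%.4f, %.4f]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Dynamic (windowed) centroids at one scale level
#'
#' The dynamic centroid of point `i` at level `h` is the mean of the
#' `2^(t0-h) + 1` contour points with indices `i - 2^(t0-h-1)` ..
#' `i + 2^(t0-h-1)` (modulo `Np`). At `h = 0` the window spans the whole
#' contour and every dynamic centroid equals the global centroid; as `h`
#' grows the window shrinks and the centroid tracks local structure.
#'
#' @param contour a [sampled_contour()].
#' @param h integer level, `0 <= h <= t0 - 1`.
#' @return `Np` x 2 matrix of centroid coordinates.
#' @export
dynamic_centroids <- function(contour, h) {
  stopifnot(inherits(contour, "sampled_contour"))
  if (!is_count(h) || h < 0 || h > contour$t0 - 1L) stopf("invalid level")
  np <- contour$np
  half <- 2L^(contour$t0 - as.integer(h) - 1L)
  len <- 2L * half + 1L
  win_mean <- function(v) {
    ext <- c(v[(np - half + 1L):np], v, v[1:half])
    cs <- c(0, cumsum(ext))
    (cs[(len + 1L):(np + len)] - cs[1:np]) / len
  }
  cbind(x = win_mean(contour$points[, 1L]),
        y = win_mean(contour$points[, 2L]))
}

#' Multiscale CCD (MSCCD) feature
#'
#' Distances from each sample point to its dynamic centroid at levels
#' `h = 0..H`. With the default `normalize = "per_level"` each row is scaled
#' by `Np / sum_j d_udc(h, j)` — its own mean — so every level has mean 1,
#' the `h = 0` row equals the CCD exactly, and fine-level rows carry weight
#' comparable to the coarse ones (local differences between two shapes then
#' grow with `h`, the behaviour the multiscale construction exists for).
#' `normalize = "global"` instead divides every level by the single CCD
#' normalizer `sum(d_uc)`, which also reduces to CCD at `h = 0` but leaves
#' fine levels an order of magnitude smaller than the coarse ones; it is
#' provided for comparison (see the methods vignette for why per-level is
#' the default).
#'
#' @param contour a [sampled_contour()].
#' @param H maximum level; `0 < H <= min(t0 - 1, 9)`.
#' @param normalize `"per_level"` (default) or `"global"`, see above.
#' @return An object of class `msccd_feature`: list with `levels`
#'   (`(H+1)` x `Np` matrix, rows named `h0..hH`), `t0`, `H`.
#' @export
msccd <- function(contour, H, normalize = c("per_level", "global")) {
  stopifnot(inherits(contour, "sampled_contour"))
  normalize <- match.arg(normalize)
  if (!is_count(H) || H < 1 || H > min(contour$t0 - 1L, 9L)) stopf("invalid H")
  H <- as.integer(H)
  duc <- centroid_distances(contour)
  if (sum(duc) <= 0) stopf("degenerate contour")
  lv <- matrix(0, H + 1L, contour$np,
               dimnames = list(paste0("h", 0:H), NULL))
  for (h in 0:H) {
    dc <- dynamic_centroids(contour, h)
    dudc <- sqrt((contour$points[, 1L] - dc[, 1L])^2 +
                 (contour$points[, 2L] - dc[, 2L])^2)
    denom <- if (normalize == "per_level") sum(dudc) else sum(duc)
    if (denom <= 0) stopf("degenerate contour")
    lv[h + 1L, ] <- dudc * contour$np / denom
  }
  structure(list(levels = lv, t0 = contour$t0, H = H), class = "msccd_feature")
}

#' @export
print.msccd_feature <- function(x, ...) {
  cat(sprintf("<msccd_feature> levels h = 0..%d, Np = %d\n",
              x$H, ncol(x$levels)))
  invisible(x)
}

#' Normalized DFT magnitude of a real sequence
#'
#' `out[k+1] = |sum_i seq[i+1] exp(-2 pi i j k / N)| / N` for `k = 0..N-1`.
#' Magnitudes are invariant under cyclic shifts of the input, which is what
#' makes the spectral descriptors start-point invariant.
#'
#' @param x numeric vector.
#' @return Numeric vector of the same length.
#' @export
dft_magnitude <- function(x) {
  if (!length(x)) stopf("empty sequence")
  Mod(fft(x)) / length(x)
}

new_spectral_feature <- function(coeffs, K, kind) {
  structure(list(coeffs = coeffs, K = as.integer(K), kind = kind),
            class = "spectral_feature")
}

#' @export
print.spectral_feature <- function(x, ...) {
  cat(sprintf("<spectral_feature:%s> %d level(s) x %d coefficients (K = %d)\n",
              x$kind, nrow(x$coeffs), ncol(x$coeffs), x$K))
  invisible(x)
}

#' Fourier descriptors: FCCD, FMSCCD, FASD
#'
#' Apply [dft_magnitude()] to each row of the spatial feature and keep
#' coefficients `k = 0..K` (`K + 1` values per row). `fccd()` consumes a
#' [ccd()] feature (one row), `fmsccd()` an [msccd()] feature (rows
#' `h = 0..H`), `fasd()` an [asd()] feature (one row per scale). The result
#' is invariant to the contour's start point, rotation, translation and
#' uniform scale.
#'
#' @param feature a `ccd_feature`, `msccd_feature` or `asd_feature`.
#' @param K highest retained frequency index, `0 <= K <= Np - 1` (default 50).
#' @return A `spectral_feature`: list with `coeffs` (levels x `K + 1`
#'   matrix), `K` and `kind`.
#' @export
fccd <- function(feature, K = 50L) {
  stopifnot(inherits(feature, "ccd_feature"))
  np <- length(feature$values)
  if (!is_count(K) || K < 0 || K > np - 1L) stopf("invalid K")
  co <- matrix(dft_magnitude(feature$values)[1:(K + 1L)], nrow = 1L,
               dimnames = list("h0", NULL))
  new_spectral_feature(co, K, "fccd")
}

#' @rdname fccd
#' @export
fmsccd <- function(feature, K = 50L) {
  stopifnot(inherits(feature, "msccd_feature"))
  np <- ncol(feature$levels)
  if (!is_count(K) || K < 0 || K > np - 1L) stopf("invalid K")
  co <- t(apply(feature$levels, 1L, function(v) dft_magnitude(v)[1:(K + 1L)]))
  dimnames(co) <- list(rownames(feature$levels), NULL)
  new_spectral_feature(co, K, "fmsccd")
}

#' @rdname fccd
#' @export
fasd <- function(feature, K = 50L) {
  stopifnot(inherits(feature, "asd_feature"))
  np <- ncol(feature$angles)
  if (!is_count(K) || K < 0 || K > np - 1L) stopf("invalid K")
  co <- t(apply(feature$angles, 1L, function(v) dft_magnitude(v)[1:(K + 1L)]))
  dimnames(co) <- list(rownames(feature$angles), NULL)
  new_spectral_feature(co, K, "fasd")
}

#' Default ASD scale set
#'
#' Interval lengths `2^(t0-h-1)` for `h = 1..H`, mirroring the multiscale
#' dynamic-centroid half-windows.
#'
#' @param t0 sampling exponent.
#' @param H number of scales.
#' @return Integer vector of scales.
#' @export
asd_default_scales <- function(t0, H = 6L) {
  H <- min(as.integer(H), as.integer(t0) - 1L)
  as.integer(2^(as.integer(t0) - seq_len(H) - 1L))
}

#' Angle-scale descriptor (ASD)
#'
#' For each scale `s`, the angle at each contour point `p_i` between the fore
#' point `p_{i+s}` and the rear point `p_{i-s}` (indices modulo `Np`),
#' measured counterclockwise from the fore vector `p_{i+s} - p_i` to the rear
#' vector `p_{i-s} - p_i` and normalized to `[0, 1)` by dividing the angle in
#' `[0, 2*pi)` by `2*pi`. For a counterclockwise convex polygon at `s = 1`
#' this is the interior vertex angle (a square corner gives 0.25). Angles are
#' invariant to rotation, translation and uniform scaling.
#'
#' @param contour a [sampled_contour()].
#' @param scales integer vector of interval lengths, each in
#'   `1..(Np-1)/2`; defaults to [asd_default_scales()].
#' @return An object of class `asd_feature`: list with `angles`
#'   (`length(scales)` x `Np` matrix, rows named `s<scale>`) and `scales`.
#' @export
asd <- function(contour, scales = asd_default_scales(contour$t0)) {
  stopifnot(inherits(contour, "sampled_contour"))
  np <- contour$np
  scales <- as.integer(scales)
  if (!length(scales) || any(scales < 1L | scales > (np - 1L) %/% 2L))
    stopf("invalid ASD scale")
  x <- contour$points[, 1L]; y <- contour$points[, 2L]
  idx <- seq_len(np)
  ang <- matrix(0, length(scales), np,
                dimnames = list(paste0("s", scales), NULL))
  for (j in seq_along(scales)) {
    s <- scales[j]
    fw <- mod1(idx + s, np); bw <- mod1(idx - s, np)
    v1x <- x[fw] - x; v1y <- y[fw] - y   # fore vector
    v2x <- x[bw] - x; v2y <- y[bw] - y   # rear vector
    a <- atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
    ang[j, ] <- (a %% (2 * pi)) / (2 * pi)
  }
  structure(list(angles = ang, scales = scales), class = "asd_feature")
}

#' @export
print.asd_feature <- function(x, ...) {
  cat(sprintf("<asd_feature> scales {%s}, Np = %d\n",
              paste(x$scales, collapse = ", "), ncol(x$angles)))
  invisible(x)
}
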