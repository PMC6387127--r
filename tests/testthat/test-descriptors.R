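test_that("global_centroid is the plain mean and translates linearly", {
  pent <- exact_circle(2, radius = 2, center = c(3, -2))
  expect_equal(global_centroid(pent), c(x = 3, y = -2), tolerance = 1e-12)

  pts <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1))
  sc <- sampled_contour(pts, 2)
  expect_equal(unname(global_centroid(sc)), c(1, 1))

  sc2 <- transform_contour(sc, shift = c(5, -7))
  expect_equal(unname(global_centroid(sc2)), c(6, -6))
})

test_that("ccd matches the per-point oracle and its closed forms", {
  # circle: constant 1 regardless of radius
  expect_equal(ccd(exact_circle(5, radius = 7))$values, rep(1, 33))

  # 2:1 ellipse: maxima at major-axis, minima at minor-axis samples
  th <- 2 * pi * (0:16) / 17
  ell <- sampled_contour(cbind(2 * cos(th), sin(th)), 4)
  v <- ccd(ell)$values
  expect_equal(which.max(v), 1)            # theta = 0 on the major axis
  # minimum at the sample nearest a minor-axis endpoint (pi/2 or 3*pi/2)
  near_minor <- c(which.min(abs(th - pi / 2)), which.min(abs(th - 3 * pi / 2)))
  expect_true(which.min(v) %in% near_minor)

  # 5-point toy contour vs direct per-point computation
  pts <- rbind(c(0, 0), c(3, 1), c(4, 4), c(1, 5), c(-1, 2))
  sc <- sampled_contour(pts, 2)
  ctr <- colMeans(pts)
  duc <- apply(pts, 1, function(p) sqrt(sum((p - ctr)^2)))
  expect_equal(ccd(sc)$values, duc * 5 / sum(duc), tolerance = 1e-12)
  expect_equal(mean(ccd(sc)$values), 1, tolerance = 1e-9)

  # degenerate: all points coincide is impossible via constructors, but a
  # zero-spread contour must error
  expect_error(ccd(sampled_contour(matrix(1, 5, 2), 2)), "degenerate")
})

test_that("dynamic centroids reduce to the global centroid at h = 0 and match
           a brute-force window oracle", {
  sq <- square_contour(3)
  dc0 <- dynamic_centroids(sq, 0)
  gc <- global_centroid(sq)
  expect_lt(max(abs(sweep(dc0, 2, gc))), 1e-12)

  # brute-force window mean oracle at t0 = 3, h = 2
  np <- sq$np; t0 <- 3L; h <- 2L
  half <- 2^(t0 - h - 1)
  oracle <- t(vapply(seq_len(np), function(i) {
    idx <- ((i - half):(i + half) - 1) %% np + 1
    colMeans(sq$points[idx, , drop = FALSE])
  }, numeric(2)))
  expect_equal(unname(dynamic_centroids(sq, 2)), unname(oracle),
               tolerance = 1e-12)

  # circle: dynamic centroid lies on the ray center -> p_i for every level
  circ <- exact_circle(5, radius = 2, center = c(1, 1))
  for (h in 0:4) {
    dc <- dynamic_centroids(circ, h)
    rel_p <- sweep(circ$points, 2, c(1, 1))
    rel_c <- sweep(dc, 2, c(1, 1))
    cross <- rel_p[, 1] * rel_c[, 2] - rel_p[, 2] * rel_c[, 1]
    expect_lt(max(abs(cross)), 1e-9)
    # same side of the center (h = 0 gives an exact zero, allow fp jitter)
    expect_true(all(rowSums(rel_p * rel_c) >= -1e-12))
  }

  expect_error(dynamic_centroids(sq, 3), "invalid level")
  expect_error(dynamic_centroids(sq, -1), "invalid level")
})

test_that("msccd normalizations both reduce to the ccd at h = 0", {
  star <- make_shape(shape_spec("star", n_spikes = 7, amp = 0.25), t0 = 6)
  ms <- msccd(star, H = 4)
  expect_equal(ms$levels["h0", ], ccd(star)$values, tolerance = 1e-12)
  expect_true(all(ms$levels >= 0))
  # per-level (default): every row has mean 1
  expect_equal(unname(rowMeans(ms$levels)), rep(1, 5), tolerance = 1e-12)

  # printed global variant: every level divided by the single CCD normalizer
  msg <- msccd(star, H = 4, normalize = "global")
  expect_equal(msg$levels["h0", ], ccd(star)$values, tolerance = 1e-12)
  duc_sum <- sum(msccd:::centroid_distances(star))
  for (h in 1:4) {
    dc <- dynamic_centroids(star, h)
    dudc <- sqrt(rowSums((star$points - dc)^2))
    expect_equal(msg$levels[h + 1, ], dudc * star$np / duc_sum,
                 tolerance = 1e-12)
    # and the per-level row is the same row rescaled to mean 1
    expect_equal(ms$levels[h + 1, ], dudc / mean(dudc), tolerance = 1e-12)
  }

  # circle rows are constant at every level
  msc <- msccd(exact_circle(5), H = 3)
  for (h in 1:4) expect_lt(diff(range(msc$levels[h, ])), 1e-9)

  expect_error(msccd(star, H = 6), "invalid H")  # H > t0 - 1
  expect_error(msccd(star, H = 0), "invalid H")
})

test_that("dft_magnitude matches a naive DFT oracle and the shift theorem", {
  # constant sequence: DC-only
  out <- dft_magnitude(rep(3.5, 17))
  expect_equal(out[1], 3.5)
  expect_lt(max(out[-1]), 1e-12)

  set.seed(42)
  for (n in c(5, 9, 17, 33)) {
    x <- rnorm(n)
    expect_equal(dft_magnitude(x), naive_dft_mag(x), tolerance = 1e-9)
    sh <- sample(n - 1, 1)
    xs <- x[((seq_len(n) - 1 + sh) %% n) + 1]
    expect_equal(dft_magnitude(x), dft_magnitude(xs), tolerance = 1e-9)
  }
})

test_that("fccd / fmsccd / fasd truncate per-level spectra to K + 1 terms", {
  star <- make_shape(shape_spec("star"), t0 = 6)
  f1 <- fccd(ccd(star), K = 50)
  expect_equal(dim(f1$coeffs), c(1, 51))

  ms <- msccd(star, H = 3)
  f2 <- fmsccd(ms, K = 50)
  expect_equal(dim(f2$coeffs), c(4, 51))
  # each row is the truncated magnitude spectrum of that level
  for (h in 1:4)
    expect_equal(f2$coeffs[h, ], dft_magnitude(ms$levels[h, ])[1:51],
                 tolerance = 1e-12)
  # fccd equals the fmsccd restricted to its h = 0 row (absolute tolerance:
  # near-zero coefficients make relative comparison meaningless)
  expect_lt(max(abs(f1$coeffs[1, ] - f2$coeffs[1, ])), 1e-12)

  # circle: every spectrum is DC-only and DC = row mean
  circ <- exact_circle(5)
  fc <- fmsccd(msccd(circ, 2), K = 10)
  for (h in 1:3) {
    expect_equal(unname(fc$coeffs[h, 1]), mean(msccd(circ, 2)$levels[h, ]),
                 tolerance = 1e-9)
    expect_lt(max(fc$coeffs[h, -1]), 1e-9)
  }

  expect_error(fccd(ccd(star), K = 65), "invalid K")
})

test_that("asd angles follow the atan2 oracle and the square corner is 0.25", {
  sq <- square_contour(3)
  a <- asd(sq, scales = 1)
  # index 1 sits on the square's (0,0) corner; interior right angle
  expect_equal(unname(a$angles[1, 1]), 0.25, tolerance = 1e-9)

  # circle: constant row at every scale
  ac <- asd(exact_circle(5), scales = c(2, 4, 8))
  for (r in 1:3) expect_lt(diff(range(ac$angles[r, ])), 1e-9)
  expect_true(all(ac$angles >= 0 & ac$angles < 1))

  # random decagon-like contour vs explicit per-vertex oracle at s = 2
  set.seed(7)
  th <- sort(runif(17, 0, 2 * pi))
  sc <- sampled_contour(cbind((1 + 0.1 * rnorm(17)) * cos(th),
                              (1 + 0.1 * rnorm(17)) * sin(th)), 4)
  got <- asd(sc, scales = 2)$angles[1, ]
  np <- 17
  want <- vapply(seq_len(np), function(i) {
    f <- sc$points[((i + 2 - 1) %% np) + 1, ] - sc$points[i, ]
    r <- sc$points[((i - 2 - 1) %% np) + 1, ] - sc$points[i, ]
    (atan2(f[1] * r[2] - f[2] * r[1], f[1] * r[1] + f[2] * r[2]) %% (2 * pi)) /
      (2 * pi)
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(asd(sq, scales = 0), "invalid ASD scale")
  expect_error(asd(sq, scales = 5), "invalid ASD scale")  # > (Np-1)/2

  fa <- fasd(asd(sq, scales = c(1, 2)), K = 4)
  expect_equal(dim(fa$coeffs), c(2, 5))
})

test_that("descriptors are similarity-invariant and start-shift covariant", {
  set.seed(11)
  base <- make_shape(shape_spec("star", n_spikes = 6, amp = 0.2,
                                noise = 0.03, seed = 4), t0 = 6)
  tr <- transform_contour(base, angle = 1.2, scale = 0.31, shift = c(-2, 9))
  expect_equal(ccd(tr)$values, ccd(base)$values, tolerance = 1e-9)
  expect_equal(msccd(tr, 4)$levels, msccd(base, 4)$levels, tolerance = 1e-9)
  expect_equal(asd(tr)$angles, asd(base)$angles, tolerance = 1e-9)

  n <- 13
  shifted <- cyclic_shift_contour(base, n)
  np <- base$np
  perm <- ((seq_len(np) - 1 + n) %% np) + 1
  expect_equal(ccd(shifted)$values, ccd(base)$values[perm], tolerance = 1e-9)
  expect_equal(msccd(shifted, 3)$levels, msccd(base, 3)$levels[, perm],
               tolerance = 1e-9)
  expect_equal(asd(shifted)$angles, asd(base)$angles[, perm],
               tolerance = 1e-9)
  # spectra unchanged by the shift
  expect_equal(fmsccd(msccd(shifted, 3))$coeffs,
               fmsccd(msccd(base, 3))$coeffs, tolerance = 1e-9)
  expect_equal(fasd(asd(shifted))$coeffs, fasd(asd(base))$coeffs,
               tolerance = 1e-9)
})
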