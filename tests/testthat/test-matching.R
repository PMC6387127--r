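test_that("level_weights follows the power law, sums to 1 and decreases", {
  expect_equal(level_weights(0, 3), 1)

  w <- level_weights(1, 5)
  a <- c(1, 0.9^5)
  expect_equal(w, a / sum(a), tolerance = 1e-12)
  expect_lt(abs(w[1] - 0.62873), 1e-4)  # printed (truncated) value

  for (H in 0:9) {
    for (ew in 1:8) {
      w <- level_weights(H, ew)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      if (H > 0) expect_true(all(diff(w) < 0))
      expect_true(all(w > 0 & w <= 1))
    }
  }
  expect_error(level_weights(10, 5), "invalid H")
  expect_error(level_weights(3, 0), "invalid ew")
})

test_that("match_config validates and carries the standard defaults", {
  cfg <- match_config()
  expect_equal(cfg$t0, 9L)
  expect_equal(cfg$H, 6L)
  expect_equal(cfg$K, 50L)
  expect_equal(cfg$ew, 5)
  expect_equal(cfg$w_fmc, 4 / 6)
  expect_equal(cfg$w_levels, level_weights(6, 5))
  expect_error(match_config(w_fmc = 1.2), "invalid w_fmc")
  expect_error(match_config(H = 11), "invalid H")
})

test_that("dist_ccd_exhaustive equals the loop oracle and absorbs shifts", {
  mkf <- function(v) structure(list(values = v, t0 = 3L), class = "ccd_feature")
  set.seed(3)
  a <- mkf(runif(9)); b <- mkf(runif(9))

  expect_equal(dist_ccd_exhaustive(a, a), 0)
  bs <- mkf(a$values[((seq_len(9) - 1 + 4) %% 9) + 1])
  expect_equal(dist_ccd_exhaustive(a, bs), 0, tolerance = 1e-12)

  expect_equal(dist_ccd_exhaustive(a, b),
               oracle_ccd_dist(a$values, b$values), tolerance = 1e-14)
  # symmetry and the min property (<= any fixed-shift distance)
  expect_equal(dist_ccd_exhaustive(b, a), dist_ccd_exhaustive(a, b),
               tolerance = 1e-14)
  expect_lte(dist_ccd_exhaustive(a, b),
             sqrt(sum((a$values - b$values)^2)) + 1e-14)

  expect_error(dist_ccd_exhaustive(a, mkf(runif(17))), "incompatible")
})

test_that("dist_msccd_exhaustive applies one common shift across levels", {
  mkm <- function(m) structure(list(levels = m, t0 = 3L, H = nrow(m) - 1L),
                               class = "msccd_feature")
  set.seed(5)
  A <- mkm(matrix(runif(27), 3, 9))
  B <- mkm(matrix(runif(27), 3, 9))
  w <- level_weights(2, 5)

  expect_equal(dist_msccd_exhaustive(A, A, w), 0)
  # every level shifted by the same n -> 0
  perm <- ((seq_len(9) - 1 + 5) %% 9) + 1
  expect_equal(dist_msccd_exhaustive(A, mkm(A$levels[, perm]), w), 0,
               tolerance = 1e-12)
  expect_equal(dist_msccd_exhaustive(A, B, w),
               oracle_msccd_dist(A$levels, B$levels, w), tolerance = 1e-14)
  expect_equal(dist_msccd_exhaustive(B, A, w),
               dist_msccd_exhaustive(A, B, w), tolerance = 1e-14)

  expect_error(dist_msccd_exhaustive(A, mkm(matrix(1, 2, 9)), w),
               "incompatible")
})

test_that("dist_spectral is the weighted city-block sum over k = 0..K", {
  mks <- function(m, kind = "fmsccd")
    msccd:::new_spectral_feature(m, ncol(m) - 1L, kind)

  # H = 0, all 51 coefficients differing by 0.1 -> 5.1 (plain Eq-6 distance)
  a <- mks(matrix(1, 1, 51), "fccd")
  b <- mks(matrix(1.1, 1, 51), "fccd")
  expect_equal(dist_spectral(a, b), 5.1)
  expect_equal(dist_spectral(a, a), 0)

  set.seed(9)
  A <- mks(matrix(runif(3 * 51), 3, 51))
  B <- mks(matrix(runif(3 * 51), 3, 51))
  w <- level_weights(2, 5)
  expect_equal(dist_spectral(A, B, w),
               oracle_spectral_dist(A$coeffs, B$coeffs, w), tolerance = 1e-12)
  # default weights for multiscale spectra are the level weights
  expect_equal(dist_spectral(A, B), dist_spectral(A, B, w), tolerance = 1e-12)

  expect_error(dist_spectral(a, mks(matrix(1, 1, 11), "fccd")), "incompatible")
})

test_that("combined_distance mixes sum-normalized matrices", {
  ids <- c("a", "b", "c"); labs <- c("x", "x", "y")
  d1 <- distance_matrix(rbind(c(0, 1, 2), c(1, 0, 3), c(2, 3, 0)), ids, labs)
  d2 <- distance_matrix(rbind(c(0, 4, 1), c(4, 0, 2), c(1, 2, 0)), ids, labs)

  # hand oracle: S1 = 12, S2 = 14
  w <- 0.25
  want <- w * d1$values / 12 + (1 - w) * d2$values / 14
  got <- combined_distance(d1, d2, w)
  expect_equal(got$values, want)

  # identical inputs: proportional to d1 with factor 1/S1 for any w_fmc
  same <- combined_distance(d1, d1, 4 / 6)
  expect_equal(same$values, d1$values / 12, tolerance = 1e-12)

  d3 <- distance_matrix(d2$values, c("a", "b", "z"), labs)
  expect_error(combined_distance(d1, d3, 0.5), "incompatible")
  expect_error(combined_distance(d1, d2, 1.5), "invalid w_fmc")
})

test_that("distance matrices validate and round-trip through CSV", {
  ids <- sprintf("s%d", 1:4)
  labs <- c("A", "A", "B", "B")
  v <- abs(outer(c(0, 1, 5, 6), c(0, 1, 5, 6), "-"))
  dm <- distance_matrix(v, ids, labs)
  f <- tempfile(fileext = ".csv")
  write_distance_matrix(dm, f)
  back <- read_distance_matrix(f)
  expect_identical(back$values, dm$values)
  expect_identical(back$ids, dm$ids)
  expect_identical(back$labels, dm$labels)

  expect_error(distance_matrix(v[1:3, ], ids[1:3], labs[1:3]), "square")
  bad <- v; bad[1, 2] <- 99
  expect_error(distance_matrix(bad, ids, labs), "symmetric")
})

test_that("start-shift of one contour leaves retrieval distances stable", {
  sc <- make_shape(shape_spec("star", n_spikes = 5, amp = 0.3,
                              noise = 0.02, seed = 2), t0 = 6)
  other <- make_shape(shape_spec("ellipse"), t0 = 6)
  sh <- cyclic_shift_contour(sc, 17)

  f0 <- fmsccd(msccd(sc, 4), 30); f1 <- fmsccd(msccd(sh, 4), 30)
  fo <- fmsccd(msccd(other, 4), 30)
  expect_lt(abs(dist_spectral(f0, fo) - dist_spectral(f1, fo)), 1e-9)

  c0 <- ccd(sc); c1 <- ccd(sh); co <- ccd(other)
  expect_lt(abs(dist_ccd_exhaustive(c0, co) - dist_ccd_exhaustive(c1, co)),
            1e-9)
})
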