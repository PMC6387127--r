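# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain elementwise loops / closed forms, independent of the vectorized
# implementation paths they check.

# circle with samples exactly on the analytic circle (equal angle = equal arc)
exact_circle <- function(t0, radius = 1, center = c(0, 0), phase = 0) {
  np <- 2L^t0 + 1L
  th <- phase + 2 * pi * (seq_len(np) - 1) / np
  sampled_contour(cbind(x = center[1] + radius * cos(th),
                        y = center[2] + radius * sin(th)), t0)
}

# axis-aligned square traversed counterclockwise, corners on samples (t0 >= 2)
square_contour <- function(t0, side = 1) {
  np <- 2L^t0 + 1L
  # walk the square perimeter at uniform arc length; np = 2^t0+1 does not
  # divide 4 evenly, so place points by arc position directly
  s <- 4 * side * (seq_len(np) - 1) / np
  xy <- t(vapply(s, function(si) {
    e <- si %/% side; f <- si %% side
    switch(as.integer(e) + 1L,
           c(f, 0), c(side, f), c(side - f, side), c(0, side - f))
  }, numeric(2)))
  sampled_contour(cbind(x = xy[, 1], y = xy[, 2]), t0)
}

rotate_pts <- function(pts, angle) {
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2)
  out <- pts %*% R
  colnames(out) <- c("x", "y")
  out
}

transform_contour <- function(sc, angle = 0, scale = 1, shift = c(0, 0)) {
  pts <- rotate_pts(sc$points, angle) * scale
  pts <- sweep(pts, 2, shift, "+")
  sampled_contour(pts, sc$t0)
}

cyclic_shift_contour <- function(sc, n) {
  np <- sc$np
  sampled_contour(sc$points[((seq_len(np) - 1 + n) %% np) + 1, ], sc$t0)
}

# naive DFT magnitude oracle: explicit sum over samples for each frequency
naive_dft_mag <- function(x) {
  n <- length(x)
  i <- 0:(n - 1)
  vapply(0:(n - 1), function(k) {
    ang <- -2 * pi * i * k / n
    sqrt(sum(x * cos(ang))^2 + sum(x * sin(ang))^2) / n
  }, numeric(1))
}

# exhaustive cyclic-shift distance oracle, elementwise loops
oracle_ccd_dist <- function(a, b) {
  np <- length(a)
  best <- Inf
  for (n in 0:(np - 1)) {
    s <- 0
    for (i in seq_len(np)) {
      j <- ((i + n - 1) %% np) + 1
      s <- s + (a[i] - b[j])^2
    }
    best <- min(best, sqrt(s))
  }
  best
}

# multiscale exhaustive oracle: common shift across levels, triple loop
oracle_msccd_dist <- function(A, B, w) {
  np <- ncol(A)
  best <- Inf
  for (n in 0:(np - 1)) {
    tot <- 0
    for (h in seq_len(nrow(A))) {
      s <- 0
      for (i in seq_len(np)) {
        j <- ((i + n - 1) %% np) + 1
        s <- s + (A[h, i] - B[h, j])^2
      }
      tot <- tot + w[h] * s
    }
    best <- min(best, sqrt(tot))
  }
  best
}

# weighted city-block spectral oracle, triple loop
oracle_spectral_dist <- function(A, B, w) {
  tot <- 0
  for (h in seq_len(nrow(A)))
    for (k in seq_len(ncol(A)))
      tot <- tot + w[h] * abs(A[h, k] - B[h, k])
  tot
}

# distance matrix from 1-D positions: d(i,j) = |p_i - p_j|
line_distance_matrix <- function(pos, labels, ids = as.character(seq_along(pos))) {
  distance_matrix(abs(outer(pos, pos, "-")), ids, labels)
}

# hand-checkable 6-shape, 2-class fixture used across evaluation tests:
# class A at positions 0, 1, 2; class B at 2.5, 10, 11 (B1 intrudes into A)
eval_fixture <- function() {
  line_distance_matrix(c(0, 1, 2, 2.5, 10, 11),
                       c("A", "A", "A", "B", "B", "B"))
}

# perfectly separated 3-class x 4-shape fixture
perfect_fixture <- function() {
  pos <- c(0, 0.1, 0.2, 0.3, 10, 10.1, 10.2, 10.3, 20, 20.1, 20.2, 20.3)
  line_distance_matrix(pos, rep(c("A", "B", "C"), each = 4))
}
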