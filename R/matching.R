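# Pairwise dissimilarities: exhaustive cyclic-shift spatial distances,
# weighted city-block spectral distances, level weights and the combined
# weighted distance for descriptor fusion.

#' Multiscale level weights
#'
#' `alpha_h = (1 - 0.1 h)^ew` for `h = 0..H`, normalized to sum to 1. The
#' weights decrease with `h` because finer-scale signatures are more easily
#' disturbed by contour noise.
#'
#' @param H maximum level, `0 <= H <= 9`.
#' @param ew positive weight exponent (default 5).
#' @return Numeric vector `w_0..w_H`, summing to 1, strictly decreasing.
#' @examples
#' level_weights(1, 5)  # c(0.6287, 0.3713)
#' @export
level_weights <- function(H, ew = 5) {
  if (!is_count(H) || H < 0 || H > 9) stopf("invalid H")
  if (!is.numeric(ew) || length(ew) != 1L || ew <= 0) stopf("invalid ew")
  alpha <- (1 - 0.1 * (0:H))^ew
  alpha / sum(alpha)
}

#' Matching configuration
#'
#' Bundles the operating parameters of the descriptor pipeline. Defaults are
#' the standard operating point: `t0 = 9` (`Np = 513`), `H = 6`, `ew = 5`,
#' `K = 50`, combination weight `w_fmc = 4/6`.
#'
#' @param t0 sampling exponent (`Np = 2^t0 + 1`).
#' @param H maximum multiscale level (clamped to `t0 - 1` at use sites).
#' @param K highest retained spectral coefficient index.
#' @param ew weight exponent for [level_weights()].
#' @param w_fmc weight of the multiscale spectral distance when combined with
#'   a second feature space, in (0, 1).
#' @param asd_scales optional integer vector of ASD scales; `NULL` means
#'   [asd_default_scales()]`(t0, H)`.
#' @return An object of class `match_config` with the fields above plus
#'   `w_levels = level_weights(H, ew)`.
#' @export
match_config <- function(t0 = 9L, H = 6L, K = 50L, ew = 5, w_fmc = 4 / 6,
                         asd_scales = NULL) {
  if (!is_count(t0) || t0 < 1) stopf("invalid t0")
  if (!is_count(H) || H < 0 || H > 9) stopf("invalid H")
  if (!is_count(K) || K < 0 || K > 2^t0) stopf("invalid K")
  if (!is.numeric(w_fmc) || w_fmc <= 0 || w_fmc >= 1) stopf("invalid w_fmc")
  cfg <- list(t0 = as.integer(t0), H = as.integer(H), K = as.integer(K),
              ew = ew, w_fmc = w_fmc,
              asd_scales = if (is.null(asd_scales)) NULL
                           else as.integer(asd_scales),
              w_levels = level_weights(H, ew))
  structure(cfg, class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  cat(sprintf("<match_config> t0=%d (Np=%d), H=%d, K=%d, ew=%g, w_fmc=%.4g\n",
              x$t0, 2^x$t0 + 1, x$H, x$K, x$ew, x$w_fmc))
  invisible(x)
}

# squared distances between a and every cyclic shift of b; returns the
# vector over shifts n = 0..Np-1 where shift n aligns a[i] with b[i+n]
shift_sq_dists <- function(a, b) {
  np <- length(a)
  vapply(0:(np - 1L), function(n) {
    sum((a - b[mod1(seq_len(np) + n, np)])^2)
  }, numeric(1))
}

#' Exhaustive cyclic-shift CCD distance
#'
#' Minimum over all `Np` cyclic start-point shifts of the Euclidean distance
#' between two CCD signatures. Symmetric; zero when one signature is a cyclic
#' shift of the other.
#'
#' @param a,b `ccd_feature` objects with equal `Np`.
#' @return Nonnegative scalar.
#' @export
dist_ccd_exhaustive <- function(a, b) {
  stopifnot(inherits(a, "ccd_feature"), inherits(b, "ccd_feature"))
  if (length(a$values) != length(b$values)) stopf("incompatible features")
  sqrt(min(shift_sq_dists(a$values, b$values)))
}

#' Exhaustive cyclic-shift multiscale distance
#'
#' Minimum over all `Np` shifts `n` of
#' `sqrt(sum_h w_h sum_i (a[h,i] - b[h,i+n])^2)`, the same shift applied to
#' every level (one start-point offset describes one contour).
#'
#' @param a,b `msccd_feature` objects with equal `Np` and `H`.
#' @param weights level weights `w_0..w_H`; defaults to
#'   [level_weights()]`(H, ew = 5)`.
#' @return Nonnegative scalar.
#' @export
dist_msccd_exhaustive <- function(a, b, weights = NULL) {
  stopifnot(inherits(a, "msccd_feature"), inherits(b, "msccd_feature"))
  if (!identical(dim(a$levels), dim(b$levels))) stopf("incompatible features")
  H <- a$H
  if (is.null(weights)) weights <- level_weights(H)
  if (length(weights) != H + 1L) stopf("incompatible weights")
  tot <- 0
  for (h in 0:H) {
    tot <- tot + weights[h + 1L] *
      shift_sq_dists(a$levels[h + 1L, ], b$levels[h + 1L, ])
  }
  sqrt(min(tot))
}

#' Weighted city-block spectral distance
#'
#' `sum_h w_h sum_{k=0..K} |a[h,k] - b[h,k]|`. With a single level this is
#' the plain FCCD city-block distance; with multiple levels it is the
#' weighted multiscale (FMSCCD) distance; applied per scale row it also
#' serves FASD matching.
#'
#' @param a,b `spectral_feature` objects with identical dimensions.
#' @param weights per-row weights; defaults to [level_weights()] for
#'   `fccd`/`fmsccd` features and uniform `1/n_rows` for `fasd`.
#' @return Nonnegative scalar.
#' @export
dist_spectral <- function(a, b, weights = NULL) {
  stopifnot(inherits(a, "spectral_feature"), inherits(b, "spectral_feature"))
  if (!identical(dim(a$coeffs), dim(b$coeffs))) stopf("incompatible features")
  nr <- nrow(a$coeffs)
  if (is.null(weights)) {
    weights <- if (a$kind %in% c("fccd", "fmsccd")) level_weights(nr - 1L)
               else rep(1 / nr, nr)
  }
  if (length(weights) != nr) stopf("incompatible weights")
  sum(weights * rowSums(abs(a$coeffs - b$coeffs)))
}

#' Distance matrix with shape identity
#'
#' @param values symmetric nonnegative `Nd` x `Nd` matrix with zero diagonal.
#' @param ids character shape identifiers.
#' @param labels class labels (coerced to character).
#' @return An object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, ids, labels) {
  values <- as.matrix(values)
  nd <- nrow(values)
  if (nd < 2L || ncol(values) != nd) stopf("distance matrix must be square, Nd >= 2")
  ids <- as.character(ids); labels <- as.character(labels)
  if (length(ids) != nd || length(labels) != nd)
    stopf("ids/labels must have length Nd")
  if (anyDuplicated(ids)) stopf("shape ids must be unique")
  if (any(values < 0)) stopf("distances must be nonnegative")
  if (max(abs(values - t(values))) > 1e-9) stopf("distance matrix not symmetric")
  if (any(abs(diag(values)) > 1e-12)) stopf("diagonal must be zero")
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids, labels = labels),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d shapes, %d classes\n",
              length(x$ids), length(unique(x$labels))))
  invisible(x)
}

#' All-pairs distance matrix from a feature list
#'
#' Applies a symmetric pairwise distance function to every unordered pair of
#' features and assembles a [distance_matrix()].
#'
#' @param features list of feature objects (one per shape).
#' @param ids,labels shape identifiers and class labels.
#' @param dist_fun function of two features returning a scalar.
#' @param ... passed on to `dist_fun`.
#' @return A [distance_matrix()].
#' @export
pairwise_distances <- function(features, ids, labels, dist_fun, ...) {
  nd <- length(features)
  vals <- matrix(0, nd, nd)
  for (i in seq_len(nd - 1L)) {
    for (j in (i + 1L):nd) {
      d <- dist_fun(features[[i]], features[[j]], ...)
      vals[i, j] <- d
      vals[j, i] <- d
    }
  }
  distance_matrix(vals, ids, labels)
}

#' Combined weighted dissimilarity of two feature spaces
#'
#' `w_fmc * d1 / S1 + (1 - w_fmc) * d2 / S2`, where `S1` and `S2` are the
#' sums of all `Nd^2` entries of the two matrices (the diagonal zeros and
#' both pair orderings included). The normalizers put the two spaces on a
#' common scale before mixing.
#'
#' @param d1,d2 [distance_matrix()] objects over the same ids/labels.
#' @param w_fmc mixing weight for `d1`, in (0, 1); default 4/6.
#' @return A [distance_matrix()].
#' @export
combined_distance <- function(d1, d2, w_fmc = 4 / 6) {
  stopifnot(inherits(d1, "distance_matrix"), inherits(d2, "distance_matrix"))
  if (!identical(d1$ids, d2$ids) || !identical(d1$labels, d2$labels))
    stopf("incompatible matrices")
  if (!is.numeric(w_fmc) || w_fmc <= 0 || w_fmc >= 1) stopf("invalid w_fmc")
  s1 <- sum(d1$values); s2 <- sum(d2$values)
  if (s1 <= 0 || s2 <= 0) stopf("degenerate distance matrix (all zeros)")
  distance_matrix(w_fmc * d1$values / s1 + (1 - w_fmc) * d2$values / s2,
                  d1$ids, d1$labels)
}

#' Read / write a distance matrix as a delimited table
#'
#' Square CSV with shape ids as header row and first column, plus a
#' `# labels:` comment line carrying the class labels.
#'
#' @param dm a [distance_matrix()].
#' @param path file path.
#' @return `read_distance_matrix()` returns a [distance_matrix()];
#'   `write_distance_matrix()` returns `path` invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# labels: %s", paste(dm$labels, collapse = ",")), con)
  writeLines(paste(c("id", dm$ids), collapse = ","), con)
  for (i in seq_along(dm$ids)) {
    writeLines(paste(c(dm$ids[i], sprintf("%.17g", dm$values[i, ])),
                     collapse = ","), con)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stopf("distance file not found: '%s'", path)
  lines <- readLines(path)
  lab_line <- grep("^# labels:", lines, value = TRUE)
  if (!length(lab_line)) stopf("missing '# labels:' line in '%s'", path)
  labels <- strsplit(sub("^# labels:\\s*", "", lab_line[1L]), ",")[[1L]]
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, sep = ",", header = TRUE,
                   check.names = FALSE, colClasses = c("character", rep(NA, length(labels))))
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  distance_matrix(vals, ids, labels)
}
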