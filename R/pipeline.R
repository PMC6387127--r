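# End-to-end glue: descriptor extraction over a database, distance-matrix
# assembly per descriptor choice, feature tables on disk, and contour
# rasterization for mask-based workflows.

descriptor_choices <- c("ccd", "fccd", "msccd", "fmsccd", "fasd", "fmsccd+fasd")

# H clamped so dynamic-centroid windows stay valid at the contour's t0
effective_H <- function(cfg, t0) min(cfg$H, as.integer(t0) - 1L)

#' Extract one descriptor for every contour of a database
#'
#' @param db a `shape_database` (see [make_database()]) or a list with
#'   elements `contours`, `ids`, `labels`.
#' @param descriptor one of `r toString(descriptor_choices)`; the combined
#'   `"fmsccd+fasd"` returns both feature lists.
#' @param cfg a [match_config()].
#' @return For single descriptors, a list of feature objects (one per
#'   shape); for `"fmsccd+fasd"`, a list with elements `fmsccd` and `fasd`.
#' @export
extract_features <- function(db, descriptor = "fmsccd", cfg = match_config()) {
  descriptor <- match.arg(descriptor, descriptor_choices)
  t0 <- db$contours[[1L]]$t0
  Hc <- effective_H(cfg, t0)
  scales <- if (is.null(cfg$asd_scales)) asd_default_scales(t0, Hc)
            else cfg$asd_scales
  one <- function(kind) {
    switch(kind,
      ccd = lapply(db$contours, ccd),
      fccd = lapply(db$contours, function(s) fccd(ccd(s), cfg$K)),
      msccd = lapply(db$contours, msccd, H = Hc),
      fmsccd = lapply(db$contours, function(s) fmsccd(msccd(s, Hc), cfg$K)),
      fasd = lapply(db$contours, function(s) fasd(asd(s, scales), cfg$K))
    )
  }
  if (descriptor == "fmsccd+fasd")
    list(fmsccd = one("fmsccd"), fasd = one("fasd"))
  else one(descriptor)
}

#' All-pairs dissimilarity matrix for a database
#'
#' Runs [extract_features()] and the matching rule appropriate to the
#' descriptor: exhaustive cyclic-shift distances for the spatial signatures
#' (`ccd`, `msccd`), weighted city-block distances for the spectra, and the
#' [combined_distance()] fusion for `"fmsccd+fasd"`.
#'
#' @inheritParams extract_features
#' @return A [distance_matrix()].
#' @export
shape_distances <- function(db, descriptor = "fmsccd", cfg = match_config()) {
  descriptor <- match.arg(descriptor, descriptor_choices)
  t0 <- db$contours[[1L]]$t0
  Hc <- effective_H(cfg, t0)
  w <- level_weights(Hc, cfg$ew)
  if (descriptor == "fmsccd+fasd") {
    d1 <- shape_distances(db, "fmsccd", cfg)
    d2 <- shape_distances(db, "fasd", cfg)
    return(combined_distance(d1, d2, cfg$w_fmc))
  }
  feats <- extract_features(db, descriptor, cfg)
  switch(descriptor,
    ccd = pairwise_distances(feats, db$ids, db$labels, dist_ccd_exhaustive),
    msccd = pairwise_distances(feats, db$ids, db$labels,
                               dist_msccd_exhaustive, weights = w),
    fccd = pairwise_distances(feats, db$ids, db$labels, dist_spectral,
                              weights = 1),
    fmsccd = pairwise_distances(feats, db$ids, db$labels, dist_spectral,
                                weights = w),
    fasd = pairwise_distances(feats, db$ids, db$labels, dist_spectral)
  )
}

# ---------------------------------------------------------------------------
# Feature tables: long delimited layout, one row per (id, level, k, value),
# with header comments carrying the feature kind and parameters.

feature_matrix <- function(f) {
  if (inherits(f, "ccd_feature"))
    list(kind = "ccd", mat = matrix(f$values, 1L, dimnames = list("h0", NULL)),
         meta = c(t0 = f$t0))
  else if (inherits(f, "msccd_feature"))
    list(kind = "msccd", mat = f$levels, meta = c(t0 = f$t0, H = f$H))
  else if (inherits(f, "asd_feature"))
    list(kind = "asd", mat = f$angles, meta = NULL)
  else if (inherits(f, "spectral_feature"))
    list(kind = f$kind, mat = f$coeffs, meta = c(K = f$K))
  else stopf("unsupported feature object")
}

#' Read / write feature tables
#'
#' Long CSV layout `id,level,k,value` (one row per coefficient; `level` is
#' the row name `h0..hH` or `s<scale>`, `k` the 0-based coefficient or
#' sample index) with `#`-comment header lines recording the feature kind
#' and parameters. Round trips losslessly at double precision.
#'
#' @param features list of feature objects (all the same kind).
#' @param ids shape identifiers, one per feature.
#' @param path file path.
#' @return `read_feature_table()` returns a list with `features` and `ids`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(features, ids, path) {
  stopifnot(length(features) == length(ids))
  fm <- feature_matrix(features[[1L]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# feature: %s", fm$kind), con)
  if (!is.null(fm$meta))
    writeLines(sprintf("# %s: %d", names(fm$meta), fm$meta), con)
  writeLines("id,level,k,value", con)
  for (i in seq_along(features)) {
    m <- feature_matrix(features[[i]])$mat
    for (r in seq_len(nrow(m))) {
      writeLines(sprintf("%s,%s,%d,%.17g", ids[i], rownames(m)[r],
                         seq_len(ncol(m)) - 1L, m[r, ]), con)
    }
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature file not found: '%s'", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kind <- sub("^# feature:\\s*", "", grep("^# feature:", hdr, value = TRUE))
  if (!length(kind)) stopf("missing '# feature:' line in '%s'", path)
  meta <- list()
  for (key in c("t0", "H", "K")) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(ln)) meta[[key]] <- as.integer(sub(sprintf("^# %s:\\s*", key), "", ln))
  }
  df <- read.table(text = lines[!grepl("^#", lines)], sep = ",", header = TRUE,
                   colClasses = c("character", "character", "integer", "numeric"))
  ids <- unique(df$id)
  features <- lapply(ids, function(id) {
    sub <- df[df$id == id, , drop = FALSE]
    levels <- unique(sub$level)
    mat <- do.call(rbind, lapply(levels, function(lv) {
      s <- sub[sub$level == lv, , drop = FALSE]
      s$value[order(s$k)]
    }))
    rownames(mat) <- levels
    switch(kind,
      ccd = structure(list(values = mat[1L, ], t0 = meta$t0),
                      class = "ccd_feature"),
      msccd = structure(list(levels = mat, t0 = meta$t0, H = meta$H),
                        class = "msccd_feature"),
      asd = structure(list(angles = mat,
                           scales = as.integer(sub("^s", "", levels))),
                      class = "asd_feature"),
      new_spectral_feature(mat, meta$K, kind)
    )
  })
  list(features = features, ids = ids, kind = kind)
}

# ---------------------------------------------------------------------------
# Rasterization (contour -> mask), for mask-based round trips and the synth
# CLI's optional mask output. Even-odd scanline polygon fill.

#' Rasterize a closed contour to a binary mask
#'
#' Scales the contour into a square pixel grid (preserving aspect ratio)
#' and fills its interior by even-odd scanline polygon filling.
#'
#' @param contour a [raw_contour()] or [sampled_contour()].
#' @param size grid side length in pixels.
#' @param margin background border in pixels.
#' @return A [binary_mask()] of dimension `size` x `size`.
#' @export
contour_to_mask <- function(contour, size = 64L, margin = 2L) {
  pts <- contour$points
  rng <- apply(pts, 2L, range)
  span <- max(rng[2L, ] - rng[1L, ])
  if (span <= 0) stopf("degenerate contour")
  scale <- (size - 1L - 2L * margin) / span
  px <- (pts[, 1L] - rng[1L, 1L]) * scale + margin
  py <- (pts[, 2L] - rng[1L, 2L]) * scale + margin
  n <- length(px)
  nxt <- c(2:n, 1L)
  m <- matrix(0L, size, size)
  for (row in seq_len(size)) {
    y0 <- row - 1
    cross <- (py <= y0) != (py[nxt] <= y0)
    if (!any(cross)) next
    i <- which(cross)
    xc <- px[i] + (y0 - py[i]) * (px[nxt[i]] - px[i]) / (py[nxt[i]] - py[i])
    xc <- sort(xc)
    for (j in seq(1L, length(xc) - 1L, by = 2L)) {
      lo <- ceiling(xc[j]); hi <- floor(xc[j + 1L])
      if (hi >= lo) m[row, (lo:hi) + 1L] <- 1L
    }
  }
  binary_mask(m)
}

#' Write a mask as an ASCII PGM (P2) file
#'
#' @param mask a [binary_mask()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mask_pgm <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", mask$width, mask$height), "255"), con)
  apply(mask$pixels * 255L, 1L, function(r)
    writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
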