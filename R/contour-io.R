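# Contour acquisition: binary masks -> traced boundary -> uniform resampling,
# plus plain-text contour tables.
#
# Coordinate convention: 0-based pixel centers, x rightward (column index),
# y downward (row index). Orientation is normalized to positive signed area.

#' Binary silhouette mask
#'
#' Construct a binary mask from an integer/logical matrix. Rows index y
#' (downward), columns index x (rightward); any nonzero entry is foreground.
#'
#' @param pixels matrix; nonzero/`TRUE` entries are foreground.
#' @return An object of class `binary_mask` with elements `pixels`
#'   (0/1 integer matrix), `height` and `width`.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:6, 3:6] <- 1L
#' binary_mask(m)
#' @export
binary_mask <- function(pixels) {
  if (!is.matrix(pixels)) stopf("`pixels` must be a matrix")
  px <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  if (!any(px == 1L)) stopf("no foreground")
  structure(
    list(pixels = px, height = nrow(px), width = ncol(px)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground\n",
              x$height, x$width, sum(x$pixels)))
  invisible(x)
}

#' Raw traced contour
#'
#' An ordered closed polygon of (x, y) points, as produced by
#' [trace_contour()] or read from a table. The closing edge from the last
#' point back to the first is implicit.
#'
#' @param points two-column numeric matrix (or data frame) of x, y.
#' @param closed logical; only closed contours are supported downstream.
#' @return An object of class `raw_contour`.
#' @export
raw_contour <- function(points, closed = TRUE) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stopf("contour must have 2 columns, got %d", ncol(pts))
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  if (nrow(pts) >= 2L && all(pts[1L, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]   # drop explicit closing duplicate
  if (nrow(pts) < 3L) stopf("contour too small")
  if (!all(is.finite(pts))) stopf("contour contains non-finite coordinates")
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1L), , drop = FALSE])^2))
  if (any(d == 0)) stopf("consecutive contour points must be distinct")
  structure(list(points = pts, closed = isTRUE(closed)), class = "raw_contour")
}

#' @export
print.raw_contour <- function(x, ...) {
  cat(sprintf("<raw_contour> %d points, %s\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Uniformly resampled closed contour
#'
#' The canonical input to all descriptors: exactly `Np = 2^t0 + 1` points at
#' equal arc-length spacing along a closed contour. Index arithmetic is
#' modulo `Np`. Usually produced by [resample_uniform()] or [make_shape()].
#'
#' @param points `Np` x 2 numeric matrix of x, y.
#' @param t0 positive integer sampling exponent, `Np = 2^t0 + 1`.
#' @return An object of class `sampled_contour`.
#' @export
sampled_contour <- function(points, t0) {
  if (!is_count(t0) || t0 < 1) stopf("invalid t0")
  t0 <- as.integer(t0)
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stopf("contour must have 2 columns, got %d", ncol(pts))
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  np <- 2L^t0 + 1L
  if (nrow(pts) != np)
    stopf("sampled contour must have 2^t0+1 = %d points, got %d", np, nrow(pts))
  if (!all(is.finite(pts))) stopf("contour contains non-finite coordinates")
  structure(list(points = pts, t0 = t0, np = np), class = "sampled_contour")
}

#' @export
print.sampled_contour <- function(x, ...) {
  cat(sprintf("<sampled_contour> Np = %d (t0 = %d)\n", x$np, x$t0))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Mask reading

# Tokenize a PGM/PBM header+ASCII body, honoring '#' comments.
pnm_ascii_tokens <- function(raw) {
  txt <- rawToChar(raw)
  txt <- gsub("#[^\n]*", " ", txt)
  scan(text = txt, what = character(), quiet = TRUE)
}

read_pnm <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (magic %in% c("P1", "P2")) {
    tok <- pnm_ascii_tokens(raw)
    nhead <- if (magic == "P1") 3L else 4L
    hd <- as.integer(tok[2:nhead])
    w <- hd[1L]; h <- hd[2L]
    vals <- as.integer(tok[(nhead + 1L):length(tok)])
    if (length(vals) < w * h) stopf("truncated PGM pixel data in '%s'", path)
    vals <- vals[seq_len(w * h)]
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P5") {
    # parse header tokens byte-wise: magic, width, height, maxval
    i <- 3L; tokens <- integer(0)
    n <- length(raw)
    while (length(tokens) < 3L && i <= n) {
      ch <- rawToChar(raw[i])
      if (ch == "#") { while (i <= n && rawToChar(raw[i]) != "\n") i <- i + 1L }
      else if (grepl("[0-9]", ch)) {
        num <- ""
        while (i <= n && grepl("[0-9]", rawToChar(raw[i]))) {
          num <- paste0(num, rawToChar(raw[i])); i <- i + 1L
        }
        tokens <- c(tokens, as.integer(num))
      } else i <- i + 1L
    }
    i <- i + 1L  # single whitespace after maxval
    w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
    bytes <- if (maxval < 256L) 1L else 2L
    body <- raw[i:n]
    if (length(body) < w * h * bytes) stopf("truncated PGM pixel data in '%s'", path)
    vals <- readBin(body, "integer", n = w * h, size = bytes,
                    signed = FALSE, endian = "big")
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    stopf("unsupported PNM magic '%s' in '%s'", magic, path)
  }
}

#' Read a binary mask from file
#'
#' Supported formats: PGM/PBM (`P1`, `P2` ASCII or `P5` binary; extension
#' `.pgm`/`.pbm`) and delimited numeric matrices (`.csv`, `.tsv`, `.txt`;
#' one row per pixel row, no header). Nonzero pixels are foreground.
#'
#' @param path file path.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("mask file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("pgm", "pbm", "pnm")) {
    read_pnm(path)
  } else if (ext %in% c("csv", "tsv", "txt", "")) {
    sep <- if (ext == "csv") "," else ""
    as.matrix(read.table(path, sep = sep, header = FALSE))
  } else {
    stopf("unsupported mask format '.%s' (use PGM/PBM or CSV/TSV)", ext)
  }
  binary_mask(px)
}

# ---------------------------------------------------------------------------
# Largest 8-connected component + Moore boundary tracing

# Returns a logical matrix selecting the largest 8-connected foreground
# component. Iterative stack-based fill; masks are padded internally.
largest_component <- function(px) {
  h <- nrow(px); w <- ncol(px)
  # pad with background so neighbor offsets never fall off the grid
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- px != 0
  hp <- nrow(m)
  offs <- c(-1L, 1L, -hp, hp, -hp - 1L, -hp + 1L, hp - 1L, hp + 1L)
  lab <- integer(length(m))
  cur <- 0L
  fg <- which(m)
  best_lab <- 0L; best_size <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    lab[s] <- cur
    size <- 0L
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      nb <- p + offs
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) { lab[nb] <- cur; stack <- c(stack, nb) }
    }
    if (size > best_size) { best_size <- size; best_lab <- cur }
  }
  keep <- matrix(lab == best_lab, hp, ncol(m)) & m
  keep[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}

#' Trace the outer boundary of a mask
#'
#' Selects the largest 8-connected foreground component and follows its outer
#' boundary with Moore-neighbour tracing. The result is an ordered closed
#' polygon of boundary pixel centers with counterclockwise orientation
#' (positive signed area under the x-right/y-down pixel convention).
#'
#' @param mask a [binary_mask()].
#' @return A [raw_contour()].
#' @export
trace_contour <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  comp <- largest_component(mask$pixels)
  h <- nrow(comp); w <- ncol(comp)
  # clockwise neighbour ring (screen orientation, y down): N NE E SE S SW W NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  start <- which(t(comp))[1L]             # row-major scan: top row first
  sr <- (start - 1L) %/% w + 1L
  sc <- (start - 1L) %% w + 1L
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && comp[r, c]
  # backtrack starts at the W neighbour (background by scan order)
  b0 <- 7L
  path_r <- sr; path_c <- sc
  pr <- sr; pc <- sc; b <- b0
  maxit <- 4L * sum(comp) + 8L
  found_any <- FALSE
  for (it in seq_len(maxit)) {
    hit <- 0L
    for (k in seq_len(8L)) {
      j <- mod1(b + k, 8L)
      nr <- pr + dr[j]; nc <- pc + dc[j]
      if (inside(nr, nc)) { hit <- j; break }
    }
    if (hit == 0L) break                   # isolated pixel
    found_any <- TRUE
    # new backtrack: neighbour examined just before the hit, relative to new pixel
    prev <- mod1(hit - 1L, 8L)
    nr <- pr + dr[hit]; nc <- pc + dc[hit]
    # position of previous (background) neighbour relative to the NEW pixel
    br <- pr + dr[prev]; bc <- pc + dc[prev]
    b <- which(dr == br - nr & dc == bc - nc)
    pr <- nr; pc <- nc
    if (pr == sr && pc == sc && b == b0) break
    path_r <- c(path_r, pr); path_c <- c(path_c, pc)
  }
  if (!found_any || length(path_r) < 3L) stopf("contour too small")
  pts <- cbind(x = path_c - 1, y = path_r - 1)  # 0-based pixel centers
  # drop any immediate duplicates produced by degenerate spurs
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) >= 2L && all(pts[nrow(pts), ] == pts[1L, ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3L) stopf("contour too small")
  if (signed_area(pts) < 0) pts <- pts[nrow(pts):1L, , drop = FALSE]
  raw_contour(pts, closed = TRUE)
}

# ---------------------------------------------------------------------------
# Uniform arc-length resampling

#' Resample a closed contour to 2^t0 + 1 uniform points
#'
#' Linearly interpolates along the cumulative arc length of the closed input
#' polygon so that the output has exactly `Np = 2^t0 + 1` points separated by
#' equal arc-length gaps (perimeter / Np). The first output point is the
#' input's first point; descriptors tolerate this arbitrary start because
#' matching either minimizes over cyclic shifts or uses shift-invariant DFT
#' magnitudes.
#'
#' @param contour a [raw_contour()] (or `sampled_contour`).
#' @param t0 positive integer; output length is `2^t0 + 1`.
#' @return A [sampled_contour()].
#' @examples
#' sq <- raw_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' resample_uniform(sq, 2)  # 5 points, arc gaps of 0.8
#' @export
resample_uniform <- function(contour, t0) {
  if (!is_count(t0) || t0 < 1) stopf("invalid t0")
  pts <- if (inherits(contour, "raw_contour") ||
             inherits(contour, "sampled_contour")) contour$points
         else raw_contour(contour)$points
  np_out <- 2L^as.integer(t0) + 1L
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  per <- cum[length(cum)]
  if (per <= 0) stopf("degenerate contour")
  s_out <- per * (seq_len(np_out) - 1) / np_out
  out <- cbind(
    x = approx(cum, closed[, 1L], xout = s_out, ties = "ordered")$y,
    y = approx(cum, closed[, 2L], xout = s_out, ties = "ordered")$y
  )
  sampled_contour(out, t0)
}

# ---------------------------------------------------------------------------
# Contour tables

#' Read / write contour point tables
#'
#' Contours are exchanged as two-column delimited tables with header `x,y`
#' (comma or tab separated), one row per point; the contour is implicitly
#' closed. Writing uses 17 significant digits so that a write/read round trip
#' is lossless at double precision.
#'
#' @param path file path.
#' @param contour a [raw_contour()] or [sampled_contour()].
#' @return `read_contour_table()` returns a [raw_contour()];
#'   `write_contour_table()` returns `path` invisibly.
#' @export
read_contour_table <- function(path) {
  if (!file.exists(path)) stopf("contour file not found: '%s'", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE)
  if (ncol(df) != 2L)
    stopf("contour table must have 2 columns (x, y), got %d", ncol(df))
  names(df) <- tolower(names(df))
  if (!identical(names(df), c("x", "y")))
    stopf("contour table header must be 'x,y', got '%s'",
          paste(names(df), collapse = ","))
  raw_contour(as.matrix(df))
}

#' @rdname read_contour_table
#' @export
write_contour_table <- function(contour, path) {
  pts <- if (is.matrix(contour)) contour else contour$points
  lines <- c("x,y", sprintf("%.17g,%.17g", pts[, 1L], pts[, 2L]))
  writeLines(lines, path)
  invisible(path)
}
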