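# Retrieval ranking and evaluation protocols: bulls-eye score, precision at
# fixed recall, top-k hit counts, intra/inter-class distance statistics.
#
# Ranking ties are broken by shape id order (stable, documented).

# ranked ids for query q; include_self controls whether the query itself may
# appear in its own ranking (bulls-eye: yes; precision/top-k: no)
rank_neighbors <- function(dm, q, include_self) {
  d <- dm$values[q, ]
  idx <- seq_along(d)
  if (!include_self) idx <- idx[idx != q]
  idx[order(d[idx], idx)]
}

check_balanced <- function(dm) {
  sizes <- table(dm$labels)
  if (length(unique(as.integer(sizes))) != 1L)
    stopf("bulls-eye requires balanced classes")
  as.integer(sizes[1L])
}

#' Bulls-eye retrieval score
#'
#' Every shape is queried in turn against the full database (the query is
#' included and its self-match counts, the standard MPEG-7 protocol). The
#' same-class hits among each query's `top_n` nearest shapes are summed and
#' divided by the maximum possible `Nd * n_c`, where `n_c` is the common
#' class size. The conventional choice is `top_n = 2 * n_c` (40 for classes
#' of 20).
#'
#' @param dm a [distance_matrix()] with balanced class labels.
#' @param top_n number of retrieved shapes inspected per query; default
#'   `2 * n_c`.
#' @return Score in `[0, 1]`, with attributes `hits` (total correct) and
#'   `max_hits` (`Nd * n_c`).
#' @export
bulls_eye <- function(dm, top_n = NULL) {
  stopifnot(inherits(dm, "distance_matrix"))
  nc <- check_balanced(dm)
  nd <- length(dm$ids)
  if (is.null(top_n)) top_n <- 2L * nc
  if (!is_count(top_n) || top_n < 1 || top_n > nd) stopf("invalid top_n")
  hits <- 0L
  for (q in seq_len(nd)) {
    rk <- rank_neighbors(dm, q, include_self = TRUE)[seq_len(top_n)]
    hits <- hits + sum(dm$labels[rk] == dm$labels[q])
  }
  structure(hits / (nd * nc), hits = hits, max_hits = nd * nc)
}

#' Precision at fixed recall points
#'
#' Each shape is queried in turn; the query is excluded from its own ranking,
#' leaving `n_c - 1` retrievable same-class shapes. For each recall point
#' (fraction of the class size `n_c`), the target correct count is
#' `m = round(f * n_c)`, clamped to `n_c - 1` when the fraction demands more
#' correct hits than exist without the query (the clamp is flagged). The
#' precision for one query is `m / r_m` where `r_m` is the rank at which the
#' `m`-th correct hit occurs; precisions are averaged over queries.
#'
#' @param dm a [distance_matrix()] with balanced classes.
#' @param recall_points numeric fractions in (0, 1]; default the eight
#'   standard points `c(10, 20, 30, 40, 50, 60, 70, 75) / 75`.
#' @return List with `table` (data frame: `recall`, `target_hits`,
#'   `clamped`, `precision`) and `average` (grand mean precision).
#' @export
precision_at_recall <- function(dm,
                                recall_points = c(10, 20, 30, 40, 50, 60, 70, 75) / 75) {
  stopifnot(inherits(dm, "distance_matrix"))
  nc <- check_balanced(dm)
  nd <- length(dm$ids)
  if (any(recall_points <= 0 | recall_points > 1)) stopf("infeasible recall point")
  m_target <- as.integer(round(recall_points * nc))
  clamped <- m_target > nc - 1L
  m_used <- pmin(m_target, nc - 1L)
  if (any(m_used < 1L)) stopf("infeasible recall point")
  prec <- matrix(NA_real_, nd, length(m_used))
  for (q in seq_len(nd)) {
    rk <- rank_neighbors(dm, q, include_self = FALSE)
    correct <- cumsum(dm$labels[rk] == dm$labels[q])
    for (j in seq_along(m_used)) {
      r_m <- match(m_used[j], correct)   # first rank reaching m correct hits
      prec[q, j] <- m_used[j] / r_m
    }
  }
  tab <- data.frame(
    recall = recall_points,
    target_hits = m_used,
    clamped = clamped,
    precision = colMeans(prec)
  )
  list(table = tab, average = mean(prec))
}

#' Top-k per-rank hit counts
#'
#' Each shape is queried in turn against the remaining shapes (query
#' excluded). `c[r]` counts the queries whose rank-`r` neighbour shares the
#' query's class label, for `r = 1..k`.
#'
#' @param dm a [distance_matrix()].
#' @param k number of ranks, `k < Nd`.
#' @return Integer vector of length `k` with attribute `total` (its sum).
#' @export
topk_hits <- function(dm, k = 10L) {
  stopifnot(inherits(dm, "distance_matrix"))
  nd <- length(dm$ids)
  if (!is_count(k) || k < 1 || k >= nd) stopf("k too large")
  counts <- integer(k)
  for (q in seq_len(nd)) {
    rk <- rank_neighbors(dm, q, include_self = FALSE)[seq_len(k)]
    counts <- counts + (dm$labels[rk] == dm$labels[q])
  }
  structure(counts, total = sum(counts))
}

#' Intra/inter-class distance statistics
#'
#' Mean dissimilarity over ordered off-diagonal pairs within the same class
#' (`intra_mean`) and across classes (`inter_mean`). Self-pairs are excluded
#' from both statistics; with a single class the inter-class mean is `NA`.
#'
#' @param dm a [distance_matrix()].
#' @return List of class `class_stats` with `intra_mean`, `inter_mean`,
#'   `n_intra_pairs`, `n_inter_pairs`.
#' @export
class_stats <- function(dm) {
  stopifnot(inherits(dm, "distance_matrix"))
  same <- outer(dm$labels, dm$labels, "==")
  off <- !diag(TRUE, length(dm$ids))
  intra <- dm$values[same & off]
  inter <- dm$values[!same]
  structure(
    list(
      intra_mean = if (length(intra)) mean(intra) else NA_real_,
      inter_mean = if (length(inter)) mean(inter) else NA_real_,
      n_intra_pairs = length(intra),
      n_inter_pairs = length(inter)
    ),
    class = "class_stats"
  )
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf("<class_stats> intra mean %.4f (%d pairs), inter mean %s (%d pairs)\n",
              x$intra_mean, x$n_intra_pairs,
              if (is.na(x$inter_mean)) "undefined" else sprintf("%.4f", x$inter_mean),
              x$n_inter_pairs))
  invisible(x)
}

#' Ranked retrieval for one query
#'
#' @param dm a [distance_matrix()].
#' @param query shape id present in `dm$ids`.
#' @param top number of results (default all others).
#' @param include_self whether the query may match itself.
#' @return Data frame: `rank`, `id`, `label`, `distance`, `hit`.
#' @export
retrieve <- function(dm, query, top = NULL, include_self = FALSE) {
  stopifnot(inherits(dm, "distance_matrix"))
  q <- match(query, dm$ids)
  if (is.na(q)) stopf("unknown query id '%s'", query)
  rk <- rank_neighbors(dm, q, include_self = include_self)
  if (!is.null(top)) rk <- head(rk, top)
  data.frame(
    rank = seq_along(rk),
    id = dm$ids[rk],
    label = dm$labels[rk],
    distance = dm$values[q, rk],
    hit = dm$labels[rk] == dm$labels[q],
    row.names = NULL
  )
}
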