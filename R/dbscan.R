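# Density-based clustering of localizations.
#
# The production path is a grid-indexed implementation in C++ (cell size
# eps, so neighbourhoods are found in the 3x3 surrounding cells); the pure-R
# O(n^2) neighbourhood-graph implementation below is retained as the
# independent reference the fast path is verified against.

#' Cluster 2D points with DBSCAN
#'
#' Standard density-based clustering: a point is a core point iff its closed
#' eps-neighbourhood (including itself) holds at least `min_pts` points;
#' clusters are the connected components of core points under mutual
#' eps-reachability; border (non-core) points join the cluster of their
#' first core neighbour in ascending row order, and everything else is
#' noise. Cluster ids are assigned in order of first member row so output is
#' reproducible. The standard parameter sets are eps 75 nm / minPts 9
#' (thioflavin-X) and eps 200 nm / minPts 10 (aptamer PAINT).
#'
#' @param points an `n x 2` matrix (nm), or a localization table.
#' @param eps detection radius (nm).
#' @param min_pts minimum localization threshold.
#' @return A list of class `"cluster_labeling"`: `labels` (integer per row,
#'   `-1` noise, clusters `0 .. K-1`), `core` (logical per row) and
#'   `n_clusters`.
#' @export
dbscan_cluster <- function(points, eps, min_pts) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (min_pts < 1L) stop("min_pts must be >= 1", call. = FALSE)
  xy <- .as_xy(points)
  res <- .dbscan_grid(xy[, 1L], xy[, 2L], eps, as.integer(min_pts))
  structure(list(labels = res$labels, core = res$core,
                 n_clusters = res$n_clusters, eps = eps,
                 min_pts = as.integer(min_pts)),
            class = "cluster_labeling")
}

.as_xy <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    cbind(points$x, points$y)
  } else matrix(as.numeric(points), ncol = 2L)
}

#' Reference O(n^2) DBSCAN
#'
#' A direct pure-R implementation working on the full distance structure:
#' explicit neighbourhood lists, breadth-first expansion over core points,
#' identical label conventions to [dbscan_cluster()]. Quadratic in the
#' number of points; intended as a verification oracle, not for production
#' data sizes.
#'
#' @inheritParams dbscan_cluster
#' @return A `"cluster_labeling"` list.
#' @export
dbscan_brute <- function(points, eps, min_pts) {
  xy <- .as_xy(points)
  n <- nrow(xy)
  labels <- rep(-1L, n)
  if (n == 0L)
    return(structure(list(labels = labels, core = logical(0),
                          n_clusters = 0L, eps = eps,
                          min_pts = as.integer(min_pts)),
                     class = "cluster_labeling"))
  d2 <- as.matrix(stats::dist(xy))^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  core <- vapply(nb, length, 0L) >= min_pts
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    labels[i] <- cid
    frontier <- i
    while (length(frontier)) {
      nxt <- integer()
      for (j in frontier) {
        cand <- nb[[j]]
        cand <- cand[core[cand] & labels[cand] == -1L]
        labels[cand] <- cid
        nxt <- c(nxt, cand)
      }
      frontier <- nxt
    }
    cid <- cid + 1L
  }
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != -1L) next
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  # renumber by first member row
  seen <- rep(NA_integer_, max(cid, 1L))
  nxt <- 0L
  for (i in seq_len(n)) {
    l <- labels[i]
    if (l >= 0L && is.na(seen[l + 1L])) {
      seen[l + 1L] <- nxt
      nxt <- nxt + 1L
    }
  }
  pos <- labels >= 0L
  labels[pos] <- seen[labels[pos] + 1L]
  structure(list(labels = as.integer(labels), core = core,
                 n_clusters = nxt, eps = eps, min_pts = as.integer(min_pts)),
            class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("DBSCAN labeling: %d points, %d clusters, %d noise (eps %g, minPts %d)\n",
              length(x$labels), x$n_clusters, sum(x$labels == -1L),
              x$eps, x$min_pts))
  invisible(x)
}
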