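# Per-aggregate morphometry: length, eccentricity, intensity.
#
# Eccentricity comes from the second central moments of the member
# localizations: with eigenvalues l1 >= l2 >= 0, e = sqrt(1 - l2/l1), which
# is exactly the focal-distance / major-axis ratio of the fitted ellipse
# (0 = circle, 1 = line, i.e. fibrillar). Length defaults to the maximum
# pairwise distance between member localizations (max Feret diameter);
# the projection extent along the major axis is available as an
# alternative metric.

# closed-form 2x2 second-moment decomposition shared by the per-cluster and
# per-sample paths; returns scalars only (no data.frame overhead)
.measure_xy <- function(x, y, metric = "feret") {
  n <- length(x)
  cx <- sum(x) / n
  cy <- sum(y) / n
  dx <- x - cx
  dy <- y - cy
  sxx <- sum(dx * dx) / n
  syy <- sum(dy * dy) / n
  sxy <- sum(dx * dy) / n
  half_tr <- (sxx + syy) / 2
  disc <- sqrt(max(0, ((sxx - syy) / 2)^2 + sxy^2))
  l1 <- half_tr + disc
  l2 <- max(half_tr - disc, 0)
  if (l1 <= 0)
    return(list(n = n, length = 0, ecc = 0, angle = 0, cx = cx, cy = cy))
  ecc <- sqrt(max(0, 1 - l2 / l1))
  angle <- (0.5 * atan2(2 * sxy, sxx - syy)) %% pi
  len <- if (metric == "feret") .max_pairwise_dist(x, y) else {
    u <- c(cos(angle), sin(angle))
    diff(range(dx * u[1L] + dy * u[2L]))
  }
  list(n = n, length = len, ecc = ecc, angle = angle, cx = cx, cy = cy)
}

#' Measure one cluster of localizations
#'
#' @param points `n x 2` matrix of member positions (nm), `n >= 2`.
#' @param intensities optional member intensities (summed into
#'   `total_intensity`).
#' @param metric length metric: `"feret"` (max pairwise distance, default)
#'   or `"extent"` (max minus min projection on the major axis).
#' @return A one-row data.frame: `n_locs`, `length`, `eccentricity`,
#'   `total_intensity`, `centroid_x`, `centroid_y`, `major_axis_angle`.
#'   Coincident point sets measure eccentricity 0 and length 0; a 2-point
#'   cluster has eccentricity exactly 1 (degenerate minor axis).
#' @export
measure_cluster <- function(points, intensities = NULL,
                            metric = c("feret", "extent")) {
  metric <- match.arg(metric)
  xy <- .as_xy(points)
  if (nrow(xy) < 2L) stop("a cluster needs at least 2 points", call. = FALSE)
  m <- .measure_xy(xy[, 1L], xy[, 2L], metric)
  data.frame(n_locs = m$n, length = m$length, eccentricity = m$ecc,
             total_intensity = if (is.null(intensities)) NA_real_ else
               sum(intensities),
             centroid_x = m$cx, centroid_y = m$cy,
             major_axis_angle = m$angle)
}

#' Measure all clusters of a sample
#'
#' Produces one morphometry record per non-noise cluster plus sample-level
#' summary statistics. With `correct_length = TRUE` each raw length is
#' deflated by twice the cluster's mean localization precision (floored at
#' zero), a first-order correction for the noise inflation of the max Feret
#' diameter; the default reports raw lengths.
#'
#' @param table a localization table.
#' @param labeling a `"cluster_labeling"` from [dbscan_cluster()] (or any
#'   list with an integer `labels` vector matching the table rows).
#' @param metric length metric, see [measure_cluster()].
#' @param correct_length apply the 2 x mean-precision length correction?
#' @return A list of class `"aggregate_morphometry"`: `records` (data.frame
#'   with `cluster_id` and the per-cluster measures) and `summary` (list:
#'   `n_clusters`, `median_length`, `mean_length`, `mean_eccentricity`,
#'   `total_localizations`, `no_clusters` flag).
#' @export
summarize_sample <- function(table, labeling, metric = c("feret", "extent"),
                             correct_length = FALSE) {
  metric <- match.arg(metric)
  validate_localizations(table)
  labels <- labeling$labels
  if (length(labels) != nrow(table))
    stop("labeling length does not match the localization table",
         call. = FALSE)
  member <- labels >= 0L
  groups <- split(which(member), labels[member])
  if (!length(groups)) {
    records <- data.frame(cluster_id = integer(), n_locs = integer(),
                          length = numeric(), eccentricity = numeric(),
                          total_intensity = numeric(), centroid_x = numeric(),
                          centroid_y = numeric(), major_axis_angle = numeric())
    summary <- list(n_clusters = 0L, median_length = NA_real_,
                    mean_length = NA_real_, mean_eccentricity = NA_real_,
                    total_localizations = 0L, no_clusters = TRUE)
    return(structure(list(records = records, summary = summary),
                     class = "aggregate_morphometry"))
  }
  k <- length(groups)
  ids <- as.integer(names(groups))
  n_locs <- integer(k)
  len <- ecc <- tot <- cx <- cy <- ang <- numeric(k)
  for (g in seq_len(k)) {
    rows <- groups[[g]]
    m <- .measure_xy(table$x[rows], table$y[rows], metric)
    n_locs[g] <- m$n
    len[g] <- if (correct_length)
      max(0, m$length - 2 * mean(table$precision[rows])) else m$length
    ecc[g] <- m$ecc
    tot[g] <- sum(table$intensity[rows])
    cx[g] <- m$cx; cy[g] <- m$cy; ang[g] <- m$angle
  }
  ord <- order(ids)
  records <- data.frame(cluster_id = ids[ord], n_locs = n_locs[ord],
                        length = len[ord], eccentricity = ecc[ord],
                        total_intensity = tot[ord], centroid_x = cx[ord],
                        centroid_y = cy[ord], major_axis_angle = ang[ord])
  summary <- list(n_clusters = nrow(records),
                  median_length = median(records$length),
                  mean_length = mean(records$length),
                  mean_eccentricity = mean(records$eccentricity),
                  total_localizations = sum(records$n_locs),
                  no_clusters = FALSE)
  structure(list(records = records, summary = summary),
            class = "aggregate_morphometry")
}

#' @export
print.aggregate_morphometry <- function(x, ...) {
  s <- x$summary
  if (isTRUE(s$no_clusters)) {
    cat("Aggregate morphometry: no clusters\n")
  } else {
    cat(sprintf(
      "Aggregate morphometry: %d clusters, median length %.1f nm, mean length %.1f nm, mean eccentricity %.2f\n",
      s$n_clusters, s$median_length, s$mean_length, s$mean_eccentricity))
  }
  invisible(x)
}

#' Write morphometry records to CSV
#'
#' Byte-deterministic CSV with columns `cluster_id, n_locs, length_nm,
#' eccentricity, total_intensity, centroid_x_nm, centroid_y_nm, angle_rad`.
#'
#' @param morpho an `"aggregate_morphometry"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(morpho, path) {
  r <- morpho$records
  lines <- "cluster_id,n_locs,length_nm,eccentricity,total_intensity,centroid_x_nm,centroid_y_nm,angle_rad"
  if (nrow(r))
    lines <- c(lines, sprintf("%d,%d,%.3f,%.6f,%.3f,%.3f,%.3f,%.6f",
                              r$cluster_id, r$n_locs, r$length,
                              r$eccentricity, r$total_intensity,
                              r$centroid_x, r$centroid_y,
                              r$major_axis_angle))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
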