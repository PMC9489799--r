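# Diffraction-limited spot counting (SiMPull and thioflavin fields):
# control-calibrated thresholds, per-field counts, specificity ratios and
# response normalization.

#' Calibrate an intensity threshold against a negative control
#'
#' Given the mean negative-control spot count per field of view as a
#' function of candidate thresholds (monotone non-increasing), returns the
#' smallest threshold whose control count does not exceed the budget. The
#' budget expresses how many non-specific spots per field are tolerable
#' (default 2).
#'
#' @param thresholds candidate intensity thresholds.
#' @param control_counts mean control spots per FoV at each threshold.
#' @param budget tolerated control spots per FoV.
#' @return The selected threshold (scalar).
#' @export
calibrate_threshold <- function(thresholds, control_counts, budget = 2) {
  stopifnot(length(thresholds) == length(control_counts),
            length(thresholds) >= 1L)
  ord <- order(thresholds)
  thresholds <- thresholds[ord]
  control_counts <- control_counts[ord]
  if (is.unsorted(rev(control_counts)))
    stop("control counts must be monotone non-increasing in the threshold",
         call. = FALSE)
  ok <- which(control_counts <= budget)
  if (!length(ok))
    stop(sprintf(
      "budget %g unreachable: minimal achievable control count is %g",
      budget, min(control_counts)), call. = FALSE)
  thresholds[ok[1L]]
}

#' Count spots above a threshold
#'
#' Counts local-maximum spots whose peak pixel exceeds the threshold, after
#' suppression of maxima within 3 pixels of a brighter one. Monotone
#' non-increasing in the threshold.
#'
#' @param image a numeric matrix.
#' @param threshold absolute peak-intensity threshold.
#' @param min_sep suppression radius (pixels).
#' @return A list of class `"field_count"`: `count`, `threshold` and the
#'   detected `spots` data.frame.
#' @export
count_spots <- function(image, threshold, min_sep = 3L) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  spots <- detect_spots(image, threshold = threshold, min_sep = min_sep)
  structure(list(count = nrow(spots), threshold = threshold, spots = spots),
            class = "field_count")
}

#' @export
print.field_count <- function(x, ...) {
  cat(sprintf("Field count: %d spots above threshold %g\n", x$count,
              x$threshold))
  invisible(x)
}

#' Specificity ratio of target over control counts
#'
#' Ratio of mean per-FoV spot counts between a target antibody and its
#' isotype control; high values indicate specific antigen binding.
#'
#' @param target_counts spot counts per FoV, target condition.
#' @param control_counts spot counts per FoV, isotype control.
#' @return A list: `ratio` (`Inf` with `control_zero = TRUE` when the
#'   control mean is 0), `target_mean`, `control_mean`, and the standard
#'   errors of both means.
#' @export
specificity_ratio <- function(target_counts, control_counts) {
  stopifnot(length(target_counts) >= 1L, length(control_counts) >= 1L)
  tm <- mean(target_counts)
  cm <- mean(control_counts)
  list(ratio = if (cm == 0) Inf else tm / cm,
       control_zero = cm == 0,
       target_mean = tm, control_mean = cm,
       target_se = sd(target_counts) / sqrt(length(target_counts)),
       control_se = sd(control_counts) / sqrt(length(control_counts)))
}

#' Normalize responses between negative and positive control means
#'
#' Linear map sending the negative-control mean to 0% and the
#' positive-control mean to 100%:
#' `100 * (v - neg_mean) / (pos_mean - neg_mean)`.
#'
#' @param values raw responses.
#' @param neg_mean negative-control mean (e.g. buffer).
#' @param pos_mean positive-control mean (e.g. LPS); must exceed `neg_mean`.
#' @return Percentages (same length as `values`).
#' @export
normalize_response <- function(values, neg_mean, pos_mean) {
  if (!(pos_mean > neg_mean))
    stop("pos_mean must exceed neg_mean", call. = FALSE)
  100 * (values - neg_mean) / (pos_mean - neg_mean)
}

#' Normalize values per total protein
#'
#' Divides responses by a per-sample total-protein scalar (e.g. a BCA
#' concentration), for comparisons across samples of unequal protein load.
#'
#' @param values raw responses.
#' @param total_protein positive scalar (or vector recycled to `values`).
#' @return `values / total_protein`.
#' @export
normalize_per_protein <- function(values, total_protein) {
  if (any(total_protein <= 0))
    stop("total_protein must be > 0", call. = FALSE)
  values / total_protein
}
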