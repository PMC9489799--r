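# Two-sample comparison of aggregate populations: normalized and cumulative
# histograms, their difference curves, Kolmogorov-Smirnov and Mann-Whitney
# tests. Sign convention throughout: differences are (a - b), so negative
# values mean the feature is more abundant in group b.

.kolmogorov_sf <- function(lambda) {
  # survival function of the Kolmogorov distribution, alternating series
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample values of the absolute ECDF
#' difference; the p-value uses the asymptotic Kolmogorov distribution at
#' `sqrt(n*m/(n+m)) * D`. Intended for the large samples (thousands of
#' aggregates) this pipeline produces; no small-sample exact p is attempted.
#'
#' @param x,y numeric samples (non-empty).
#' @return A list: `D`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  fx <- ecdf_at(x, pooled)
  fy <- ecdf_at(y, pooled)
  D <- max(abs(fx - fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  list(D = D, p = .kolmogorov_sf(sqrt(ne) * D),
       n_x = length(x), n_y = length(y))
}

#' Empirical CDF evaluated at given points
#'
#' @param sample numeric sample.
#' @param at evaluation points.
#' @return `P(sample <= at)` per point.
#' @export
ecdf_at <- function(sample, at) {
  findInterval(at, sort(sample)) / length(sample)
}

# exact null distribution of the rank-sum count via the standard recursion
# c(u; n, m) = c(u - m; n - 1, m) + c(u; n, m - 1); returns P(U <= u) for
# u = 0..n*m
.u_null_cdf <- function(n, m) {
  counts <- vector("list", (n + 1L) * (m + 1L))
  idx <- function(i, j) i * (m + 1L) + j + 1L
  for (j in 0:m) counts[[idx(0L, j)]] <- 1  # U identically 0
  for (i in 1:n) {
    counts[[idx(i, 0L)]] <- 1
    for (j in 1:m) {
      a <- counts[[idx(i - 1L, j)]]        # over U = 0..(i-1)*j, shifted by j
      b <- counts[[idx(i, j - 1L)]]        # over U = 0..i*(j-1)
      len <- i * j + 1L
      v <- numeric(len)
      v[(j + 1L):(j + length(a))] <- a
      v[seq_along(b)] <- v[seq_along(b)] + b
      counts[[idx(i, j)]] <- v
    }
  }
  v <- counts[[idx(n, m)]]
  cumsum(v) / sum(v)
}

#' Two-sample Mann-Whitney U test
#'
#' U counts the pairs with `x_i > y_j` plus half the ties; the reported
#' statistic is `min(U, n*m - U)`. The two-sided p-value is exact
#' (`2 * P(U <= U_min)` from the enumerated null distribution, capped at 1)
#' when `n*m <= 400` and the data are tie-free; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return A list: `U`, `p`, `method` (`"exact"` or `"normal"`), `n_x`,
#'   `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n <- length(x); m <- length(y)
  if (!n || !m) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n)]) - n * (n + 1) / 2  # counts x > y (+ half ties)
  u <- min(u_x, n * m - u_x)
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (!has_ties && n * m <= 400) {
    cdf <- .u_null_cdf(n, m)
    p <- min(1, 2 * cdf[round(u) + 1L])
    method <- "exact"
  } else {
    N <- n + m
    mu <- n * m / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * ((N + 1) - tie_term))
    z <- (abs(u_x - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = u, p = p, method = method, n_x = n, n_y = m)
}

#' Compare two aggregate populations
#'
#' Builds unit-mass histograms of the two samples on shared bin edges, their
#' per-bin difference, both ECDFs over the pooled support, the cumulative
#' difference curve and its largest absolute excursion, and runs the KS and
#' Mann-Whitney tests. All differences are (a - b): negative values mean
#' more abundance in group b.
#'
#' @param a,b numeric samples (e.g. aggregate lengths in nm).
#' @param bin_width histogram bin width (same units as the samples).
#' @param names labels for the two groups.
#' @return A list of class `"dist_comparison"`; see fields in the source.
#' @export
compare_groups <- function(a, b, bin_width = 10, names = c("a", "b")) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty",
                                     call. = FALSE)
  lo <- floor(min(a, b) / bin_width) * bin_width
  hi <- ceiling(max(a, b) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  hist_a <- hist(a, breaks = edges, plot = FALSE)$counts / length(a)
  hist_b <- hist(b, breaks = edges, plot = FALSE)$counts / length(b)
  pooled <- sort(unique(c(a, b)))
  ecdf_a <- ecdf_at(a, pooled)
  ecdf_b <- ecdf_at(b, pooled)
  cum_diff <- ecdf_a - ecdf_b
  peak_i <- which.max(abs(cum_diff))
  ks <- ks_two_sample(a, b)
  mwu <- mann_whitney_u(a, b)
  structure(list(names = names, bin_edges = edges,
                 hist_a = hist_a, hist_b = hist_b,
                 hist_difference = hist_a - hist_b,
                 support = pooled, ecdf_a = ecdf_a, ecdf_b = ecdf_b,
                 cumulative_difference = cum_diff,
                 max_cum_difference = list(location = pooled[peak_i],
                                           value = cum_diff[peak_i]),
                 ks_D = ks$D, ks_p = ks$p,
                 mwu_U = mwu$U, mwu_p = mwu$p,
                 median_a = median(a), median_b = median(b),
                 n_a = length(a), n_b = length(b)),
            class = "dist_comparison")
}

#' @export
print.dist_comparison <- function(x, ...) {
  cat(sprintf("Distribution comparison: %s (n=%d) vs %s (n=%d)\n",
              x$names[1L], x$n_a, x$names[2L], x$n_b))
  cat(sprintf("  medians: %.2f vs %.2f\n", x$median_a, x$median_b))
  cat(sprintf("  KS D = %.4f, p = %.3g\n", x$ks_D, x$ks_p))
  cat(sprintf("  Mann-Whitney U = %.1f, p = %.3g\n", x$mwu_U, x$mwu_p))
  cat(sprintf("  largest cumulative difference %.3f at %.1f\n",
              x$max_cum_difference$value, x$max_cum_difference$location))
  invisible(x)
}

#' @describeIn compare_groups four-panel base-graphics view: the two
#'   normalized histograms, their difference, the ECDFs and the cumulative
#'   difference curve.
#' @param x a `"dist_comparison"` object.
#' @param ... ignored.
#' @export
plot.dist_comparison <- function(x, ...) {
  old <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  mids <- (head(x$bin_edges, -1L) + tail(x$bin_edges, -1L)) / 2
  plot(mids, x$hist_a, type = "s", col = "firebrick", xlab = "value",
       ylab = "frequency", main = "normalized histograms")
  lines(mids, x$hist_b, type = "s", col = "gray40")
  legend("topright", legend = x$names, col = c("firebrick", "gray40"),
         lty = 1, bty = "n")
  plot(mids, x$hist_difference, type = "h", xlab = "value",
       ylab = sprintf("%s - %s", x$names[1L], x$names[2L]),
       main = "histogram difference")
  abline(h = 0, col = "gray70")
  plot(x$support, x$ecdf_a, type = "s", col = "firebrick", xlab = "value",
       ylab = "cumulative fraction", main = "ECDFs")
  lines(x$support, x$ecdf_b, type = "s", col = "gray40")
  plot(x$support, x$cumulative_difference, type = "l", xlab = "value",
       ylab = sprintf("%s - %s", x$names[1L], x$names[2L]),
       main = "cumulative difference")
  abline(h = 0, col = "gray70")
  abline(v = x$max_cum_difference$location, col = "firebrick", lty = 2)
  invisible(x)
}

#' Serialize a distribution comparison to JSON
#'
#' Deterministic JSON (fixed key order, full precision) suitable for the
#' pipeline's comparison reports.
#'
#' @param comparison a `"dist_comparison"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  out <- comparison
  class(out) <- NULL
  out$support <- NULL
  out$ecdf_a <- NULL
  out$ecdf_b <- NULL
  out$cumulative_difference <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
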