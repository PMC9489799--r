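test_that("frame averaging behaves like the arithmetic mean", {
  st <- array(rep(c(0, 2), each = 16), c(4, 4, 2))
  expect_equal(average_frames(st), matrix(1, 4, 4))
  same <- array(7, c(3, 3, 5))
  expect_equal(average_frames(same), matrix(7, 3, 3))
  expect_error(average_frames(array(0, c(2, 2, 0))), "frame")

  # variance of the mean of Poisson frames
  set.seed(501)
  st <- array(rpois(32 * 32 * 50, 100), c(32, 32, 50))
  expect_equal(sd(average_frames(st)), sqrt(100 / 50), tolerance = 0.15)
})

test_that("influx equation: endpoints, direct value, affine invariance", {
  expect_equal(compute_influx(100, 100, 300)$mean_influx_pct, 0)
  expect_equal(compute_influx(100, 300, 300)$mean_influx_pct, 100)
  expect_equal(compute_influx(100, 150, 300)$mean_influx_pct, 25)

  # affine transform v -> a*v + g leaves the percentage unchanged
  set.seed(502)
  fb <- runif(20, 50, 150); fi <- fb + runif(20, 100, 500)
  fs <- fb + runif(20) * (fi - fb)
  base <- compute_influx(fb, fs, fi)$spots$influx_pct
  for (i in 1:10) {
    a <- runif(1, 0.1, 10); g <- runif(1, -50, 50)
    tr <- compute_influx(a * fb + g, a * fs + g, a * fi + g)$spots$influx_pct
    expect_equal(tr, base, tolerance = 1e-9)
  }

  # unresponsive spots are flagged and an all-invalid field errors
  res <- compute_influx(c(100, 100), c(150, 90), c(300, 100))
  expect_equal(res$n_invalid, 1L)
  expect_equal(res$mean_influx_pct, 25)
  expect_error(compute_influx(100, 90, 100), "responsive")
})

test_that("mutual nearest-neighbour matching equals the brute-force search", {
  set.seed(503)
  # well-separated grid so only true counterparts can ever match
  g <- expand.grid(x = seq(1000, 16000, by = 3000),
                   y = seq(1000, 16000, by = 3000))[1:30, ]
  a <- data.frame(x = g$x + runif(30, -200, 200),
                  y = g$y + runif(30, -200, 200))
  jitter2 <- function(d, s) data.frame(x = d$x + rnorm(nrow(d), 0, s),
                                       y = d$y + rnorm(nrow(d), 0, s))
  b <- jitter2(a, 50)[sample.int(30), ]
  c3 <- jitter2(a, 50)
  m <- match_spots(a, b, c3, radius = 474)
  # identical lists: everything matches
  full <- match_spots(a, a, a, radius = 474)
  expect_equal(nrow(full$triplets), 30L)
  expect_equal(full$triplets$sample, full$triplets$background)
  # offset by 2*radius: nothing matches
  far <- data.frame(x = a$x + 2 * 474, y = a$y)
  expect_equal(nrow(match_spots(a, far, a, radius = 474)$triplets), 0L)
  # brute-force mutual-NN oracle on (a, b)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
  oracle <- vapply(seq_len(30), function(i) {
    j <- which.min(d2[i, ])
    if (which.min(d2[, j]) == i && d2[i, j] <= 474^2) j else NA_integer_
  }, 1L)
  got <- rep(NA_integer_, 30)
  got[m$triplets$background] <- m$triplets$sample
  # triplet membership also requires a c-match; restrict to those rows
  expect_true(all(got[!is.na(got)] == oracle[!is.na(got)]))
})

test_that("threshold calibration picks the smallest threshold within budget", {
  thr <- c(100, 200, 300, 400)
  counts <- c(50, 10, 2, 0)
  expect_equal(calibrate_threshold(thr, counts, budget = 2), 300)
  expect_equal(calibrate_threshold(thr, counts, budget = Inf), 100)
  expect_equal(calibrate_threshold(thr, c(0, 0, 0, 0), budget = 2), 100)
  expect_error(calibrate_threshold(thr, counts, budget = -1), "unreachable")
  expect_error(calibrate_threshold(thr, c(1, 2, 3, 4), 2), "monotone")

  # exhaustive-scan oracle on a synthetic control intensity CDF
  set.seed(504)
  intens <- rexp(2000, 1 / 100)
  grid <- seq(0, 1000, by = 25)
  counts2 <- vapply(grid, function(t) sum(intens > t) / 10, 0)
  budget <- 5
  oracle <- grid[which(counts2 <= budget)[1L]]
  expect_equal(calibrate_threshold(grid, counts2, budget), oracle)
})

test_that("spot counting is correct on constructed fields and monotone", {
  set.seed(505)
  k <- 7
  pos <- cbind(runif(k, 2000, 28000), runif(k, 2000, 28000))
  img <- average_frames(render_frame_stack(pos, 3000, 150, 237, 30000,
                                           n_frames = 10, baseline = 100))
  fc <- count_spots(img, threshold = 150)
  expect_equal(fc$count, k)
  expect_equal(count_spots(img, threshold = max(img) + 1)$count, 0L)
  thresholds <- quantile(img, c(0.5, 0.9, 0.99, 1))
  counts <- vapply(thresholds, function(t) count_spots(img, t)$count, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("specificity ratios and response normalization", {
  expect_equal(specificity_ratio(c(60, 60), c(3, 3))$ratio, 20)
  expect_equal(specificity_ratio(1:3, 1:3)$ratio, 1)
  z <- specificity_ratio(c(5, 5), c(0, 0))
  expect_true(is.infinite(z$ratio) && z$control_zero)

  expect_equal(normalize_response(10, 10, 60), 0)
  expect_equal(normalize_response(60, 10, 60), 100)
  expect_equal(normalize_response(35, 10, 60), 50)
  expect_error(normalize_response(1, 5, 5), "exceed")
  expect_equal(normalize_per_protein(c(10, 20), 2), c(5, 10))
})

test_that("a simulated influx experiment is recovered end to end", {
  set.seed(506)
  sim <- simulate_influx_experiment(n_liposomes = 80, true_influx = 0.3)
  res <- analyze_influx_experiment(sim$stack_background, sim$stack_sample,
                                   sim$stack_ionomycin)
  expect_gt(nrow(res$spots), 40)
  expect_lt(abs(res$mean_influx_pct - 30), 3)

  # degenerate settings: influx 0 matches background, 1 matches ionomycin
  set.seed(507)
  sim0 <- simulate_influx_experiment(n_liposomes = 40, true_influx = 0)
  r0 <- analyze_influx_experiment(sim0$stack_background, sim0$stack_sample,
                                  sim0$stack_ionomycin)
  expect_lt(abs(r0$mean_influx_pct), 3)
  sim1 <- simulate_influx_experiment(n_liposomes = 40, true_influx = 1)
  r1 <- analyze_influx_experiment(sim1$stack_background, sim1$stack_sample,
                                  sim1$stack_ionomycin)
  expect_lt(abs(r1$mean_influx_pct - 100), 3)
})
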