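test_that("a noiseless sub-pixel spot is recovered to better than 1 nm", {
  pixel <- 98.8
  truth <- c(3210.4, 2897.3)
  stack <- render_frame_stack(rbind(truth), photons = 2000, psf_sigma = 150,
                              pixel_size = pixel, fov_size = 6000,
                              noise = FALSE, baseline = 10)
  locs <- localize_stack(stack, pixel_size = pixel)
  expect_equal(nrow(locs), 1L)
  expect_lt(abs(locs$x - truth[1L]), 1)
  expect_lt(abs(locs$y - truth[2L]), 1)
  expect_equal(locs$intensity, 2000, tolerance = 0.01)
})

test_that("blank noisy frames yield essentially no false positives", {
  set.seed(201)
  blank <- array(rpois(64 * 64 * 10, 100), c(64, 64, 10))
  locs <- localize_stack(blank, pixel_size = 237, detect_threshold_k = 5)
  expect_lte(nrow(locs), 1L)  # <= 1 false positive per 10 frames
})

test_that("two well-separated spots give exactly two localizations", {
  pixel <- 100
  pos <- rbind(c(1950, 2050), c(2950, 2050))  # 10 pixels apart
  stack <- render_frame_stack(pos, photons = 3000, psf_sigma = 130,
                              pixel_size = pixel, fov_size = 5000,
                              noise = FALSE, baseline = 10)
  locs <- localize_stack(stack, pixel_size = pixel)
  expect_equal(nrow(locs), 2L)
  expect_equal(sort(locs$x), pos[, 1L], tolerance = 1e-2)
})

test_that("filtering equals the row-by-row predicate and is idempotent", {
  set.seed(202)
  tab <- make_loc_table(500)
  f <- filter_localizations(tab, min_signal = 100, max_precision = 20)
  # brute-force oracle
  keep <- vapply(seq_len(nrow(tab)), function(i)
    tab$intensity[i] >= 100 && tab$precision[i] <= 20, TRUE)
  expect_equal(nrow(f), sum(keep))
  expect_equal(f$x, tab$x[keep])

  # identity settings
  expect_equal(filter_localizations(tab, 0, Inf), tab, ignore_attr = TRUE)
  # idempotence
  expect_equal(filter_localizations(f, 100, 20), f)
  # permutation-commutation as a set operation
  perm <- sample.int(nrow(tab))
  fp <- filter_localizations(tab[perm, ], 100, 20)
  expect_equal(sort(fp$x), sort(f$x))
  # boundary predicate: precision 25 under max 20 is removed
  one <- localization_table(frame = 0L, x = 1, y = 1, intensity = 500,
                            precision = 25)
  expect_equal(nrow(filter_localizations(one, 100, 20)), 0L)
})

test_that("fitted precision is consistent with the actual error", {
  # Poisson-noise spots at ~1000 photons: RMSE within a factor 2 of the
  # mean Thompson prediction
  set.seed(203)
  pixel <- 98.8
  err <- pred <- numeric(0)
  for (i in 1:60) {
    truth <- c(2000, 2000) + runif(2, -pixel / 2, pixel / 2)
    stack <- render_frame_stack(rbind(truth), photons = 1000,
                                psf_sigma = 150, pixel_size = pixel,
                                fov_size = 4000, noise = TRUE, baseline = 20)
    locs <- localize_stack(stack, pixel_size = pixel)
    if (nrow(locs) != 1L) next
    err <- c(err, locs$x - truth[1L], locs$y - truth[2L])
    pred <- c(pred, locs$precision)
  }
  expect_gt(length(pred), 40)
  rmse <- sqrt(mean(err^2))
  ratio <- rmse / mean(pred)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("drift correction recovers a linear drift from fiducials", {
  set.seed(204)
  p <- simulation_params(n_aggregates = 0L, n_fiducials = 4L,
                         drift_model = "linear", drift_rate = 0.05,
                         n_frames = 2000L, fiducial_sigma = 0,
                         background_rate = 0)
  sim <- apply_drift_and_fiducials(localization_table(), p)
  res <- correct_drift(sim$table, sim$fiducials, n_frames = 2000L)
  resid <- sqrt(mean((res$trajectory$dx - sim$trajectory$dx)^2 +
                     (res$trajectory$dy - sim$trajectory$dy)^2))
  expect_lt(resid, 2)
  expect_equal(nrow(res$table), 0L)  # all fiducial rows removed

  # zero drift, noiseless fiducials: output equals input minus fiducials
  set.seed(205)
  base <- make_loc_table(30, n_frames = 500)
  p0 <- simulation_params(n_aggregates = 0L, n_fiducials = 2L,
                          drift_rate = 0, n_frames = 500L,
                          fiducial_sigma = 0)
  sim0 <- apply_drift_and_fiducials(base, p0)
  res0 <- correct_drift(sim0$table, sim0$fiducials, n_frames = 500L)
  expect_equal(sort(res0$table$x), sort(base$x), tolerance = 1e-9)
  expect_true(all(abs(res0$trajectory$dx) < 1e-9))

  # no fiducial near any reference is an error
  expect_error(correct_drift(base, cbind(1e6, 1e6)), "frame 0")
})
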