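test_that("aggregate sampling honours counts, envelopes and the length law", {
  set.seed(101)
  p <- simulation_params(n_aggregates = 0L)
  expect_length(sample_aggregates(p), 0L)

  # law of large numbers on the lognormal median
  p <- simulation_params(n_aggregates = 10000L, length_median = 200,
                         fov_size = 1e6)
  ag <- sample_aggregates(p)
  med <- median(vapply(ag, `[[`, 0, "length"))
  expect_lt(abs(med - 200) / 200, 0.05)

  # rod sites lie within width/2 of the axis segment
  rod <- ag[[1L]]
  u <- c(cos(rod$orientation), sin(rod$orientation))
  rel <- sweep(rod$sites, 2L, rod$center)
  along <- rel %*% u
  across <- rel %*% c(-u[2L], u[1L])
  expect_true(all(abs(across) <= rod$width / 2 + 1e-9))
  expect_true(all(abs(along) <= rod$length / 2 + 1e-9))
  expect_equal(rod$n_sites, max(1L, round(p$site_density * rod$length)))
})

test_that("localization counts follow the binomial binding model", {
  set.seed(102)
  p <- simulation_params(n_aggregates = 1L, length_median = 200,
                         length_sigma_log = 1e-9, p_bind = 0.01,
                         background_rate = 0, n_frames = 8000L)
  # one rod of exactly 20 sites
  ag <- sample_aggregates(p)
  ag[[1L]]$sites <- ag[[1L]]$sites[1:20, ]
  ag[[1L]]$n_sites <- 20L
  tab <- simulate_localizations(ag, p)
  expected <- 20 * 8000 * 0.01
  expect_lt(abs(nrow(tab) - expected), 4 * sqrt(expected))

  # localizations stay near their aggregate (Gaussian tail bound)
  d <- sqrt((tab$x - ag[[1L]]$center[1L])^2 + (tab$y - ag[[1L]]$center[2L])^2)
  expect_true(all(d <= ag[[1L]]$length / 2 + 5 * p$sigma_loc))
  expect_true(all(tab$source_id == 0L))
})

test_that("zero binding and zero background give an empty table", {
  set.seed(103)
  p <- simulation_params(n_aggregates = 5L, p_bind = 0, background_rate = 0)
  expect_equal(nrow(simulate_localizations(sample_aggregates(p), p)), 0L)
})

test_that("localization yield scales linearly with p_bind and n_frames", {
  set.seed(104)
  yield <- function(p_bind, n_frames) {
    p <- simulation_params(n_aggregates = 50L, p_bind = p_bind,
                           background_rate = 0, n_frames = n_frames)
    ag <- sample_aggregates(p)
    nrow(simulate_localizations(ag, p)) /
      sum(vapply(ag, `[[`, 0L, "n_sites"))
  }
  y1 <- yield(2e-4, 4000L)
  y2 <- yield(4e-4, 4000L)
  y3 <- yield(2e-4, 8000L)
  expect_equal(y2 / y1, 2, tolerance = 0.15)
  expect_equal(y3 / y1, 2, tolerance = 0.15)
})

test_that("drift displaces localizations and fiducials as specified", {
  set.seed(105)
  p <- simulation_params(n_aggregates = 0L, n_fiducials = 2L,
                         drift_model = "linear", drift_rate = 0.05,
                         drift_angle = 0, n_frames = 8000L,
                         fiducial_sigma = 0, background_rate = 0)
  res <- apply_drift_and_fiducials(localization_table(), p)
  expect_equal(res$trajectory$dx[1L], 0)
  expect_equal(res$trajectory$dy[1L], 0)
  expect_equal(res$trajectory$dx[8000L], 0.05 * 7999, tolerance = 1e-9)
  # fiducial displacement at the last frame ~ 400 nm from frame 0
  f1 <- res$table[res$table$source_id == -2L, ]
  first <- f1[f1$frame == 0L, ][1L, ]
  last <- f1[f1$frame == 7999L & abs(f1$y - first$y) < 1, ][1L, ]
  expect_equal(last$x - first$x, 0.05 * 7999, tolerance = 1e-6)

  # zero drift: positions unchanged, fiducial rows appended
  set.seed(106)
  base <- make_loc_table(20, n_frames = 100)
  p0 <- simulation_params(n_aggregates = 0L, n_fiducials = 1L,
                          drift_rate = 0, n_frames = 100L)
  res0 <- apply_drift_and_fiducials(base, p0)
  kept <- res0$table[res0$table$source_id != -2L, ]
  expect_equal(sort(kept$x), sort(base$x))
  expect_equal(sum(res0$table$source_id == -2L), 100L)
})

test_that("the same seed reproduces byte-identical simulated tables", {
  run <- function() {
    set.seed(321)
    p <- scenario_preset("fraction20", n_aggregates = 20L)
    tab <- simulate_localizations(sample_aggregates(p), p)
    path <- tempfile()
    write_localizations(tab, path)
    on.exit(unlink(path))
    readBin(path, "raw", file.size(path))
  }
  expect_identical(run(), run())
})
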