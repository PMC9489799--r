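test_that("eccentricity closed forms: square, collinear, two points", {
  s <- 120
  square <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  m <- measure_cluster(square)
  expect_equal(m$eccentricity, 0)
  expect_equal(m$length, s * sqrt(2))

  line <- cbind(c(0, 50, 130, 260), rep(5, 4))
  expect_equal(measure_cluster(line)$eccentricity, 1)

  two <- rbind(c(0, 0), c(10, 10))
  expect_equal(measure_cluster(two)$eccentricity, 1)

  expect_error(measure_cluster(rbind(c(1, 1))), "2 points")
  same <- rbind(c(3, 3), c(3, 3), c(3, 3))
  expect_equal(measure_cluster(same)$eccentricity, 0)
  expect_equal(measure_cluster(same)$length, 0)
})

test_that("uniform elliptical samples recover sqrt(1 - b^2/a^2)", {
  set.seed(401)
  for (ab in c(2, 4)) {
    th <- runif(10000, 0, 2 * pi)
    pts <- cbind(ab * 100 * cos(th), 100 * sin(th))
    ecc <- measure_cluster(pts)$eccentricity
    expect_lt(abs(ecc - sqrt(1 - 1 / ab^2)), 0.02)
  }
})

test_that("length and eccentricity are rigid-motion invariant", {
  set.seed(402)
  pts <- make_blob(40, c(0, 0), 50)
  base <- measure_cluster(pts)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    moved <- pts %*% R + matrix(runif(2, -1e4, 1e4), nrow(pts), 2,
                                byrow = TRUE)
    m <- measure_cluster(moved)
    expect_equal(m$length, base$length, tolerance = 1e-9)
    expect_equal(m$eccentricity, base$eccentricity, tolerance = 1e-9)
  }
})

test_that("adding a point never decreases the max Feret length", {
  set.seed(403)
  pts <- make_blob(20, c(0, 0), 30)
  len <- measure_cluster(pts)$length
  for (i in 1:20) {
    pts <- rbind(pts, runif(2, -100, 100))
    len2 <- measure_cluster(pts)$length
    expect_gte(len2, len)
    len <- len2
  }
})

test_that("summaries: empty labelings, ground-truth purity, length ordering", {
  set.seed(404)
  tab <- make_loc_table(30)
  allnoise <- list(labels = rep(-1L, 30))
  s <- summarize_sample(tab, allnoise)
  expect_equal(nrow(s$records), 0L)
  expect_true(s$summary$no_clusters)

  # two ground-truth clusters, no background: DBSCAN recovers the partition
  pts <- rbind(make_blob(25, c(1000, 1000), 15),
               make_blob(25, c(3000, 3000), 15))
  tab2 <- localization_table(frame = rep(0L, 50), x = pts[, 1L],
                             y = pts[, 2L], intensity = rep(1000, 50),
                             precision = rep(15, 50),
                             source_id = rep(c(0L, 1L), each = 25))
  lab2 <- dbscan_cluster(tab2, 75, 9)
  s2 <- summarize_sample(tab2, lab2)
  expect_equal(nrow(s2$records), 2L)
  for (k in 0:1) {
    ids <- unique(tab2$source_id[lab2$labels == k])
    expect_length(ids, 1L)  # 100% source purity
  }
  expect_error(summarize_sample(tab2, list(labels = 1L)), "match")

  # rods of increasing ground-truth length produce increasing measured medians
  set.seed(405)
  med <- vapply(c(190, 390), function(L) {
    p <- simulation_params(n_aggregates = 60L, length_median = L,
                           fov_size = 60000)
    measure_population(p)$summary$median_length
  }, 0)
  expect_lt(med[1L], med[2L])
})

test_that("disk populations are rounder than rod populations", {
  set.seed(406)
  ecc_of <- function(rod_fraction) {
    p <- simulation_params(n_aggregates = 60L, length_median = 300,
                           rod_fraction = rod_fraction, fov_size = 60000)
    measure_population(p)$summary$mean_eccentricity
  }
  expect_lt(ecc_of(0), ecc_of(1))
})

test_that("super-resolution rendering conserves mass and shifts with data", {
  expect_equal(sum(render_superres(localization_table(), pixel = 10,
                                   fov_size = 500)), 0)
  one <- localization_table(frame = 0L, x = 105, y = 205, intensity = 1,
                            precision = 10)
  img <- render_superres(one, pixel = 10, blur_sigma = 20, fov_size = 500)
  expect_equal(sum(img), 1, tolerance = 1e-9)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 21, col = 11))

  set.seed(407)
  tab <- make_loc_table(200)
  tab$x <- pmin(tab$x, 4000); tab$y <- pmin(tab$y, 4000)
  imgA <- render_superres(tab, 10, blur_sigma = 20, fov_size = 5000)
  shifted <- tab; shifted$x <- shifted$x + 10
  imgB <- render_superres(shifted, 10, blur_sigma = 20, fov_size = 5000)
  expect_equal(imgB[, 2:500], imgA[, 1:499], tolerance = 1e-9)
})
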