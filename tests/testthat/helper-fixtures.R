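# Shared fixtures: all synthetic, built in code at test time.

# isotropic Gaussian blob of localizations around a center
make_blob <- function(n, center, sd = 10) {
  cbind(center[1L] + rnorm(n, 0, sd), center[2L] + rnorm(n, 0, sd))
}

# small valid localization table
make_loc_table <- function(n = 10, n_frames = 100) {
  localization_table(frame = sample.int(n_frames, n, replace = TRUE) - 1L,
                     x = runif(n, 0, 5000), y = runif(n, 0, 5000),
                     intensity = rexp(n, 1 / 1000),
                     precision = runif(n, 5, 30),
                     source_id = rep(-1L, n))
}

# one simulated rod population measured through filter + cluster + morphometry
measure_population <- function(params, preset = "thx",
                               correct_length = FALSE) {
  cfg <- analysis_config(preset = preset)
  aggregates <- sample_aggregates(params)
  tab <- simulate_localizations(aggregates, params)
  f <- filter_localizations(tab, cfg$min_signal, cfg$max_precision)
  lab <- dbscan_cluster(f, cfg$eps, cfg$min_pts)
  summarize_sample(f, lab, correct_length = correct_length)
}

# partition-equality up to label renaming
same_partition <- function(la, lb) {
  if (length(la) != length(lb)) return(FALSE)
  if (!identical(la == -1L, lb == -1L)) return(FALSE)
  m <- la != -1L
  if (!any(m)) return(TRUE)
  tab <- table(la[m], lb[m])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
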