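# Synthetic-data generation: ground-truth aggregate populations,
# transient-binding localization tables, stage drift and fiducial beads.
#
# The generator abstracts imager binding kinetics to an independent per-site
# per-frame Bernoulli event; localization noise is isotropic Gaussian with sd
# sigma_loc, photon counts are exponential (heavy-tailed, as single-molecule
# intensities are), and the recorded per-localization precision follows
# sigma_loc * sqrt(photon_mean / photons) so that the filtering stage sees
# realistic variation around the nominal 20 nm precision.

#' Simulation parameters
#'
#' Defaults describe a transient-binding super-resolution experiment:
#' 8000 frames at 50 ms, 20 nm localization precision, aggregates placed
#' uniformly in the field of view.
#'
#' @param n_aggregates number of aggregates.
#' @param length_median median of the lognormal length distribution (nm).
#' @param length_sigma_log lognormal sigma (log scale, unitless).
#' @param rod_fraction fraction of aggregates that are rods (the rest are
#'   disks whose `length` is the diameter).
#' @param rod_width lateral extent of rods (nm); binding sites get uniform
#'   lateral jitter across it, approximating a protofilament cross-section.
#' @param site_density binding sites per nm of rod length.
#' @param disk_sites binding sites per disk aggregate.
#' @param p_bind per-site per-frame binding probability.
#' @param photon_mean mean photons per localization (exponential model).
#' @param sigma_loc localization noise sd (nm).
#' @param background_rate false localizations per um^2 per frame.
#' @param n_fiducials number of fiducial beads.
#' @param fiducial_sigma fiducial localization noise sd (nm).
#' @param fiducial_photons photons recorded for fiducial localizations.
#' @param drift_model `"linear"` or `"random-walk"`.
#' @param drift_rate drift magnitude (nm/frame; step sd for random walk).
#' @param drift_angle direction of linear drift (radians).
#' @param fov_size field-of-view side (nm).
#' @param n_frames number of acquisition frames.
#' @return A named list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_aggregates = 100L,
                              length_median = 190,
                              length_sigma_log = 0.25,
                              rod_fraction = 1,
                              rod_width = 10,
                              site_density = 0.1,
                              disk_sites = 10L,
                              p_bind = 4e-4,
                              photon_mean = 1000,
                              sigma_loc = 20,
                              background_rate = 1e-5,
                              n_fiducials = 0L,
                              fiducial_sigma = 2,
                              fiducial_photons = 5e4,
                              drift_model = c("linear", "random-walk"),
                              drift_rate = 0,
                              drift_angle = pi / 4,
                              fov_size = 20000,
                              n_frames = 8000L) {
  drift_model <- match.arg(drift_model)
  params <- list(n_aggregates = as.integer(n_aggregates),
                 length_median = length_median,
                 length_sigma_log = length_sigma_log,
                 rod_fraction = rod_fraction, rod_width = rod_width,
                 site_density = site_density,
                 disk_sites = as.integer(disk_sites),
                 p_bind = p_bind, photon_mean = photon_mean,
                 sigma_loc = sigma_loc, background_rate = background_rate,
                 n_fiducials = as.integer(n_fiducials),
                 fiducial_sigma = fiducial_sigma,
                 fiducial_photons = fiducial_photons,
                 drift_model = drift_model, drift_rate = drift_rate,
                 drift_angle = drift_angle,
                 fov_size = fov_size, n_frames = as.integer(n_frames))
  stopifnot(params$p_bind >= 0, params$p_bind <= 1, params$sigma_loc > 0,
            params$background_rate >= 0, params$length_median > 0,
            params$rod_fraction >= 0, params$rod_fraction <= 1,
            params$fov_size > 0, params$n_frames >= 1)
  class(params) <- c("simulation_params", "list")
  params
}

#' Named simulation scenarios
#'
#' Presets emulating the study conditions of the two experiment families:
#' the four sucrose-gradient fractions of in-vitro aggregates
#' (`"fraction20"` ... `"fraction50"`, rod-like populations with lognormal
#' length medians 190/240/290/390 nm) and the brain-extract populations
#' (`"pd_brain"`/`"hc_brain"`, mixed rod/disk populations with medians
#' 55/68 nm and a broader spread so that most aggregates are below 100 nm
#' with a heavier tail in the control group). Brain presets use one large
#' synthetic field equivalent to many pooled fields of view at a sparse
#' single-molecule surface density (~0.03 aggregates/um^2).
#'
#' @param name scenario name.
#' @param ... overrides passed through to [simulation_params()].
#' @return A [simulation_params()] object.
#' @export
scenario_preset <- function(name = c("fraction20", "fraction30", "fraction40",
                                     "fraction50", "pd_brain", "hc_brain"),
                            ...) {
  name <- match.arg(name)
  base <- switch(name,
    fraction20 = list(length_median = 190),
    fraction30 = list(length_median = 240),
    fraction40 = list(length_median = 290),
    fraction50 = list(length_median = 390),
    pd_brain = list(length_median = 55, length_sigma_log = 0.5,
                    rod_fraction = 0.5, n_aggregates = 6000L,
                    fov_size = 450000),
    hc_brain = list(length_median = 68, length_sigma_log = 0.5,
                    rod_fraction = 0.5, n_aggregates = 6000L,
                    fov_size = 450000))
  # fraction presets: imager density high enough that clusters retain
  # >= 50 localizations after the 100-photon / 20-nm filter (which keeps
  # ~37% of exponential-photon localizations)
  if (startsWith(name, "fraction"))
    base <- c(base, list(n_aggregates = 300L, fov_size = 100000,
                         p_bind = 1.2e-3))
  overrides <- list(...)
  base[names(overrides)] <- overrides
  do.call(simulation_params, base)
}

#' Sample a ground-truth aggregate population
#'
#' Lengths are lognormal with the requested median; shapes are rods (binding
#' sites evenly spaced along the axis with uniform lateral jitter across the
#' width) or disks (sites uniform over the disk). Centers are uniform in the
#' field of view with a margin of half the aggregate length.
#'
#' @param params a [simulation_params()] object.
#' @return A list of aggregates, each a list with `id`, `shape`, `center`,
#'   `orientation`, `length`, `width`, `n_sites` and an `n_sites x 2` site
#'   matrix in absolute nm coordinates.
#' @export
sample_aggregates <- function(params) {
  n <- params$n_aggregates
  if (n == 0L) return(list())
  lengths <- rlnorm(n, meanlog = log(params$length_median),
                    sdlog = params$length_sigma_log)
  if (any(lengths >= params$fov_size))
    stop("field of view too small for the sampled aggregate lengths",
         call. = FALSE)
  is_rod <- runif(n) < params$rod_fraction
  orientation <- runif(n, 0, pi)
  cx <- runif(n, lengths / 2, params$fov_size - lengths / 2)
  cy <- runif(n, lengths / 2, params$fov_size - lengths / 2)
  lapply(seq_len(n), function(i) {
    L <- lengths[i]
    if (is_rod[i]) {
      k <- max(1L, as.integer(round(params$site_density * L)))
      t <- if (k == 1L) 0 else seq(-L / 2, L / 2, length.out = k)
      lat <- runif(k, -params$rod_width / 2, params$rod_width / 2)
      u <- c(cos(orientation[i]), sin(orientation[i]))
      v <- c(-u[2L], u[1L])
      sites <- cbind(cx[i] + t * u[1L] + lat * v[1L],
                     cy[i] + t * u[2L] + lat * v[2L])
      shape <- "rod"
    } else {
      k <- max(1L, params$disk_sites)
      r <- (L / 2) * sqrt(runif(k))
      a <- runif(k, 0, 2 * pi)
      sites <- cbind(cx[i] + r * cos(a), cy[i] + r * sin(a))
      shape <- "disk"
    }
    list(id = i - 1L, shape = shape, center = c(cx[i], cy[i]),
         orientation = orientation[i], length = L,
         width = if (is_rod[i]) params$rod_width else L,
         n_sites = nrow(sites), sites = sites)
  })
}

#' Simulate transient-binding localizations
#'
#' Each binding site emits, independently per frame with probability
#' `p_bind`, one localization at the site position plus isotropic Gaussian
#' noise of sd `sigma_loc`. Photons are exponential with mean `photon_mean`
#' and the recorded precision is `sigma_loc * sqrt(photon_mean / photons)`.
#' Background false localizations arrive as a homogeneous spatio-temporal
#' Poisson process at `background_rate` per um^2 per frame with
#' `source_id = -1`.
#'
#' @param aggregates output of [sample_aggregates()].
#' @param params the matching [simulation_params()].
#' @return A localization table; `source_id` records the emitting aggregate.
#' @export
simulate_localizations <- function(aggregates, params) {
  sites <- do.call(rbind, lapply(aggregates, `[[`, "sites"))
  ids <- unlist(lapply(aggregates, function(a) rep(a$id, a$n_sites)))
  parts <- list()
  if (!is.null(sites) && nrow(sites) && params$p_bind > 0) {
    counts <- rbinom(nrow(sites), params$n_frames, params$p_bind)
    keep <- counts > 0L
    if (any(keep)) {
      idx <- rep(which(keep), counts[keep])
      m <- length(idx)
      frames <- unlist(lapply(counts[keep],
                              function(k) sample.int(params$n_frames, k))) - 1L
      parts$signal <- data.frame(
        frame = frames,
        x = sites[idx, 1L] + rnorm(m, 0, params$sigma_loc),
        y = sites[idx, 2L] + rnorm(m, 0, params$sigma_loc),
        photons = rexp(m, 1 / params$photon_mean),
        source_id = ids[idx])
    }
  }
  if (params$background_rate > 0) {
    area_um2 <- (params$fov_size / 1000)^2
    n_bg <- rpois(1L, params$background_rate * area_um2 * params$n_frames)
    if (n_bg > 0L)
      parts$background <- data.frame(
        frame = sample.int(params$n_frames, n_bg, replace = TRUE) - 1L,
        x = runif(n_bg, 0, params$fov_size),
        y = runif(n_bg, 0, params$fov_size),
        photons = rexp(n_bg, 1 / params$photon_mean),
        source_id = -1L)
  }
  if (!length(parts))
    return(localization_table())
  all <- do.call(rbind, parts)
  all <- all[order(all$frame, all$x), , drop = FALSE]
  localization_table(frame = all$frame, x = all$x, y = all$y,
                     intensity = all$photons,
                     precision = params$sigma_loc *
                       sqrt(params$photon_mean / all$photons),
                     source_id = all$source_id)
}

#' Simulate a drift trajectory
#'
#' @param params a [simulation_params()] object.
#' @return A data.frame `frame, dx, dy` of per-frame displacements (nm) with
#'   `(0, 0)` at frame 0.
#' @export
drift_trajectory <- function(params) {
  f <- seq_len(params$n_frames) - 1L
  if (params$drift_model == "linear") {
    dx <- params$drift_rate * f * cos(params$drift_angle)
    dy <- params$drift_rate * f * sin(params$drift_angle)
  } else {
    dx <- cumsum(c(0, rnorm(params$n_frames - 1L, 0, params$drift_rate)))
    dy <- cumsum(c(0, rnorm(params$n_frames - 1L, 0, params$drift_rate)))
  }
  data.frame(frame = f, dx = dx, dy = dy)
}

#' Apply stage drift and append fiducial-bead localizations
#'
#' Every localization is displaced by the trajectory value of its frame.
#' Each fiducial bead contributes one bright localization per frame (noise sd
#' `fiducial_sigma`, `source_id = -2`), also displaced by the drift.
#'
#' @param table a localization table.
#' @param params a [simulation_params()] object.
#' @return A list with the drifted `table`, the `trajectory` data.frame and
#'   `fiducials`, the true (frame-0) bead positions as an `n x 2` matrix.
#' @export
apply_drift_and_fiducials <- function(table, params) {
  validate_localizations(table)
  if (params$n_fiducials < 1L && params$drift_rate > 0)
    warning("drift without fiducials cannot be corrected downstream",
            call. = FALSE)
  traj <- drift_trajectory(params)
  out <- table
  if (nrow(out)) {
    out$x <- out$x + traj$dx[out$frame + 1L]
    out$y <- out$y + traj$dy[out$frame + 1L]
  }
  fid_pos <- NULL
  if (params$n_fiducials >= 1L) {
    fid_pos <- cbind(runif(params$n_fiducials, 0.1, 0.9) * params$fov_size,
                     runif(params$n_fiducials, 0.1, 0.9) * params$fov_size)
    n <- params$n_frames
    fid <- do.call(rbind, lapply(seq_len(params$n_fiducials), function(i) {
      data.frame(frame = traj$frame,
                 x = fid_pos[i, 1L] + traj$dx + rnorm(n, 0, params$fiducial_sigma),
                 y = fid_pos[i, 2L] + traj$dy + rnorm(n, 0, params$fiducial_sigma),
                 intensity = params$fiducial_photons,
                 precision = max(params$fiducial_sigma, 0.5),
                 source_id = -2L)
    }))
    out <- rbind(out, fid)
    out <- out[order(out$frame, out$x), , drop = FALSE]
    rownames(out) <- NULL
  }
  list(table = validate_localizations(out), trajectory = traj,
       fiducials = fid_pos)
}
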