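# Liposome calcium-influx quantification.
#
# Three co-registered TIRF stacks of the same positions are acquired:
# background (dye-loaded liposomes alone), sample (after adding the
# aggregate preparation) and ionomycin (ionophore fully permeabilizes the
# liposomes, defining 100%). Per matched spot,
#   influx% = 100 * (F_sample - F_background) / (F_ionomycin - F_background)
# with F the spot fluorescence under each condition. The ratio is invariant
# under any common affine rescaling of the intensities, so a constant
# camera baseline cancels and per-spot values are not clamped to [0, 100]
# (noise can produce small negatives; clamping would bias field-of-view
# means).

#' Average an image stack over frames
#'
#' @param stack a `[ny, nx, n_frames]` array (or a matrix, returned as is).
#' @return The per-pixel arithmetic mean across frames.
#' @export
average_frames <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (length(dim(stack)) != 3L || dim(stack)[3L] < 1L)
    stop("stack must hold at least one frame", call. = FALSE)
  rowMeans(stack, dims = 2L)
}

#' Match spots across three conditions
#'
#' Mutual nearest-neighbour matching: spots a_i and b_j match when each is
#' the other's nearest neighbour and their distance is at most `radius`;
#' a triplet requires the background spot to match mutually in both other
#' conditions. Unmatched spots are excluded and counted.
#'
#' @param spots_background,spots_sample,spots_ionomycin data.frames with
#'   `x, y` (nm) columns, e.g. from [detect_spots()].
#' @param radius maximum match distance (nm); default two diffraction-limited
#'   pixels.
#' @return A list: `triplets` (data.frame of row indices `background,
#'   sample, ionomycin`) and `n_unmatched` per condition.
#' @export
match_spots <- function(spots_background, spots_sample, spots_ionomycin,
                        radius = 474) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  mutual_nn <- function(a, b) {
    # index in b of the mutual NN of each a row, NA when absent
    if (!nrow(a) || !nrow(b)) return(rep(NA_integer_, nrow(a)))
    d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    ab <- apply(d2, 1L, which.min)
    ba <- apply(d2, 2L, which.min)
    ok <- ba[ab] == seq_len(nrow(a)) &
      d2[cbind(seq_len(nrow(a)), ab)] <= radius^2
    ifelse(ok, ab, NA_integer_)
  }
  to_s <- mutual_nn(spots_background, spots_sample)
  to_i <- mutual_nn(spots_background, spots_ionomycin)
  ok <- !is.na(to_s) & !is.na(to_i)
  triplets <- data.frame(background = which(ok), sample = to_s[ok],
                         ionomycin = to_i[ok])
  list(triplets = triplets,
       n_unmatched = c(background = nrow(spots_background) - sum(ok),
                       sample = nrow(spots_sample) - sum(ok),
                       ionomycin = nrow(spots_ionomycin) - sum(ok)))
}

#' Compute per-spot and field-of-view calcium influx
#'
#' @param f_background,f_sample,f_ionomycin spot fluorescence per matched
#'   triplet (same length).
#' @return A list: `spots` (data.frame with the three intensities,
#'   `influx_pct` and a `valid` flag), `mean_influx_pct` (arithmetic mean
#'   over valid spots) and `n_invalid`. Spots with
#'   `F_ionomycin <= F_background` are flagged invalid and excluded from the
#'   mean; all spots invalid is an error (no responsive liposomes).
#' @export
compute_influx <- function(f_background, f_sample, f_ionomycin) {
  n <- length(f_background)
  stopifnot(length(f_sample) == n, length(f_ionomycin) == n)
  if (!n) stop("no matched spots", call. = FALSE)
  valid <- is.finite(f_background) & is.finite(f_sample) &
    is.finite(f_ionomycin) & (f_ionomycin > f_background)
  influx <- ifelse(valid,
                   100 * (f_sample - f_background) /
                     (f_ionomycin - f_background), NA_real_)
  if (!any(valid))
    stop("no responsive liposomes: F_ionomycin <= F_background for all spots",
         call. = FALSE)
  list(spots = data.frame(spot_id = seq_len(n) - 1L,
                          F_background = f_background,
                          F_sample = f_sample, F_ionomycin = f_ionomycin,
                          influx_pct = influx, valid = valid),
       mean_influx_pct = mean(influx[valid]),
       n_invalid = sum(!valid))
}

.aperture_sum <- function(image, ix, iy, r_px) {
  ny <- nrow(image); nx <- ncol(image)
  rows <- max(1L, iy - r_px):min(ny, iy + r_px)
  cols <- max(1L, ix - r_px):min(nx, ix + r_px)
  sum(image[rows, cols])
}

#' Analyze an influx experiment from three stacks
#'
#' Averages each stack over its frames, detects spots independently in each
#' averaged image, matches them by mutual nearest neighbour and evaluates
#' the influx percentage per spot. Spot fluorescence is the integrated
#' aperture sum ((2r+1)^2 pixels); the camera baseline cancels in the
#' influx ratio.
#'
#' @param stack_background,stack_sample,stack_ionomycin `[ny, nx, frames]`
#'   arrays of the three conditions.
#' @param pixel_size camera pixel (nm).
#' @param radius matching radius (nm).
#' @param aperture_px aperture half-width in pixels.
#' @param detect_k detection threshold in robust sd units.
#' @return The [compute_influx()] result, plus `n_unmatched`.
#' @export
analyze_influx_experiment <- function(stack_background, stack_sample,
                                      stack_ionomycin, pixel_size = 237,
                                      radius = 474, aperture_px = 2L,
                                      detect_k = 5) {
  avg_b <- average_frames(stack_background)
  avg_s <- average_frames(stack_sample)
  avg_i <- average_frames(stack_ionomycin)
  sp_b <- detect_spots(avg_b, k = detect_k, pixel_size = pixel_size)
  sp_s <- detect_spots(avg_s, k = detect_k, pixel_size = pixel_size)
  sp_i <- detect_spots(avg_i, k = detect_k, pixel_size = pixel_size)
  m <- match_spots(sp_b, sp_s, sp_i, radius = radius)
  tr <- m$triplets
  if (!nrow(tr)) stop("no spot triplets matched across conditions",
                      call. = FALSE)
  f_of <- function(img, sp, idx) vapply(idx, function(i)
    .aperture_sum(img, sp$ix[i] + 1L, sp$iy[i] + 1L, aperture_px), 0)
  res <- compute_influx(f_of(avg_b, sp_b, tr$background),
                        f_of(avg_s, sp_s, tr$sample),
                        f_of(avg_i, sp_i, tr$ionomycin))
  res$n_unmatched <- m$n_unmatched
  res
}

#' Simulate a liposome influx experiment
#'
#' Generates three co-registered 50-frame stacks of the same liposome field:
#' per liposome the background fluorescence is F_b, the ionomycin
#' fluorescence F_b + A (A the per-liposome dynamic range) and the sample
#' fluorescence F_b + influx * A. Rendering and Poisson noise follow
#' [render_frame_stack()].
#'
#' @param n_liposomes number of liposomes.
#' @param true_influx per-liposome influx fraction in `[0, 1]` (recycled).
#' @param fov_size field side (nm).
#' @param pixel_size camera pixel (nm).
#' @param n_frames frames per condition.
#' @param psf_sigma PSF sd (nm).
#' @param baseline camera baseline counts.
#' @param f_background_mean,dynamic_range_mean lognormal means of F_b and A
#'   (photons per frame).
#' @param noise add Poisson noise?
#' @return A list: `stack_background`, `stack_sample`, `stack_ionomycin`,
#'   and `ground_truth` (positions, F_b, A, influx per liposome).
#' @export
simulate_influx_experiment <- function(n_liposomes = 100L, true_influx = 0.3,
                                       fov_size = 30000, pixel_size = 237,
                                       n_frames = 50L, psf_sigma = 150,
                                       baseline = 100,
                                       f_background_mean = 300,
                                       dynamic_range_mean = 1500,
                                       noise = TRUE) {
  true_influx <- rep_len(true_influx, n_liposomes)
  if (any(true_influx < 0 | true_influx > 1))
    stop("true_influx must lie in [0, 1]", call. = FALSE)
  margin <- 5 * psf_sigma
  pos <- cbind(runif(n_liposomes, margin, fov_size - margin),
               runif(n_liposomes, margin, fov_size - margin))
  f_b <- rlnorm(n_liposomes, log(f_background_mean), 0.2)
  a <- rlnorm(n_liposomes, log(dynamic_range_mean), 0.2)
  render <- function(photons)
    render_frame_stack(pos, photons, psf_sigma, pixel_size, fov_size,
                       n_frames = n_frames, baseline = baseline,
                       noise = noise)
  list(stack_background = render(f_b),
       stack_sample = render(f_b + true_influx * a),
       stack_ionomycin = render(f_b + a),
       ground_truth = list(positions = pos, F_background = f_b,
                           dynamic_range = a, influx = true_influx))
}
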