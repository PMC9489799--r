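# Image formation and rendering.
#
# Convention: continuous nm coordinates with the origin at the lower-left
# corner of the field of view; pixel (i, j) covers the half-open square
# [i*p, (i+1)*p) x [j*p, (j+1)*p). Images are matrices indexed [iy, ix]
# with row 1 the bottom row.

.gauss_pixel_fractions <- function(center, sigma, n_pix, pixel) {
  # integral of a unit 1D Gaussian over each pixel along one axis
  edges <- (0:n_pix) * pixel
  diff(pnorm(edges, mean = center, sd = sigma))
}

#' Render a diffraction-limited frame stack
#'
#' Each spot contributes a pixel-integrated 2D Gaussian whose total integral
#' equals its photon count (before noise and edge losses). Frames share the
#' same noiseless expectation; per-pixel Poisson noise is added on top of a
#' constant baseline when `noise = TRUE`.
#'
#' @param positions `n x 2` matrix of spot centers (nm), inside the FOV.
#' @param photons photons per spot per frame (length n or scalar).
#' @param psf_sigma PSF standard deviation (nm); must be positive.
#' @param pixel_size camera pixel (nm).
#' @param fov_size field-of-view side (nm).
#' @param n_frames number of frames to render.
#' @param baseline constant background counts per pixel.
#' @param noise add Poisson noise per frame?
#' @return A `[ny, nx, n_frames]` array of counts. A warning flags values
#'   exceeding the 16-bit range.
#' @export
render_frame_stack <- function(positions, photons, psf_sigma, pixel_size,
                               fov_size, n_frames = 1L, baseline = 100,
                               noise = TRUE) {
  if (!is.numeric(psf_sigma) || psf_sigma <= 0)
    stop("psf_sigma must be > 0", call. = FALSE)
  n_pix <- as.integer(ceiling(fov_size / pixel_size))
  positions <- matrix(positions, ncol = 2L)
  if (nrow(positions) &&
      (any(positions < 0) || any(positions > fov_size)))
    stop("spot positions must lie inside the field of view", call. = FALSE)
  photons <- rep_len(photons, nrow(positions))
  expected <- matrix(baseline, n_pix, n_pix)
  for (s in seq_len(nrow(positions))) {
    fx <- .gauss_pixel_fractions(positions[s, 1L], psf_sigma, n_pix, pixel_size)
    fy <- .gauss_pixel_fractions(positions[s, 2L], psf_sigma, n_pix, pixel_size)
    expected <- expected + photons[s] * (fy %o% fx)
  }
  stack <- array(0, c(n_pix, n_pix, n_frames))
  for (f in seq_len(n_frames))
    stack[, , f] <- if (noise)
      matrix(rpois(length(expected), expected), n_pix, n_pix) else expected
  if (any(stack > 65535))
    warning("rendered counts exceed the 16-bit range", call. = FALSE)
  stack
}

.conv1_zero <- function(v, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  padded <- c(rep(0, r), v, rep(0, r))
  out <- stats::filter(padded, kernel, sides = 2L)
  as.numeric(out[(r + 1L):(r + length(v))])
}

#' Render a super-resolution image from localizations
#'
#' A 2D histogram of localization positions at the given pixel size,
#' convolved with a unit-mass Gaussian kernel of sd `blur_sigma`. The image
#' therefore integrates to the number of localizations, up to mass blurred
#' across the image border (zero-padded convolution; edge losses are the
#' only deviation).
#'
#' @param table a localization table.
#' @param pixel rendering pixel size (nm).
#' @param blur_sigma Gaussian rendering blur (nm); 0 disables blurring.
#' @param fov_size field-of-view side (nm); defaults to covering the data.
#' @return A `[ny, nx]` matrix with attribute `pixel_size`.
#' @export
render_superres <- function(table, pixel, blur_sigma = 20, fov_size = NULL) {
  if (!is.numeric(pixel) || pixel <= 0) stop("pixel must be > 0", call. = FALSE)
  if (is.null(fov_size))
    fov_size <- if (nrow(table)) max(table$x, table$y) + pixel else pixel
  n_pix <- as.integer(ceiling(fov_size / pixel))
  img <- matrix(0, n_pix, n_pix)
  if (nrow(table)) {
    ix <- pmin(pmax(floor(table$x / pixel), 0), n_pix - 1L)
    iy <- pmin(pmax(floor(table$y / pixel), 0), n_pix - 1L)
    counts <- tabulate(iy + n_pix * ix + 1L, nbins = n_pix * n_pix)
    img <- matrix(counts, n_pix, n_pix)
  }
  if (blur_sigma > 0 && nrow(table)) {
    s_px <- blur_sigma / pixel
    r <- max(1L, as.integer(ceiling(3 * s_px)))
    kernel <- dnorm(-r:r, sd = s_px)
    kernel <- kernel / sum(kernel)
    img <- apply(img, 2L, .conv1_zero, kernel = kernel)
    img <- t(apply(img, 1L, .conv1_zero, kernel = kernel))
  }
  attr(img, "pixel_size") <- pixel
  img
}

#' Detect bright spots in an image
#'
#' Candidates are strict 8-neighbourhood local maxima above a threshold
#' (default: image median plus `k` robust noise sd, estimated by the scaled
#' MAD); candidates within `min_sep` pixels of a brighter one are suppressed.
#'
#' @param image a numeric matrix `[iy, ix]`.
#' @param k threshold in robust noise sd above the median (used when
#'   `threshold` is `NULL`).
#' @param threshold absolute intensity threshold overriding `k`.
#' @param min_sep suppression radius in pixels.
#' @param pixel_size pixel size (nm) used to report nm positions.
#' @return A data.frame `ix, iy` (0-based pixel indices), `x, y` (pixel
#'   centers, nm) and `peak`, ordered by decreasing peak value.
#' @export
detect_spots <- function(image, k = 5, threshold = NULL, min_sep = 3L,
                         pixel_size = 1) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels",
                                   call. = FALSE)
  if (is.null(threshold))
    threshold <- median(image) + k * mad(image)
  ny <- nrow(image); nx <- ncol(image)
  if (ny < 3L || nx < 3L)
    return(data.frame(ix = integer(), iy = integer(), x = numeric(),
                      y = numeric(), peak = numeric()))
  core <- image[2:(ny - 1L), 2:(nx - 1L), drop = FALSE]
  is_max <- core > threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- image[(2:(ny - 1L)) + dy, (2:(nx - 1L)) + dx, drop = FALSE]
    is_max <- is_max & (core >= nb)
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(ix = integer(), iy = integer(), x = numeric(),
                      y = numeric(), peak = numeric()))
  iy <- hits[, 1L] + 1L; ix <- hits[, 2L] + 1L
  peak <- image[cbind(iy, ix)]
  ord <- order(-peak, iy, ix)
  iy <- iy[ord]; ix <- ix[ord]; peak <- peak[ord]
  keep <- rep(TRUE, length(peak))
  for (i in seq_along(peak)) {
    if (!keep[i]) next
    if (i < length(peak)) {
      later <- (i + 1L):length(peak)
      clash <- abs(iy[later] - iy[i]) <= min_sep &
               abs(ix[later] - ix[i]) <= min_sep
      keep[later][clash] <- FALSE
    }
  }
  data.frame(ix = ix[keep] - 1L, iy = iy[keep] - 1L,
             x = (ix[keep] - 0.5) * pixel_size,
             y = (iy[keep] - 0.5) * pixel_size,
             peak = peak[keep])
}
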