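# Spot fitting, localization filtering and fiducial drift correction.
#
# Fitting uses a pixel-integrated 2D Gaussian plus constant baseline on a
# 7x7 pixel ROI. The nonlinear search runs over (x0, y0, log sigma); for
# fixed shape the amplitude and baseline are solved in closed form, which
# keeps the optimization low-dimensional and robust. The per-fit precision
# is the Thompson-style closed form
#   sigma_loc^2 = (s^2 + a^2/12) / N + 8*pi*s^4*b / (a^2 * N^2)
# with s the fitted PSF sd, a the pixel size, N the fitted photons and b the
# fitted background counts per pixel (Poisson variance proxy).

.thompson_precision <- function(psf_sigma, pixel, photons, background) {
  s2a <- psf_sigma^2 + pixel^2 / 12
  sqrt(s2a / photons +
       8 * pi * psf_sigma^4 * background / (pixel^2 * photons^2))
}

.fit_gaussian_roi <- function(roi, pixel_size) {
  n_roi <- nrow(roi)  # square ROI, coordinates in pixel units [0, n_roi]
  yv <- as.numeric(roi)
  shape_sse <- function(par) {
    x0 <- par[1L]; y0 <- par[2L]; s <- exp(par[3L])
    fx <- diff(pnorm(0:n_roi, x0, s))
    fy <- diff(pnorm(0:n_roi, y0, s))
    g <- as.numeric(fy %o% fx)
    X <- cbind(g, 1)
    coefs <- tryCatch(qr.coef(qr(X), yv), error = function(e) c(NA, NA))
    if (any(!is.finite(coefs))) return(list(sse = Inf, N = NA, b = NA))
    resid <- yv - X %*% coefs
    list(sse = sum(resid^2), N = coefs[1L], b = coefs[2L])
  }
  obj <- function(par) shape_sse(par)$sse
  init <- c(n_roi / 2, n_roi / 2, log(1.3))
  fit <- tryCatch(optim(init, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 800)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  x0 <- fit$par[1L]; y0 <- fit$par[2L]; s <- exp(fit$par[3L])
  if (x0 < 0 || x0 > n_roi || y0 < 0 || y0 > n_roi) return(NULL)
  lin <- shape_sse(fit$par)
  if (!is.finite(lin$N) || lin$N <= 0) return(NULL)
  list(x0 = x0, y0 = y0, sigma = s, N = lin$N, b = max(lin$b, 0))
}

#' Fit localizations from a diffraction-limited image stack
#'
#' Per frame, candidate spots are local maxima above the frame median plus
#' `detect_threshold_k` robust noise sd (scaled MAD); adjacent candidates
#' within 3 pixels keep only the brighter. Each candidate is fit on a 7x7
#' ROI; fits whose center leaves the ROI, fail to converge, or return
#' non-positive photons are dropped.
#'
#' @param stack a `[ny, nx, n_frames]` array (or matrix for one frame).
#' @param pixel_size camera pixel (nm).
#' @param detect_threshold_k detection threshold in robust sd units.
#' @return A localization table with `intensity` the fitted photon count and
#'   `precision` the Thompson estimate (nm). Extra columns `background` and
#'   `psf_sigma` carry the remaining fit parameters.
#' @export
localize_stack <- function(stack, pixel_size, detect_threshold_k = 5) {
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0", call. = FALSE)
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (length(stack) == 0L)
    return(localization_table())
  if (any(!is.finite(stack)))
    stop("stack contains non-finite pixels", call. = FALSE)
  half <- 3L
  rows <- list()
  for (f in seq_len(dim(stack)[3L])) {
    frame <- stack[, , f]
    cands <- detect_spots(frame, k = detect_threshold_k, min_sep = 3L)
    for (ci in seq_len(nrow(cands))) {
      iyc <- cands$iy[ci] + 1L; ixc <- cands$ix[ci] + 1L
      if (iyc - half < 1L || iyc + half > nrow(frame) ||
          ixc - half < 1L || ixc + half > ncol(frame)) next
      roi <- frame[(iyc - half):(iyc + half), (ixc - half):(ixc + half)]
      fit <- .fit_gaussian_roi(roi, pixel_size)
      if (is.null(fit)) next
      s_nm <- fit$sigma * pixel_size
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f - 1L,
        x = (ixc - 1L - half + fit$x0) * pixel_size,
        y = (iyc - 1L - half + fit$y0) * pixel_size,
        intensity = fit$N,
        precision = .thompson_precision(s_nm, pixel_size, fit$N, fit$b),
        source_id = -1L,
        background = fit$b,
        psf_sigma = s_nm)
    }
  }
  if (!length(rows)) return(localization_table())
  out <- do.call(rbind, rows)
  validate_localizations(out)
}

#' Filter localizations by signal and precision
#'
#' Keeps exactly the rows with `intensity >= min_signal` and
#' `precision <= max_precision`, preserving row order. The two standard
#' settings are 100 photons / 20 nm (thioflavin-X) and 60 photons / 40 nm
#' (aptamer PAINT).
#'
#' @param table a localization table.
#' @param min_signal minimum fitted photons.
#' @param max_precision maximum localization uncertainty (nm).
#' @param verbose report the surviving count with a message?
#' @return The filtered table.
#' @export
filter_localizations <- function(table, min_signal = 100, max_precision = 20,
                                 verbose = FALSE) {
  validate_localizations(table)
  keep <- table$intensity >= min_signal & table$precision <= max_precision
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (verbose)
    message(sprintf("filter: kept %d / %d localizations", nrow(out),
                    nrow(table)))
  out
}

#' Correct XY stage drift against fiducial beads
#'
#' Per frame, the drift estimate is the mean displacement of the matched
#' fiducial localizations from their frame-0 positions. Each bead is tracked
#' from its frame-0 localization onward: a frame's match is the nearest
#' localization within `search_radius` of the previously tracked position,
#' so tracks follow cumulative drift of any magnitude provided per-frame
#' steps stay inside the radius. The raw per-frame estimate is smoothed by a
#' centered
#' moving average of `smooth_window` frames (shrinking at the edges) and
#' linearly interpolated across frames with no matched fiducial. Matched
#' fiducial rows are removed from the output table.
#'
#' @param table a localization table.
#' @param fiducial_refs `k x 2` matrix of approximate bead positions (nm);
#'   the matched frame-0 localization becomes each bead's anchor.
#' @param search_radius matching radius (nm).
#' @param smooth_window moving-average window (frames).
#' @param n_frames optional total frame count for the trajectory length;
#'   defaults to `max(frame) + 1`.
#' @return A list: `table` (drift-corrected, fiducials removed),
#'   `trajectory` (data.frame `frame, dx, dy`) and `coverage` (fraction of
#'   frames with at least one matched fiducial). Coverage below 80% warns.
#' @export
correct_drift <- function(table, fiducial_refs, search_radius = 500,
                          smooth_window = 100L, n_frames = NULL) {
  validate_localizations(table)
  fiducial_refs <- matrix(fiducial_refs, ncol = 2L)
  if (nrow(fiducial_refs) < 1L)
    stop("at least one fiducial reference is required", call. = FALSE)
  if (is.null(n_frames)) n_frames <- max(table$frame) + 1L
  n_frames <- as.integer(n_frames)

  frame_rows <- vector("list", n_frames)
  present <- split(seq_len(nrow(table)), table$frame)
  frame_rows[as.integer(names(present)) + 1L] <- present

  # track each bead from its frame-0 localization; every frame is matched
  # against the previously tracked position, so the track follows drift of
  # any magnitude as long as per-frame steps stay within the search radius
  disp_x <- matrix(NA_real_, n_frames, nrow(fiducial_refs))
  disp_y <- matrix(NA_real_, n_frames, nrow(fiducial_refs))
  matched_rows <- logical(nrow(table))
  r2 <- search_radius^2
  for (r in seq_len(nrow(fiducial_refs))) {
    target <- fiducial_refs[r, ]
    anchor <- NULL
    for (f in seq_len(n_frames)) {
      rows <- frame_rows[[f]]
      if (is.null(rows)) next
      d2 <- (table$x[rows] - target[1L])^2 + (table$y[rows] - target[2L])^2
      j <- which.min(d2)
      if (d2[j] > r2) next
      hit <- rows[j]
      pos <- c(table$x[hit], table$y[hit])
      if (is.null(anchor)) {
        if (f > 1L) break  # bead never seen in frame 0: leave track empty
        anchor <- pos
      }
      matched_rows[hit] <- TRUE
      disp_x[f, r] <- pos[1L] - anchor[1L]
      disp_y[f, r] <- pos[2L] - anchor[2L]
      target <- pos
    }
  }
  if (all(is.na(disp_x[1L, ])))
    stop("no fiducial matched in frame 0; cannot anchor drift correction",
         call. = FALSE)
  raw_dx <- rowMeans(disp_x, na.rm = TRUE)
  raw_dy <- rowMeans(disp_y, na.rm = TRUE)
  coverage <- mean(!is.nan(raw_dx))
  if (coverage < 0.8)
    warning(sprintf("fiducials localized in only %.0f%% of frames; drift %s",
                    100 * coverage, "interpolated across gaps"),
            call. = FALSE)
  fill <- function(v) {
    bad <- !is.finite(v)
    if (any(bad))
      v <- approx(which(!bad), v[!bad], xout = seq_along(v), rule = 2)$y
    v
  }
  smooth <- function(v) {
    h <- max(0L, as.integer(smooth_window) %/% 2L)
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  dx <- smooth(fill(raw_dx))
  dy <- smooth(fill(raw_dy))
  # frame 0 is the reference frame: trajectory(0) = (0, 0)
  dx <- dx - dx[1L]
  dy <- dy - dy[1L]

  out <- table[!matched_rows, , drop = FALSE]
  if (nrow(out)) {
    out$x <- out$x - dx[out$frame + 1L]
    out$y <- out$y - dy[out$frame + 1L]
  }
  rownames(out) <- NULL
  list(table = out,
       trajectory = data.frame(frame = 0:(n_frames - 1L), dx = dx, dy = dy),
       coverage = coverage)
}
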