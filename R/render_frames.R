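# Forward model: turn switching events into raw camera frames with an
# astigmatic PSF, EMCCD-like noise and stage drift.

#' Camera noise model
#'
#' Counts are `gain * photons` plus a constant `offset`, with Poisson shot
#' noise on the signal and additive Gaussian read noise.
#'
#' @param offset baseline counts added to every pixel.
#' @param read_noise Gaussian read noise standard deviation, counts.
#' @param gain counts per detected photon.
#' @param shot_noise logical; disable for noiseless ground-truth rendering.
#' @export
camera_model <- function(offset = 100, read_noise = 2, gain = 1,
                         shot_noise = TRUE) {
  if (gain <= 0) stop("camera gain must be > 0")
  if (read_noise < 0) stop("read noise must be >= 0")
  if (offset < 0) stop("camera offset must be >= 0")
  structure(list(offset = offset, read_noise = read_noise, gain = gain,
                 shot_noise = shot_noise), class = "camera_model")
}

#' Frame stack geometry
#'
#' @param width_px,height_px frame size in pixels.
#' @param pixel_nm camera pixel size, nm. The center of pixel (1,1) sits at
#'   (0.5, 0.5) pixels = (`pixel_nm/2`, `pixel_nm/2`) nm from the FOV corner.
#' @param n_frames movie length.
#' @param focal_z nominal axial position of the focal plane, nm.
#' @param origin_nm (x, y) of the FOV corner in global coordinates, nm.
#' @param fov_id,pass_id identifiers carried into localization tables.
#' @export
stack_geometry <- function(width_px = 64, height_px = 64, pixel_nm = 160,
                           n_frames = 1000, focal_z = 0, origin_nm = c(0, 0),
                           fov_id = 1L, pass_id = 1L) {
  stopifnot_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_nm = pixel_nm, n_frames = as.integer(n_frames),
                 focal_z = focal_z, origin_nm = origin_nm,
                 fov_id = fov_id, pass_id = pass_id),
            class = "stack_geometry")
}

# wx/wy sigma (nm) of the PSF at axial offset zrel from the focal plane.
# `psf` is a storm_calibration, a single sigma, or c(wx, wy).
psf_widths <- function(psf, zrel) {
  if (inherits(psf, "storm_calibration")) {
    z <- pmin(pmax(zrel, psf$z_range[1]), psf$z_range[2])
    calibration_eval(psf, z)
  } else if (is.numeric(psf)) {
    if (length(psf) == 1) psf <- c(psf, psf)
    list(wx = rep(psf[1], length(zrel)), wy = rep(psf[2], length(zrel)))
  } else stop("psf must be a storm_calibration or numeric sigma(s)")
}

psf_detect_range <- function(psf) {
  if (inherits(psf, "storm_calibration")) psf$z_range else c(-Inf, Inf)
}

# Add one pixel-integrated elliptical Gaussian spot (total = photons) to `img`.
# x0/y0 in nm from FOV corner, sx/sy sigma in nm, `a` pixel size in nm.
add_spot <- function(img, x0, y0, sx, sy, photons, a) {
  W <- ncol(img); H <- nrow(img)
  cx <- x0 / a; cy <- y0 / a           # position in pixel units
  rx <- ceiling(4 * sx / a); ry <- ceiling(4 * sy / a)
  c0 <- max(1L, floor(cx - rx)); c1 <- min(W, ceiling(cx + rx + 1))
  r0 <- max(1L, floor(cy - ry)); r1 <- min(H, ceiling(cy + ry + 1))
  if (c0 > c1 || r0 > r1) return(img)
  xs <- (c0 - 1):(c1 - 1)              # pixel left edges, px units
  ys <- (r0 - 1):(r1 - 1)
  fx <- stats::pnorm((xs + 1 - cx) * a, sd = sx) -
        stats::pnorm((xs - cx) * a, sd = sx)
  fy <- stats::pnorm((ys + 1 - cy) * a, sd = sy) -
        stats::pnorm((ys - cy) * a, sd = sy)
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + photons * (fy %o% fx)
  img
}

#' Render switching events into raw camera frames
#'
#' Each event adds a pixel-integrated elliptical Gaussian spot at its emitter's
#' (drifted) position, with widths given by the PSF model evaluated at the
#' emitter's axial offset from the focal plane. Events outside the detectable
#' z-range of the PSF (the calibration's valid range, nominally +/- 400 nm)
#' are silently dropped. Camera noise follows [camera_model()].
#'
#' @param events event data.frame from [schedule_blinking()].
#' @param emitters matching emitter data.frame (true positions).
#' @param psf a `storm_calibration`, or numeric sigma(s) in nm for a
#'   z-independent PSF.
#' @param camera a [camera_model()].
#' @param geometry a [stack_geometry()].
#' @param drift optional [drift_trace()] displacing spot centers per frame, or
#'   a function `f(frame) -> c(dx, dy)` nm.
#' @param schedule optional [activation_schedule()] recorded in the stack.
#' @param frame_range optional `c(first, last)`: render only this absolute
#'   frame window (for chunked processing of long movies).
#' @param seed RNG seed for the noise.
#' @return A `frame_stack`: list with `frames` (H x W x T array), `pixel_nm`,
#'   `focal_z`, `frame_offset`, `fov_id`, `pass_id`, `schedule`.
#' @export
render_frames <- function(events, emitters, psf, camera = camera_model(),
                          geometry = stack_geometry(), drift = NULL,
                          schedule = NULL, frame_range = NULL, seed = NULL) {
  stopifnot(inherits(camera, "camera_model"),
            inherits(geometry, "stack_geometry"))
  if (is.null(frame_range)) frame_range <- c(1L, geometry$n_frames)
  f0 <- frame_range[1]; f1 <- frame_range[2]
  n_t <- f1 - f0 + 1L
  H <- geometry$height_px; W <- geometry$width_px; a <- geometry$pixel_nm

  ev <- events[events$frame >= f0 & events$frame <= f1, , drop = FALSE]
  if (nrow(ev)) {
    m <- match(ev$emitter_id, emitters$emitter_id)
    ev$x_nm <- emitters$x_nm[m] - geometry$origin_nm[1]
    ev$y_nm <- emitters$y_nm[m] - geometry$origin_nm[2]
    ev$zrel <- emitters$z_nm[m] - geometry$focal_z
    dr <- psf_detect_range(psf)
    ev <- ev[ev$zrel >= dr[1] & ev$zrel <= dr[2], , drop = FALSE]
  }
  dxy <- NULL
  if (!is.null(drift)) {
    frames_abs <- f0:f1
    dxy <- if (is.function(drift)) {
      t(vapply(frames_abs, drift, numeric(2)))
    } else drift_offsets_at(drift, frames_abs)
  }

  frames <- array(0, dim = c(H, W, n_t))
  if (nrow(ev)) {
    w <- psf_widths(psf, ev$zrel)
    for (i in seq_len(nrow(ev))) {
      ti <- ev$frame[i] - f0 + 1L
      x0 <- ev$x_nm[i]; y0 <- ev$y_nm[i]
      if (!is.null(dxy)) { x0 <- x0 + dxy[ti, 1]; y0 <- y0 + dxy[ti, 2] }
      frames[, , ti] <- add_spot(frames[, , ti], x0, y0, w$wx[i], w$wy[i],
                                 ev$photons[i], a)
    }
  }
  with_seed(seed, {
    if (camera$shot_noise) {
      lam <- camera$gain * frames + camera$offset
      frames <- array(stats::rpois(length(lam), lam), dim = dim(frames))
    } else {
      frames <- camera$gain * frames + camera$offset
    }
    if (camera$read_noise > 0)
      frames <- frames + array(stats::rnorm(length(frames),
                                            sd = camera$read_noise),
                               dim = dim(frames))
  })
  structure(list(frames = frames, pixel_nm = a, focal_z = geometry$focal_z,
                 frame_offset = f0 - 1L, n_frames_total = geometry$n_frames,
                 origin_nm = geometry$origin_nm,
                 fov_id = geometry$fov_id, pass_id = geometry$pass_id,
                 schedule = schedule),
            class = "frame_stack")
}

#' Write / read a frame stack as multi-page TIFF plus a YAML manifest
#'
#' Counts are stored as 16-bit TIFF pages; the manifest records pixel size,
#' focal plane, frame offset, schedule and the seed used to generate the data.
#'
#' @param stack a `frame_stack`.
#' @param path TIFF path; the manifest is written next to it as `<path>.yaml`.
#' @param seed optional seed recorded in the manifest.
#' @export
write_frame_stack <- function(stack, path, seed = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(t)
    round(pmin(pmax(stack$frames[, , t], 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  man <- list(pixel_nm = stack$pixel_nm, focal_z = stack$focal_z,
              frame_offset = stack$frame_offset,
              n_frames = dim(stack$frames)[3],
              origin_nm = as.numeric(stack$origin_nm),
              fov_id = stack$fov_id, pass_id = stack$pass_id,
              scale = 65535,
              cycle = if (!is.null(stack$schedule)) stack$schedule$cycle,
              frame_rate = if (!is.null(stack$schedule))
                stack$schedule$frame_rate,
              seed = seed)
  yaml::write_yaml(man, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  man <- yaml::read_yaml(paste0(path, ".yaml"))
  sc <- if (!is.null(man$scale)) man$scale else 65535
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * sc
  schedule <- if (!is.null(man$cycle))
    activation_schedule(man$cycle, man$frame_rate)
  structure(list(frames = frames, pixel_nm = man$pixel_nm,
                 focal_z = man$focal_z, frame_offset = man$frame_offset,
                 n_frames_total = man$n_frames + man$frame_offset,
                 origin_nm = if (!is.null(man$origin_nm)) man$origin_nm
                 else c(0, 0),
                 fov_id = man$fov_id, pass_id = man$pass_id,
                 schedule = schedule),
            class = "frame_stack")
}
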