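# Frame-to-localization pipeline: band-pass filtering, peak finding,
# 2D / elliptical-3D Gaussian fitting and z assignment.

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate (edge-clamp) padding.
gauss_blur <- function(img, sigma) {
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ridx <- pmin(pmax(seq_len(H + 2L * r) - r, 1L), H)
  cidx <- pmin(pmax(seq_len(W + 2L * r) - r, 1L), W)
  P <- img[ridx, , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * P[i:(i + H - 1L), , drop = FALSE]
  P <- out[, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * P[, i:(i + W - 1L), drop = FALSE]
  out
}

#' Band-pass filter a raw frame
#'
#' Difference-of-Gaussians: a small-scale smoothing (suppressing pixel noise)
#' minus a large-scale blur (estimating the diffuse background), so that a
#' featureless frame maps to approximately zero everywhere.
#'
#' @param img 2D non-negative numeric matrix.
#' @param scales length-2, strictly increasing Gaussian sigmas in pixels.
#' @return filtered matrix of the same size.
#' @export
filter_frame <- function(img, scales = c(1, 5)) {
  if (length(scales) != 2 || !(scales[1] < scales[2]) || any(scales <= 0))
    stop("scales must be two strictly increasing positive sigmas")
  if (any(img < 0)) stop("image must be non-negative")
  gauss_blur(img, scales[1]) - gauss_blur(img, scales[2])
}

#' Find candidate peaks in a filtered frame
#'
#' Strict local maxima over the 8-neighborhood that exceed `threshold`.
#' Candidates closer than `merge_dist` (Chebyshev metric, pixels) are merged
#' into the brighter one.
#'
#' @param img filtered image.
#' @param threshold positive intensity threshold.
#' @param merge_dist merge radius in pixels.
#' @return data.frame with columns `row`, `col`, `value`.
#' @export
find_peaks <- function(img, threshold, merge_dist = 2) {
  m <- find_peaks_mat(img, threshold, merge_dist)
  data.frame(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
             value = m[, 3])
}

# Matrix-returning core of find_peaks (columns row, col, value), used on the
# per-frame hot path.
find_peaks_mat <- function(img, threshold, merge_dist = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  H <- nrow(img); W <- ncol(img)
  P <- matrix(-Inf, H + 2L, W + 2L)
  P[2:(H + 1L), 2:(W + 1L)] <- img
  ctr <- P[2:(H + 1L), 2:(W + 1L)]
  is_max <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr > P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)])
    if (!any(is_max)) break
  }
  idx <- which(is_max, arr.ind = TRUE, useNames = FALSE)
  if (!nrow(idx))
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("row", "col", "value"))))
  out <- cbind(row = idx[, 1], col = idx[, 2], value = img[idx])
  if (merge_dist > 0 && nrow(out) > 1) {
    out <- out[order(-out[, 3]), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out) - 1)) {
      if (!keep[i]) next
      j <- (i + 1):nrow(out)
      close <- pmax(abs(out[j, 1] - out[i, 1]),
                    abs(out[j, 2] - out[i, 2])) < merge_dist
      keep[j][close] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Pixel-integrated Gaussian factors along one axis for an ROI of n pixels.
# mu in pixel units from the ROI corner; pixel i spans [i-1, i].
pixint <- function(n, mu, sigma) {
  e <- stats::pnorm((0:n - mu) / sigma)
  diff(e)
}

roi_model <- function(n, par, elliptical) {
  if (elliptical)
    par[["N"]] * (pixint(n, par[["y0"]], par[["sy"]]) %o%
                  pixint(n, par[["x0"]], par[["sx"]])) + par[["b"]]
  else
    par[["N"]] * (pixint(n, par[["y0"]], par[["s"]]) %o%
                  pixint(n, par[["x0"]], par[["s"]])) + par[["b"]]
}

fit_roi <- function(roi, elliptical, sigma0 = 1.2) {
  n <- nrow(roi)
  med <- stats::median(roi)
  noise <- stats::mad(roi)
  peak <- max(roi) - med
  if (peak <= 0 || (noise > 0 && peak < 5 * noise))
    return(list(ok = FALSE, reason = "flat"))
  w <- pmax(roi - med, 0)
  tot <- sum(w)
  xs <- (seq_len(n) - 0.5)
  x0 <- sum(w %*% cbind(xs)) / tot   # column weights
  y0 <- sum(xs * rowSums(w)) / tot
  start <- if (elliptical)
    c(x0 = x0, y0 = y0, sx = sigma0, sy = sigma0, N = tot, b = med)
  else
    c(x0 = x0, y0 = y0, s = sigma0, N = tot, b = med)
  lower <- if (elliptical) c(0, 0, 0.2, 0.2, 1e-6, -Inf)
           else c(0, 0, 0.2, 1e-6, -Inf)
  upper <- if (elliptical) c(n, n, n, n, Inf, Inf) else c(n, n, n, Inf, Inf)
  fit <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p) as.vector(roi_model(n, as.list(p), elliptical) - roi),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info < 1 || fit$info > 4)
    return(list(ok = FALSE, reason = "nonconv"))
  p <- as.list(fit$par)
  if (p$N <= 0 || p$x0 <= 0.5 || p$x0 >= n - 0.5 || p$y0 <= 0.5 ||
      p$y0 >= n - 0.5)
    return(list(ok = FALSE, reason = "nonconv"))
  rss <- sum(fit$fvec^2)
  c(list(ok = TRUE, reason = "ok",
         residual = sqrt(rss / length(roi))), p)
}

#' Fit a symmetric 2D Gaussian to a candidate ROI
#'
#' Least-squares fit of a pixel-integrated symmetric Gaussian plus constant
#' background. Positions are reported in nm using the pixel size; `photons`
#' is the fitted integrated signal.
#'
#' @param roi square numeric matrix centered on the candidate.
#' @param pixel_nm camera pixel size, nm.
#' @param sigma0 initial width guess, pixels.
#' @return list with `ok`, and on success `x_nm`, `y_nm` (relative to the ROI
#'   corner), `photons`, `width_nm`, `residual`; on failure `reason`
#'   (`"flat"` or `"nonconv"`).
#' @export
fit_peak_2d <- function(roi, pixel_nm = 160, sigma0 = 1.2) {
  f <- fit_roi(roi, elliptical = FALSE, sigma0 = sigma0)
  if (!f$ok) return(f)
  list(ok = TRUE, x_nm = f$x0 * pixel_nm, y_nm = f$y0 * pixel_nm,
       photons = f$N, width_nm = f$s * pixel_nm, residual = f$residual)
}

#' Fit an elliptical Gaussian to a candidate ROI
#'
#' As [fit_peak_2d()] but with independent x and y widths (axes aligned with
#' the camera axes), the fit used for astigmatic 3D localization.
#'
#' @inheritParams fit_peak_2d
#' @return list with `ok`, `x_nm`, `y_nm`, `photons`, `wx_nm`, `wy_nm`,
#'   `residual`, or `reason` on failure.
#' @export
fit_peak_3d <- function(roi, pixel_nm = 160, sigma0 = 1.2) {
  f <- fit_roi(roi, elliptical = TRUE, sigma0 = sigma0)
  if (!f$ok) return(f)
  list(ok = TRUE, x_nm = f$x0 * pixel_nm, y_nm = f$y0 * pixel_nm,
       photons = f$N, wx_nm = f$sx * pixel_nm, wy_nm = f$sy * pixel_nm,
       residual = f$residual)
}

#' Assign an axial position from fitted elliptical widths
#'
#' Finds the z in the calibration's valid range whose calibration widths are
#' nearest to the measured widths in (sqrt(wx), sqrt(wy)) space, the
#' conventional distance measure for astigmatic z lookup. Localizations whose
#' minimal distance exceeds `gate` are rejected as off-curve.
#'
#' @param wx,wy fitted widths (sigma, nm); vectors are accepted.
#' @param cal a `storm_calibration`.
#' @param gate rejection distance in sqrt-nm units.
#' @param z_step lookup grid pitch, nm (refined by parabolic interpolation).
#' @return data.frame with columns `z_nm` (relative to the focal plane),
#'   `dist`, `ok`.
#' @export
assign_z <- function(wx, wy, cal, gate = 1.5, z_step = 1) {
  stopifnot(inherits(cal, "storm_calibration"))
  if (any(wx <= 0) || any(wy <= 0)) stop("widths must be positive")
  zg <- seq(cal$z_range[1], cal$z_range[2], by = z_step)
  w <- calibration_eval(cal, zg)
  sx <- sqrt(w$wx); sy <- sqrt(w$wy)
  n <- length(wx)
  z <- numeric(n); d <- numeric(n)
  rx <- sqrt(wx); ry <- sqrt(wy)
  for (i in seq_len(n)) {
    d2 <- (sx - rx[i])^2 + (sy - ry[i])^2
    j <- which.min(d2)
    off <- if (j > 1 && j < length(zg))
      parabolic_offset(d2[j - 1], d2[j], d2[j + 1]) else 0
    z[i] <- zg[j] + off * z_step
    d[i] <- sqrt(d2[j])
  }
  data.frame(z_nm = z, dist = d, ok = d <= gate)
}

#' Localization parameters
#'
#' @param filter_scales difference-of-Gaussians sigmas, pixels.
#' @param threshold_k detection threshold in units of the robust (MAD) standard
#'   deviation of the filtered frame.
#' @param fit_window square fit ROI side, pixels (odd).
#' @param merge_dist peak merge radius, pixels.
#' @param sigma0 initial fit width, pixels.
#' @param z_gate off-curve rejection distance for [assign_z()], sqrt-nm.
#' @param width_gate widths outside `[width_gate[1] * min, width_gate[2] * max]`
#'   of the calibration width range are rejected (ellipticity gate).
#' @export
localize_params <- function(filter_scales = c(1, 5), threshold_k = 5,
                            fit_window = 7, merge_dist = 2, sigma0 = 1.2,
                            z_gate = 1.5, width_gate = c(0.3, 3)) {
  structure(list(filter_scales = filter_scales, threshold_k = threshold_k,
                 fit_window = as.integer(fit_window), merge_dist = merge_dist,
                 sigma0 = sigma0, z_gate = z_gate, width_gate = width_gate),
            class = "localize_params")
}

# Fit all candidate spots in one frame; shared by localize_movie and
# calibrate_from_stack. Returns a matrix with columns x_nm, y_nm, photons,
# wx_nm, wy_nm, residual plus rejection counts as an attribute.
fit_frame_spots <- function(img, pixel_nm, params, elliptical) {
  rej <- c(border = 0L, overlap = 0L, flat = 0L, nonconv = 0L)
  empty <- matrix(numeric(0), 0, 6, dimnames = list(
    NULL, c("x_nm", "y_nm", "photons", "wx_nm", "wy_nm", "residual")))
  filt <- filter_frame(img, params$filter_scales)
  sig <- stats::mad(filt)
  if (sig <= 0) sig <- stats::sd(filt)
  if (!is.finite(sig) || sig <= 0)
    return(structure(empty, rejections = rej))
  pk <- find_peaks_mat(filt, params$threshold_k * sig, params$merge_dist)
  if (!nrow(pk)) return(structure(empty, rejections = rej))
  w <- params$fit_window
  h <- w %/% 2L
  inb <- pk[, 1] - h >= 1 & pk[, 1] + h <= nrow(img) &
         pk[, 2] - h >= 1 & pk[, 2] + h <= ncol(img)
  rej["border"] <- sum(!inb)
  pk <- pk[inb, , drop = FALSE]
  if (nrow(pk) > 1) {    # activations with overlapping ROIs: drop both
    ov <- rep(FALSE, nrow(pk))
    for (i in seq_len(nrow(pk) - 1)) {
      j <- (i + 1):nrow(pk)
      hit <- pmax(abs(pk[j, 1] - pk[i, 1]), abs(pk[j, 2] - pk[i, 2])) < w
      if (any(hit)) { ov[i] <- TRUE; ov[j][hit] <- TRUE }
    }
    rej["overlap"] <- sum(ov)
    pk <- pk[!ov, , drop = FALSE]
  }
  out <- matrix(NA_real_, nrow(pk), 6, dimnames = dimnames(empty))
  for (i in seq_len(nrow(pk))) {
    r <- pk[i, 1]; cc <- pk[i, 2]
    roi <- img[(r - h):(r + h), (cc - h):(cc + h)]
    f <- if (elliptical) fit_peak_3d(roi, pixel_nm, params$sigma0)
         else fit_peak_2d(roi, pixel_nm, params$sigma0)
    if (!f$ok) { rej[f$reason] <- rej[f$reason] + 1L; next }
    out[i, ] <- c((cc - 1L - h) * pixel_nm + f$x_nm,
                  (r - 1L - h) * pixel_nm + f$y_nm,
                  f$photons,
                  if (elliptical) f$wx_nm else f$width_nm,
                  if (elliptical) f$wy_nm else f$width_nm,
                  f$residual)
  }
  out <- out[!is.na(out[, 1]), , drop = FALSE]
  structure(out, rejections = rej)
}

#' Localize all frames of a movie
#'
#' Per frame: band-pass filter, threshold at `threshold_k` robust sigma,
#' detect local maxima, drop candidates at the border or with overlapping fit
#' windows (both members of an overlapping pair are discarded), least-squares
#' fit, and - in 3D mode - width-gate and z-assign against the calibration.
#' Every rejected candidate is counted by reason in the table's
#' `"rejections"` attribute.
#'
#' @param stack a `frame_stack` (see [render_frames()] / [read_frame_stack()]).
#' @param cal a `storm_calibration`; required in 3D mode.
#' @param params a [localize_params()].
#' @param mode `"2d"` or `"3d"`.
#' @return A localization table: data.frame with columns `frame`, `x_nm`,
#'   `y_nm`, `z_nm` (NA in 2D mode; absolute, i.e. relative focal offset plus
#'   the stack's focal plane, in 3D), `photons`, `wx_nm`, `wy_nm`, `residual`,
#'   `channel`, `fov_id`, `pass_id`. Coordinates are continuous nm with origin
#'   at the FOV corner (pixel (1,1) center at 0.5 px). Metadata (`pixel_nm`,
#'   `n_frames`, `schedule`, `focal_z`, `origin_nm`, `rejections`) is attached
#'   as attributes.
#' @export
localize_movie <- function(stack, cal = NULL, params = localize_params(),
                           mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "frame_stack"))
  if (mode == "3d" && !inherits(cal, "storm_calibration"))
    stop("3D mode requires a calibration curve")
  elliptical <- mode == "3d"
  n_t <- dim(stack$frames)[3]
  rej_tot <- c(border = 0L, overlap = 0L, flat = 0L, nonconv = 0L,
               ellipticity = 0L, off_curve = 0L)
  per_frame <- vector("list", n_t)
  wrange <- if (elliptical) {
    w <- calibration_eval(cal, seq(cal$z_range[1], cal$z_range[2],
                                   length.out = 201))
    range(c(w$wx, w$wy))
  }
  for (t in seq_len(n_t)) {
    fits <- fit_frame_spots(stack$frames[, , t], stack$pixel_nm, params,
                            elliptical)
    rj <- attr(fits, "rejections")
    rej_tot[names(rj)] <- rej_tot[names(rj)] + rj
    if (!nrow(fits)) next
    if (elliptical) {
      okw <- fits[, "wx_nm"] >= params$width_gate[1] * wrange[1] &
             fits[, "wx_nm"] <= params$width_gate[2] * wrange[2] &
             fits[, "wy_nm"] >= params$width_gate[1] * wrange[1] &
             fits[, "wy_nm"] <= params$width_gate[2] * wrange[2]
      rej_tot["ellipticity"] <- rej_tot["ellipticity"] + sum(!okw)
      fits <- fits[okw, , drop = FALSE]
    }
    if (!nrow(fits)) next
    per_frame[[t]] <- cbind(fits, frame = t + stack$frame_offset)
  }
  per_frame <- per_frame[!vapply(per_frame, is.null, logical(1))]
  m <- if (length(per_frame)) do.call(rbind, per_frame) else
    matrix(numeric(0), 0, 7, dimnames = list(
      NULL, c("x_nm", "y_nm", "photons", "wx_nm", "wy_nm", "residual",
              "frame")))
  tab <- data.frame(x_nm = m[, "x_nm"], y_nm = m[, "y_nm"],
                    photons = m[, "photons"], wx_nm = m[, "wx_nm"],
                    wy_nm = m[, "wy_nm"], residual = m[, "residual"],
                    frame = as.integer(m[, "frame"]))
  if (elliptical && nrow(tab)) {
    za <- assign_z(tab$wx_nm, tab$wy_nm, cal, gate = params$z_gate)
    rej_tot["off_curve"] <- sum(!za$ok)
    tab$z_nm <- za$z_nm + stack$focal_z
    tab <- tab[za$ok, , drop = FALSE]
  } else {
    tab$z_nm <- rep(NA_real_, nrow(tab))
  }
  tab$channel <- rep("unassigned", nrow(tab))
  tab$fov_id <- rep(stack$fov_id, nrow(tab))
  tab$pass_id <- rep(stack$pass_id, nrow(tab))
  tab <- tab[, c("frame", "x_nm", "y_nm", "z_nm", "photons", "wx_nm", "wy_nm",
                 "residual", "channel", "fov_id", "pass_id")]
  rownames(tab) <- NULL
  attr(tab, "pixel_nm") <- stack$pixel_nm
  attr(tab, "n_frames") <- stack$n_frames_total
  attr(tab, "schedule") <- stack$schedule
  attr(tab, "focal_z") <- stack$focal_z
  attr(tab, "origin_nm") <- stack$origin_nm
  attr(tab, "rejections") <- rej_tot
  tab
}
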