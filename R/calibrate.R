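# Astigmatism z-calibration: parameterize the x/y widths of the PSF as a
# function of axial position and invert them to look up z.

defocus_width <- function(z, par) {
  u <- (z - par[["c"]]) / par[["d"]]
  par[["w0"]] * sqrt(pmax(1 + u^2 + par[["A"]] * u^3 + par[["B"]] * u^4, 1e-12))
}

#' Construct an astigmatic calibration curve from known coefficients
#'
#' The widths along each camera axis follow the standard astigmatic defocusing
#' curve \deqn{w(z) = w_0 \sqrt{1 + u^2 + A u^3 + B u^4}, \quad u = (z - c)/d,}
#' where `c` is the focal offset of that axis (the cylindrical lens focuses the
#' x and y axes at different depths) and `d` is the depth of focus. Widths are
#' Gaussian standard deviations in nanometres; `z` is the axial offset from the
#' nominal focal plane in nanometres.
#'
#' @param wx,wy named numeric vectors with elements `w0`, `c`, `d`, `A`, `B`
#'   describing each axis.
#' @param z_range length-2 numeric, valid z interval in nm.
#' @return An object of class `storm_calibration`.
#' @export
astig_calibration <- function(wx = c(w0 = 150, c = 250, d = 400, A = 0, B = 0),
                              wy = c(w0 = 150, c = -250, d = 400, A = 0, B = 0),
                              z_range = c(-400, 400)) {
  req <- c("w0", "c", "d", "A", "B")
  if (!all(req %in% names(wx)) || !all(req %in% names(wy)))
    stop("`wx` and `wy` need elements w0, c, d, A, B")
  cal <- structure(list(method = "poly", wx = wx[req], wy = wy[req],
                        z_range = sort(as.numeric(z_range))),
                   class = "storm_calibration")
  cal$z0 <- calibration_crossing(cal)
  cal
}

calibration_eval <- function(cal, z) {
  if (cal$method == "poly") {
    list(wx = defocus_width(z, as.list(cal$wx)),
         wy = defocus_width(z, as.list(cal$wy)))
  } else {
    list(wx = stats::predict(cal$wx, z)$y, wy = stats::predict(cal$wy, z)$y)
  }
}

calibration_crossing <- function(cal) {
  zg <- seq(cal$z_range[1], cal$z_range[2], length.out = 1601)
  w <- calibration_eval(cal, zg)
  dif <- w$wx - w$wy
  s <- which(diff(sign(dif)) != 0)
  if (!length(s)) return(NA_real_)
  i <- s[1]
  # linear interpolation of the sign change
  zg[i] + (zg[i + 1] - zg[i]) * abs(dif[i]) / (abs(dif[i]) + abs(dif[i + 1]))
}

#' Fit a z-calibration curve to width measurements
#'
#' Fits the astigmatic defocusing polynomial (see [astig_calibration()]) to
#' measured x and y PSF widths sampled at known axial positions, as obtained by
#' stepping isolated point emitters through the focus with a nanopositioner.
#' The signed width difference `wx(z) - wy(z)` must be strictly monotonic over
#' the sampled range, otherwise the curve cannot be inverted to assign z and an
#' error is raised.
#'
#' @param width_samples data.frame with columns `z_nm`, `wx_nm`, `wy_nm`
#'   (widths are Gaussian sigmas in nm).
#' @param method `"poly"` for the defocusing polynomial (default) or
#'   `"spline"` for a smoothing-spline parameterization.
#' @return A `storm_calibration` whose valid range is the sampled z interval.
#' @export
build_calibration <- function(width_samples, method = c("poly", "spline")) {
  method <- match.arg(method)
  df <- as.data.frame(width_samples)
  if (!all(c("z_nm", "wx_nm", "wy_nm") %in% names(df)))
    stop("width_samples needs columns z_nm, wx_nm, wy_nm")
  df <- df[order(df$z_nm), ]
  z <- df$z_nm
  if (length(unique(z)) < 5 || diff(range(z)) <= 200)
    stop("need >= 5 distinct z samples spanning more than 200 nm")
  if (any(df$wx_nm <= 0) || any(df$wy_nm <= 0))
    stop("widths must be positive")

  fit_axis <- function(w) {
    if (method == "spline")
      return(stats::smooth.spline(z, w, df = min(length(unique(z)), 8)))
    start <- list(w0 = min(w), c = z[which.min(w)], d = diff(range(z)) / 2,
                  A = 0, B = 0)
    fit <- minpack.lm::nlsLM(
      w ~ w0 * sqrt(pmax(1 + ((z - c)/d)^2 + A * ((z - c)/d)^3 +
                           B * ((z - c)/d)^4, 1e-12)),
      start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    cf[c("w0", "c", "d", "A", "B")]
  }

  cal <- structure(list(method = method, wx = fit_axis(df$wx_nm),
                        wy = fit_axis(df$wy_nm), z_range = range(z)),
                   class = "storm_calibration")

  zg <- seq(cal$z_range[1], cal$z_range[2], length.out = 801)
  w <- calibration_eval(cal, zg)
  dif <- w$wx - w$wy
  dd <- diff(dif)
  if (all(abs(dif) < 1e-6) || !(all(dd > 0) || all(dd < 0)))
    stop("uninvertible calibration: wx(z) - wy(z) is not strictly monotonic ",
         "over the sampled range (no astigmatism?)")
  if (any(w$wx <= 0) || any(w$wy <= 0)) stop("fitted widths are not positive")
  cal$z0 <- calibration_crossing(cal)
  res <- calibration_eval(cal, z)
  cal$fit_rms <- sqrt(mean(c(res$wx - df$wx_nm, res$wy - df$wy_nm)^2))
  cal
}

#' Evaluate calibration widths at an axial position
#'
#' @param cal a `storm_calibration`.
#' @param z axial offset(s) from the focal plane, nm; must lie inside the
#'   calibration's valid range.
#' @return list with numeric vectors `wx`, `wy` (sigma, nm).
#' @export
widths_at <- function(cal, z) {
  stopifnot(inherits(cal, "storm_calibration"))
  if (any(z < cal$z_range[1] - 1e-9) || any(z > cal$z_range[2] + 1e-9))
    stop(sprintf("z outside calibration valid range [%g, %g] nm",
                 cal$z_range[1], cal$z_range[2]))
  calibration_eval(cal, z)
}

#' @export
print.storm_calibration <- function(x, ...) {
  cat(sprintf("storm_calibration (%s): valid z [%g, %g] nm, crossing z0 = %s nm\n",
              x$method, x$z_range[1], x$z_range[2],
              if (is.na(x$z0)) "none" else sprintf("%.1f", x$z0)))
  invisible(x)
}

#' Write / read a calibration as YAML
#'
#' Only polynomial calibrations are serializable; spline calibrations should be
#' refit from the stored width samples.
#' @param cal a `storm_calibration` with `method = "poly"`.
#' @param path file path.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "storm_calibration"))
  if (cal$method != "poly") stop("only polynomial calibrations are serialized")
  yaml::write_yaml(list(method = "poly", wx = as.list(cal$wx),
                        wy = as.list(cal$wy),
                        z_range = as.numeric(cal$z_range), z0 = cal$z0), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  astig_calibration(wx = unlist(y$wx), wy = unlist(y$wy),
                    z_range = as.numeric(y$z_range))
}

#' Build a calibration from a bead z-scan stack
#'
#' Localizes isolated spots in every plane of a z-scan of point emitters
#' (one plane per z step), averages the fitted elliptical widths per plane and
#' fits the calibration curve to the averages.
#'
#' @param stack 3D array (H x W x planes) of camera counts.
#' @param z_positions axial position of each plane, nm.
#' @param pixel_nm camera pixel size, nm.
#' @param params localization parameters, see [localize_params()].
#' @inheritParams build_calibration
#' @export
calibrate_from_stack <- function(stack, z_positions, pixel_nm,
                                 params = localize_params(),
                                 method = "poly") {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] == length(z_positions))
  rows <- lapply(seq_along(z_positions), function(k) {
    fits <- fit_frame_spots(stack[, , k], pixel_nm, params, elliptical = TRUE)
    if (!nrow(fits)) return(NULL)
    data.frame(z_nm = z_positions[k], wx_nm = mean(fits[, "wx_nm"]),
               wy_nm = mean(fits[, "wy_nm"]))
  })
  samples <- do.call(rbind, rows)
  if (is.null(samples) || nrow(samples) < 5)
    stop("too few usable calibration planes")
  build_calibration(samples, method = method)
}
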