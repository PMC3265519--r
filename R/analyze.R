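# Rendering, profile / FWHM measurement, and the label-density / Nyquist
# resolution calculus.
#
# The image resolution of STORM is set jointly by (i) the localization
# precision of single fluorophores and (ii) the finite label density: by the
# Nyquist sampling criterion a structure labeled at density `a` (labels per
# um^d) cannot be resolved better than twice the mean neighbor spacing,
#   alpha_Nyquist = 2 / a^(1/d),
# and the two independent error sources combine in quadrature,
#   resolution = sqrt(alpha_Nyquist^2 + precision^2).

#' Render a localization table as a STORM image
#'
#' Each localization contributes a unit-volume Gaussian (total intensity 1),
#' so image intensity counts localizations. With
#' `width_mode = "theoretical"` the kernel sigma is the first-order
#' localization uncertainty `psf_sigma / sqrt(photons)`; with
#' `width_mode = "fixed"` a constant `fixed_sigma` is used. In 3D mode the
#' table is split into z slices of `slice_nm` and each slice rendered as one
#' page.
#'
#' @param table localization table.
#' @param pitch pixel pitch, nm.
#' @param mode `"2d"` or `"3d"`.
#' @param width_mode `"theoretical"` or `"fixed"`.
#' @param psf_sigma PSF sigma used for the theoretical width, nm.
#' @param fixed_sigma kernel sigma for `width_mode = "fixed"`, nm.
#' @param slice_nm z slice thickness for 3D stacks, nm.
#' @param xlim,ylim,zlim optional axis limits, nm (defaults: data range padded
#'   by 3 kernel sigmas).
#' @return A `storm_image`: list with `data` (matrix, or H x W x slices
#'   array), `pitch`, `origin` (nm of the lower corner), `slice_nm`,
#'   `z0` (first slice's lower edge; 3D only).
#' @export
render_storm <- function(table, pitch = 10, mode = c("2d", "3d"),
                         width_mode = c("theoretical", "fixed"),
                         psf_sigma = 150, fixed_sigma = 20, slice_nm = 100,
                         xlim = NULL, ylim = NULL, zlim = NULL) {
  mode <- match.arg(mode)
  width_mode <- match.arg(width_mode)
  if (pitch <= 0) stop("pitch must be > 0")
  if (!nrow(table)) stop("cannot render an empty table")
  sig <- if (width_mode == "theoretical") psf_sigma / sqrt(table$photons)
         else rep(fixed_sigma, nrow(table))
  pad <- 4 * max(sig)          # keep kernel truncation below 0.5%
  if (is.null(xlim)) xlim <- range(table$x_nm) + c(-pad, pad)
  if (is.null(ylim)) ylim <- range(table$y_nm) + c(-pad, pad)
  W <- max(1L, ceiling((xlim[2] - xlim[1]) / pitch))
  H <- max(1L, ceiling((ylim[2] - ylim[1]) / pitch))
  render_slice <- function(idx) {
    img <- matrix(0, H, W)
    for (i in idx)
      img <- add_spot(img, table$x_nm[i] - xlim[1], table$y_nm[i] - ylim[1],
                      sig[i], sig[i], 1, pitch)
    img
  }
  if (mode == "2d") {
    out <- list(data = render_slice(seq_len(nrow(table))), pitch = pitch,
                origin = c(xlim[1], ylim[1]), slice_nm = NULL)
  } else {
    if (all(is.na(table$z_nm))) stop("3D rendering needs z coordinates")
    if (is.null(zlim)) zlim <- range(table$z_nm, na.rm = TRUE)
    edges <- seq(floor(zlim[1] / slice_nm) * slice_nm, zlim[2] + slice_nm,
                 by = slice_nm)
    sl <- findInterval(table$z_nm, edges, rightmost.closed = TRUE)
    arr <- array(0, dim = c(H, W, length(edges) - 1L))
    for (s in unique(sl[!is.na(sl) & sl >= 1]))
      arr[, , s] <- render_slice(which(sl == s))
    out <- list(data = arr, pitch = pitch, origin = c(xlim[1], ylim[1]),
                slice_nm = slice_nm, z0 = edges[1])
  }
  structure(out, class = "storm_image")
}

#' Write a rendered image as 16-bit TIFF
#'
#' @param img a `storm_image`.
#' @param path output path (multi-page for 3D stacks).
#' @param scale counts mapped to full scale (default: image maximum).
#' @export
write_storm_image <- function(img, path, scale = NULL) {
  stopifnot(inherits(img, "storm_image"))
  d <- img$data
  if (is.null(scale)) scale <- max(d, 1e-12)
  if (length(dim(d)) == 2) {
    tiff::writeTIFF(pmin(d / scale, 1), path, bits.per.sample = 16)
  } else {
    pages <- lapply(seq_len(dim(d)[3]), function(s) pmin(d[, , s] / scale, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  }
  invisible(path)
}

bilinear_at <- function(img, x, y) {
  # x, y in pixel units (0 at image edge); pixel centers at 0.5, 1.5, ...
  H <- nrow(img); W <- ncol(img)
  cx <- pmin(pmax(x - 0.5, 0), W - 1)
  cy <- pmin(pmax(y - 0.5, 0), H - 1)
  c0 <- pmin(floor(cx), W - 2); r0 <- pmin(floor(cy), H - 2)
  fx <- cx - c0; fy <- cy - r0
  i00 <- img[cbind(r0 + 1, c0 + 1)]; i01 <- img[cbind(r0 + 1, c0 + 2)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]; i11 <- img[cbind(r0 + 2, c0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Intensity profile along a line segment
#'
#' Samples the image along the segment (bilinear interpolation), averaging
#' across `width` nm perpendicular to it.
#'
#' @param img a `storm_image` (2D).
#' @param p0,p1 segment endpoints, nm (same frame as the table).
#' @param width averaging width perpendicular to the segment, nm.
#' @param step sampling step along the segment, nm (default: the pitch).
#' @return data.frame with `dist_nm`, `value`.
#' @export
line_profile <- function(img, p0, p1, width = 0, step = NULL) {
  stopifnot(inherits(img, "storm_image"), length(dim(img$data)) == 2)
  if (is.null(step)) step <- img$pitch
  v <- (p1 - p0)
  L <- sqrt(sum(v^2))
  if (L <= 0) stop("degenerate segment")
  u <- v / L
  nrm <- c(-u[2], u[1])
  dist <- seq(0, L, by = step)
  offs <- if (width > 0) seq(-width / 2, width / 2, by = step) else 0
  vals <- vapply(dist, function(s) {
    pts_x <- p0[1] + s * u[1] + offs * nrm[1] - img$origin[1]
    pts_y <- p0[2] + s * u[2] + offs * nrm[2] - img$origin[2]
    mean(bilinear_at(img$data, pts_x / img$pitch, pts_y / img$pitch))
  }, numeric(1))
  data.frame(dist_nm = dist, value = vals)
}

#' Full width at half maximum of a 1D profile
#'
#' Linear interpolation of the half-maximum crossings around the global
#' maximum. An all-zero (or flat) profile has no defined FWHM and is signaled
#' with a warning and `NA`.
#'
#' @param profile data.frame with `dist_nm`, `value` (see [line_profile()]).
#' @return FWHM in nm, or `NA` with a warning if undefined.
#' @export
profile_fwhm <- function(profile) {
  v <- profile$value
  d <- profile$dist_nm
  if (all(!is.finite(v)) || max(v) <= 0 || diff(range(v)) == 0) {
    warning("undefined FWHM: profile is flat or empty")
    return(NA_real_)
  }
  half <- max(v) / 2
  im <- which.max(v)
  left <- NA_real_; right <- NA_real_
  for (i in seq(im, 2)) if (v[i - 1] < half) {
    left <- d[i - 1] + (d[i] - d[i - 1]) * (half - v[i - 1]) / (v[i] - v[i - 1])
    break
  }
  for (i in seq(im, length(v) - 1)) if (v[i + 1] < half) {
    right <- d[i] + (d[i + 1] - d[i]) * (v[i] - half) / (v[i] - v[i + 1])
    break
  }
  if (is.na(left) || is.na(right)) {
    warning("undefined FWHM: half-maximum crossing outside the profile")
    return(NA_real_)
  }
  right - left
}

#' Theoretical localization precision of a Gaussian fit
#'
#' First-order localization uncertainty of a least-squares Gaussian fit with
#' pixelation and background terms:
#' \deqn{\sigma^2 = \frac{s^2 + a^2/12}{N} + \frac{8 \pi s^4 b}{a^2 N^2},}
#' where `s` is the PSF sigma, `a` the pixel size, `N` the photon count and
#' `b` the background variance per pixel. With `bg_var = 0` this reduces to
#' the photon-counting limit `s_eff / sqrt(N)` used for display widths.
#'
#' @param psf_sigma PSF sigma, nm.
#' @param photons detected photons.
#' @param pixel_nm camera pixel size, nm.
#' @param bg_var background variance per pixel, counts^2.
#' @return standard deviation of the position estimate, nm.
#' @export
theoretical_precision <- function(psf_sigma, photons, pixel_nm = 160,
                                  bg_var = 0) {
  s2 <- psf_sigma^2 + pixel_nm^2 / 12
  sqrt(s2 / photons +
         8 * pi * psf_sigma^4 * bg_var / (pixel_nm^2 * photons^2))
}

#' Localization precision from clusters of repeated localizations
#'
#' Repeated switching events of isolated single labels form small clusters.
#' Each cluster is recentred to its center of mass, the recentred positions
#' are pooled, and a Gaussian is fitted to the pooled distribution per axis;
#' the FWHM of that Gaussian is the localization precision.
#'
#' @param table localization table with a `cluster` column, or a list of
#'   per-cluster tables.
#' @param min_clusters,min_per_cluster minimal data for a reportable estimate.
#' @return list with `fwhm_x`, `fwhm_y`, `fwhm_z` (NA without z data),
#'   `n_clusters`, `n_localizations`.
#' @export
localization_precision <- function(table, min_clusters = 10,
                                   min_per_cluster = 5) {
  clusters <- if (is.data.frame(table)) {
    if (is.null(table$cluster)) stop("table needs a `cluster` column")
    split(table, table$cluster)
  } else table
  clusters <- Filter(function(cl) nrow(cl) >= min_per_cluster, clusters)
  if (length(clusters) < min_clusters)
    stop(sprintf("need >= %d clusters with >= %d localizations each",
                 min_clusters, min_per_cluster))
  recentre <- function(cl) {
    data.frame(x = cl$x_nm - mean(cl$x_nm), y = cl$y_nm - mean(cl$y_nm),
               z = if (!all(is.na(cl$z_nm))) cl$z_nm - mean(cl$z_nm)
                   else rep(NA_real_, nrow(cl)))
  }
  pooled <- do.call(rbind, lapply(clusters, recentre))
  # Least-squares Gaussian fit to the pooled histogram per axis (robust to
  # the occasional mis-fit localization far from any cluster)
  gauss_fwhm <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(NA_real_)
    s0 <- stats::mad(v)
    if (s0 == 0) return(sigma_to_fwhm(stats::sd(v)))
    h <- graphics::hist(v, breaks = "FD", plot = FALSE)
    x <- h$mids; y <- h$counts
    fit <- try(minpack.lm::nls.lm(
      par = c(A = max(y), mu = stats::median(v), s = s0),
      fn = function(p) p[["A"]] * exp(-(x - p[["mu"]])^2 /
                                        (2 * p[["s"]]^2)) - y,
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    s <- if (inherits(fit, "try-error") || fit$info < 1 || fit$info > 4) s0
         else abs(fit$par[["s"]])
    sigma_to_fwhm(s)
  }
  list(fwhm_x = gauss_fwhm(pooled$x), fwhm_y = gauss_fwhm(pooled$y),
       fwhm_z = gauss_fwhm(pooled$z), n_clusters = length(clusters),
       n_localizations = nrow(pooled))
}

#' Label density from localization counts
#'
#' Counts localizations inside each region, divides by the region's measure
#' and by the mean number of localizations per label `n` (each fluorophore
#' undergoes several switching cycles; `n = 4` by default), giving labels per
#' um^2 (d = 2; the data is projected, z ignored) or per um^3 (d = 3).
#'
#' @param table localization table.
#' @param regions data.frame with bounds `xmin`, `xmax`, `ymin`, `ymax`
#'   (nm; plus `zmin`, `zmax` for d = 3) and optionally `measure_um`, the
#'   region's area (um^2) or volume (um^3). Without `measure_um` the
#'   bounding-box measure is used - supply the membrane surface area when
#'   densities are defined per membrane area.
#' @param d dimension, 2 or 3.
#' @param n_locs_per_label divisor n (mean localizations per label).
#' @return list with `per_region` (densities), `mean`, `sd`, `n_regions`.
#' @export
label_density <- function(table, regions, d = 2, n_locs_per_label = 4) {
  if (!d %in% c(2, 3)) stop("d must be 2 or 3")
  regions <- as.data.frame(regions)
  if (!nrow(regions)) stop("empty region list")
  dens <- vapply(seq_len(nrow(regions)), function(r) {
    rg <- regions[r, ]
    sel <- table$x_nm >= rg$xmin & table$x_nm <= rg$xmax &
           table$y_nm >= rg$ymin & table$y_nm <= rg$ymax
    if (d == 3) {
      sel <- sel & !is.na(table$z_nm) & table$z_nm >= rg$zmin &
             table$z_nm <= rg$zmax
    }
    measure <- if (!is.null(rg$measure_um) && is.finite(rg$measure_um))
      rg$measure_um
    else {
      m <- (rg$xmax - rg$xmin) * (rg$ymax - rg$ymin) * 1e-6
      if (d == 3) m <- m * (rg$zmax - rg$zmin) * 1e-3
      m
    }
    if (measure <= 0) stop("region measure must be > 0")
    sum(sel) / measure / n_locs_per_label
  }, numeric(1))
  list(per_region = dens, mean = mean(dens),
       sd = if (length(dens) > 1) stats::sd(dens) else NA_real_,
       n_regions = length(dens))
}

#' Nyquist resolution limit from label density
#'
#' Twice the mean distance between neighboring labels:
#' `alpha_Nyquist = 2 / a^(1/d)`, with `a` in labels per um^d and the result
#' in nm.
#'
#' @param a label density, labels per um^d.
#' @param d dimension, 2 or 3.
#' @return resolution limit, nm.
#' @export
nyquist_resolution <- function(a, d = 2) {
  if (any(a <= 0)) stop("label density must be > 0")
  if (!all(d %in% c(2, 3))) stop("d must be 2 or 3")
  1000 * 2 / a^(1 / d)
}

#' Combine Nyquist limit and localization precision in quadrature
#'
#' The two error sources are independent, so the final image resolution is
#' `sqrt(alpha_Nyquist^2 + precision^2)`.
#'
#' @param alpha_nyquist Nyquist resolution limit, nm.
#' @param precision_fwhm localization precision FWHM, nm.
#' @return combined resolution, nm.
#' @export
combined_resolution <- function(alpha_nyquist, precision_fwhm) {
  if (any(alpha_nyquist < 0) || any(precision_fwhm < 0))
    stop("arguments must be >= 0")
  sqrt(alpha_nyquist^2 + precision_fwhm^2)
}

#' Fold changes in density and Nyquist resolution
#'
#' @param a1,a2 label densities (labels per um^d).
#' @param d dimension.
#' @return list with `density_fold` (`a1/a2`) and `nyquist_fold`
#'   (`(a1/a2)^(1/d)`, the factor by which the Nyquist limit improves).
#' @export
density_fold_change <- function(a1, a2, d = 2) {
  if (a1 <= 0 || a2 <= 0) stop("densities must be > 0")
  list(density_fold = a1 / a2, nyquist_fold = (a1 / a2)^(1 / d))
}

#' Serial-scan imaging time from voxel dwell time
#'
#' Time to raster a volume at a given voxel pitch with a fixed dwell per
#' voxel (the arithmetic behind comparing STORM to scanning EM speed).
#'
#' @param volume_um length-3 volume dimensions, um.
#' @param pitch_nm voxel pitch, nm.
#' @param dwell_us dwell time per voxel, us.
#' @return total time, seconds.
#' @export
voxel_dwell_time <- function(volume_um, pitch_nm = 50, dwell_us = 10) {
  if (any(volume_um < 0) || pitch_nm <= 0 || dwell_us <= 0)
    stop("dimensions must be >= 0, pitch and dwell > 0")
  prod(volume_um * 1000 / pitch_nm) * dwell_us * 1e-6
}

#' Per-channel localization fractions in a region
#'
#' Fractions of the specific color channels (nonspecific and unassigned
#' localizations excluded); used to check that color ratios are uniform along
#' a neural process.
#'
#' @param table color-coded localization table.
#' @param region optional bounds list/row (`xmin`, `xmax`, `ymin`, `ymax`).
#' @param channels channels to report.
#' @return named numeric of fractions summing to 1.
#' @export
channel_ratio <- function(table, region = NULL,
                          channels = c("ch405", "ch457", "ch532")) {
  tab <- table
  if (!is.null(region))
    tab <- tab[tab$x_nm >= region$xmin & tab$x_nm <= region$xmax &
               tab$y_nm >= region$ymin & tab$y_nm <= region$ymax, ]
  counts <- vapply(channels, function(ch) sum(tab$channel == ch), numeric(1))
  if (sum(counts) == 0)
    stop("no specific localizations in the region; ratio undefined")
  counts / sum(counts)
}

#' Assemble a resolution report
#'
#' Evaluates the Nyquist limit at the given label density and combines it in
#' quadrature with the localization precision per axis.
#'
#' @param a label density, labels per um^d.
#' @param d dimension, 2 or 3.
#' @param precision_xy lateral localization precision FWHM, nm.
#' @param precision_z axial precision FWHM, nm (3D only).
#' @param n_locs_per_label divisor used to obtain `a` (recorded).
#' @return A `resolution_report` list: `label_density`, `d`,
#'   `n_locs_per_label`, `alpha_nyquist_nm`, `precision_xy_nm`,
#'   `precision_z_nm`, `resolution_xy_nm`, `resolution_z_nm`.
#' @export
resolution_report <- function(a, d = 2, precision_xy, precision_z = NA,
                              n_locs_per_label = 4) {
  alpha <- nyquist_resolution(a, d)
  structure(list(
    label_density = a, d = d, n_locs_per_label = n_locs_per_label,
    alpha_nyquist_nm = alpha,
    precision_xy_nm = precision_xy, precision_z_nm = precision_z,
    resolution_xy_nm = combined_resolution(alpha, precision_xy),
    resolution_z_nm = if (is.na(precision_z)) NA_real_
                      else combined_resolution(alpha, precision_z)),
    class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat(sprintf("resolution_report: a = %.0f labels/um^%d (n = %g)\n",
              x$label_density, x$d, x$n_locs_per_label))
  cat(sprintf("  Nyquist limit   : %.1f nm\n", x$alpha_nyquist_nm))
  cat(sprintf("  precision (xy)  : %.1f nm FWHM\n", x$precision_xy_nm))
  if (!is.na(x$precision_z_nm))
    cat(sprintf("  precision (z)   : %.1f nm FWHM\n", x$precision_z_nm))
  cat(sprintf("  resolution (xy) : %.1f nm\n", x$resolution_xy_nm))
  if (!is.na(x$resolution_z_nm))
    cat(sprintf("  resolution (z)  : %.1f nm\n", x$resolution_z_nm))
  invisible(x)
}
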