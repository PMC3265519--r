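# Drift estimation and correction by cross-correlating images reconstructed
# from temporal subsets of localizations.

# 2D count histogram of localizations at `pixel` nm pitch over fixed limits.
render_hist2d <- function(x, y, pixel, xlim, ylim) {
  W <- max(1L, ceiling((xlim[2] - xlim[1]) / pixel))
  H <- max(1L, ceiling((ylim[2] - ylim[1]) / pixel))
  cx <- pmin(pmax(floor((x - xlim[1]) / pixel), 0), W - 1)
  cy <- pmin(pmax(floor((y - ylim[1]) / pixel), 0), H - 1)
  matrix(tabulate(cy + H * cx + 1, nbins = H * W), H, W)
}

# Translation of `img` relative to `ref` (in pixels) by FFT cross-correlation
# with 3-point parabolic sub-pixel refinement per axis.
xcorr_shift <- function(ref, img) {
  H <- nrow(ref); W <- ncol(ref)
  P <- 2L * c(H, W)                       # zero-pad to avoid wrap ambiguity
  rp <- matrix(0, P[1], P[2]); rp[1:H, 1:W] <- ref - mean(ref)
  ip <- matrix(0, P[1], P[2]); ip[1:H, 1:W] <- img - mean(img)
  cc <- Re(stats::fft(Conj(stats::fft(rp)) * stats::fft(ip), inverse = TRUE))
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  wrap <- function(i, n) ((i - 1 + n / 2) %% n) - n / 2
  at <- function(r, c) cc[((r - 1) %% P[1]) + 1, ((c - 1) %% P[2]) + 1]
  dr <- parabolic_offset(at(pk[1] - 1, pk[2]), at(pk[1], pk[2]),
                         at(pk[1] + 1, pk[2]))
  dc <- parabolic_offset(at(pk[1], pk[2] - 1), at(pk[1], pk[2]),
                         at(pk[1], pk[2] + 1))
  conf <- (max(cc) - mean(cc)) / stats::sd(cc)
  c(dx = wrap(pk[2], P[2]) + dc, dy = wrap(pk[1], P[1]) + dr,
    confidence = conf)
}

#' Construct a drift trace
#'
#' Per-time-bin lateral offsets. Between bin centers the offset is
#' piecewise-linear; beyond the first/last bin center it is held constant.
#'
#' @param bins data.frame with columns `bin_start`, `bin_end`, `dx_nm`,
#'   `dy_nm` and optionally `dz_nm` (defaults to 0) and `confidence`.
#' @param reference_bin index of the bin whose offset defines zero.
#' @export
drift_trace <- function(bins, reference_bin = 1L) {
  bins <- as.data.frame(bins)
  if (is.null(bins$dz_nm)) bins$dz_nm <- 0
  if (is.null(bins$confidence)) bins$confidence <- NA_real_
  bins$frame_center <- (bins$bin_start + bins$bin_end) / 2
  structure(bins, reference_bin = as.integer(reference_bin),
            class = c("drift_trace", "data.frame"))
}

# Interpolated (dx, dy, dz) nm at the given frames.
drift_offsets_at <- function(trace, frames) {
  stopifnot(inherits(trace, "drift_trace"))
  if (nrow(trace) == 1)
    return(cbind(dx = rep(trace$dx_nm, length(frames)),
                 dy = rep(trace$dy_nm, length(frames)),
                 dz = rep(trace$dz_nm, length(frames))))
  fc <- trace$frame_center
  cbind(dx = stats::approx(fc, trace$dx_nm, frames, rule = 2)$y,
        dy = stats::approx(fc, trace$dy_nm, frames, rule = 2)$y,
        dz = stats::approx(fc, trace$dz_nm, frames, rule = 2)$y)
}

#' Estimate sample drift from a localization table
#'
#' Splits the movie into frame bins, reconstructs a 2D image per bin and
#' cross-correlates each against the reference bin's image (by default the
#' first bin). The correlation peak is refined to sub-pixel precision by
#' quadratic interpolation.
#'
#' @param table localization table.
#' @param bin_frames frames per bin (500-1000 typical).
#' @param render_pixel reconstruction pixel, nm.
#' @param reference_bin bin index used as reference.
#' @param min_confidence bins whose correlation peak prominence (peak minus
#'   mean, in correlation-image standard deviations) falls below this are
#'   considered featureless and raise an error.
#' @param min_per_bin emit a warning when a bin holds fewer localizations.
#' @return A [drift_trace()].
#' @export
estimate_drift <- function(table, bin_frames = 1000, render_pixel = 25,
                           reference_bin = 1L, min_confidence = 5,
                           min_per_bin = 1000) {
  n_frames <- attr(table, "n_frames") %||% max(table$frame)
  if (n_frames < 2 * bin_frames)
    stop("need at least 2 bins; reduce bin_frames")
  starts <- seq(1L, n_frames, by = bin_frames)
  ends <- pmin(starts + bin_frames - 1L, n_frames)
  xlim <- range(table$x_nm) + c(-2, 2) * render_pixel
  ylim <- range(table$y_nm) + c(-2, 2) * render_pixel
  bin_of <- findInterval(table$frame, starts)
  imgs <- lapply(seq_along(starts), function(b) {
    sel <- bin_of == b
    if (sum(sel) < min_per_bin)
      warning(sprintf("bin %d has only %d localizations; consider larger bins",
                      b, sum(sel)))
    render_hist2d(table$x_nm[sel], table$y_nm[sel], render_pixel, xlim, ylim)
  })
  ref <- imgs[[reference_bin]]
  rows <- lapply(seq_along(imgs), function(b) {
    if (b == reference_bin)
      return(data.frame(bin_start = starts[b], bin_end = ends[b], dx_nm = 0,
                        dy_nm = 0, dz_nm = 0, confidence = Inf))
    s <- xcorr_shift(ref, imgs[[b]])
    if (s["confidence"] < min_confidence)
      stop(sprintf(paste0("featureless bin %d (correlation confidence %.1f);",
                          " use larger bins"), b, s["confidence"]))
    data.frame(bin_start = starts[b], bin_end = ends[b],
               dx_nm = s[["dx"]] * render_pixel,
               dy_nm = s[["dy"]] * render_pixel, dz_nm = 0,
               confidence = s[["confidence"]])
  })
  drift_trace(do.call(rbind, rows), reference_bin = reference_bin)
}

#' Subtract a drift trace from a localization table
#'
#' Each localization is shifted by the interpolated offset at its frame.
#' Counts, photons and z are untouched.
#'
#' @param table localization table.
#' @param trace a [drift_trace()] covering the table's frame range.
#' @return corrected table (metadata preserved).
#' @export
apply_drift <- function(table, trace) {
  stopifnot(inherits(trace, "drift_trace"))
  if (nrow(table) == 0) return(table)
  if (min(table$frame) < min(trace$bin_start) ||
      max(table$frame) > max(trace$bin_end))
    stop("drift trace does not cover the table's frame range")
  off <- drift_offsets_at(trace, table$frame)
  out <- table
  out$x_nm <- table$x_nm - off[, "dx"]
  out$y_nm <- table$y_nm - off[, "dy"]
  if (any(off[, "dz"] != 0) && !all(is.na(out$z_nm)))
    out$z_nm <- table$z_nm - off[, "dz"]
  copy_table_meta(out, table)
}
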