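# Independent oracles and fixture builders shared by the tests. Oracles are
# written as direct brute-force computations, independent of the package's
# implementation paths.

test_calibration <- function() {
  astig_calibration(wx = c(w0 = 150, c = 250, d = 400, A = 0, B = 0),
                    wy = c(w0 = 150, c = -250, d = 400, A = 0, B = 0),
                    z_range = c(-400, 400))
}

# Direct-summation difference-of-Gaussians: full 2D kernels, nested loops,
# replicate padding. O(HW k^2); only for small fixtures.
dog_oracle <- function(img, k_small, k_large) {
  conv_direct <- function(img, kern) {
    r <- (length(kern) - 1L) %/% 2L
    K <- outer(kern, kern)
    H <- nrow(img); W <- ncol(img)
    out <- matrix(0, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      acc <- 0
      for (a in -r:r) for (b in -r:r) {
        ii <- min(max(i + a, 1L), H)
        jj <- min(max(j + b, 1L), W)
        acc <- acc + K[a + r + 1L, b + r + 1L] * img[ii, jj]
      }
      out[i, j] <- acc
    }
    out
  }
  conv_direct(img, k_small) - conv_direct(img, k_large)
}

# Exhaustive scan for strict 8-neighborhood local maxima above a threshold.
peaks_oracle <- function(img, threshold) {
  H <- nrow(img); W <- ncol(img)
  hits <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- img[i, j]
    if (v <= threshold) next
    ok <- TRUE
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && img[ii, jj] >= v)
        ok <- FALSE
    }
    if (ok) hits <- rbind(hits, c(i, j))
  }
  hits
}

# Pixel-integrated Gaussian ROI (independent construction via pnorm).
make_roi <- function(n, x0, y0, sx, sy, N, b) {
  fx <- diff(stats::pnorm((0:n - x0) / sx))
  fy <- diff(stats::pnorm((0:n - y0) / sy))
  N * (fy %o% fx) + b
}

# Exhaustive grid-search least-squares oracle for the symmetric 2D Gaussian
# fit: profiles amplitude and background out by linear least squares at every
# grid point of (x0, y0, sigma).
oracle_fit_2d <- function(roi, xg, yg, sg) {
  n <- nrow(roi)
  np <- n * n
  Sd <- sum(roi)
  best <- list(rss = Inf)
  for (s in sg) {
    Gx <- vapply(xg, function(x) diff(stats::pnorm((0:n - x) / s)),
                 numeric(n))
    Gy <- vapply(yg, function(y) diff(stats::pnorm((0:n - y) / s)),
                 numeric(n))
    s1x <- colSums(Gx); s1y <- colSums(Gy)
    s2x <- colSums(Gx^2); s2y <- colSums(Gy^2)
    S1 <- s1y %o% s1x                 # sum of shape, per (y, x)
    S2 <- s2y %o% s2x                 # sum of shape^2
    Smd <- t(Gy) %*% roi %*% Gx       # sum of shape * data
    den <- np * S2 - S1^2
    A <- (np * Smd - S1 * Sd) / den
    b <- (Sd - A * S1) / np
    rss <- sum(roi^2) - 2 * A * Smd - 2 * b * Sd + A^2 * S2 +
      2 * A * b * S1 + b^2 * np
    k <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    if (min(rss) < best$rss)
      best <- list(rss = min(rss), x0 = xg[k[2]], y0 = yg[k[1]], s = s,
                   A = A[k[1], k[2]], b = b[k[1], k[2]])
  }
  best
}

# Elliptical variant: grid over (x0, y0, sx, sy).
oracle_fit_3d <- function(roi, xg, yg, sxg, syg) {
  n <- nrow(roi)
  np <- n * n
  Sd <- sum(roi)
  best <- list(rss = Inf)
  for (sx in sxg) for (sy in syg) {
    Gx <- vapply(xg, function(x) diff(stats::pnorm((0:n - x) / sx)),
                 numeric(n))
    Gy <- vapply(yg, function(y) diff(stats::pnorm((0:n - y) / sy)),
                 numeric(n))
    S1 <- colSums(Gy) %o% colSums(Gx)
    S2 <- colSums(Gy^2) %o% colSums(Gx^2)
    Smd <- t(Gy) %*% roi %*% Gx
    den <- np * S2 - S1^2
    A <- (np * Smd - S1 * Sd) / den
    b <- (Sd - A * S1) / np
    rss <- sum(roi^2) - 2 * A * Smd - 2 * b * Sd + A^2 * S2 +
      2 * A * b * S1 + b^2 * np
    k <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    if (min(rss) < best$rss)
      best <- list(rss = min(rss), x0 = xg[k[2]], y0 = yg[k[1]],
                   sx = sx, sy = sy)
  }
  best
}

# Least-squares oracle for the mosaic layout: solve the normal equations of
# p_j - p_i = d_ij per axis with the anchor eliminated.
layout_ls_oracle <- function(offsets, anchor) {
  nodes <- unique(c(as.character(offsets$fov_i), as.character(offsets$fov_j)))
  free <- setdiff(nodes, anchor)
  A <- matrix(0, nrow(offsets), length(free))
  for (e in seq_len(nrow(offsets))) {
    i <- as.character(offsets$fov_i[e]); j <- as.character(offsets$fov_j[e])
    if (i != anchor) A[e, match(i, free)] <- -1
    if (j != anchor) A[e, match(j, free)] <- 1
  }
  sol <- vapply(c("dx_nm", "dy_nm", "dz_nm"), function(col)
    stats::coef(stats::lm.fit(A, offsets[[col]])), numeric(length(free)))
  out <- rbind(0, sol)
  rownames(out) <- c(anchor, free)
  colnames(out) <- c("X_nm", "Y_nm", "Z_nm")
  out
}

# Minimal localization table with the attributes downstream stages expect.
make_loc_table <- function(frame, x, y, z = NA_real_, photons = 5000,
                           channel = "unassigned", n_frames = max(frame),
                           pixel_nm = 160) {
  n <- length(frame)
  tab <- data.frame(frame = frame, x_nm = x, y_nm = y,
                    z_nm = rep_len(z, n), photons = rep_len(photons, n),
                    wx_nm = 160, wy_nm = 160, residual = 0,
                    channel = rep_len(channel, n), fov_id = 1L, pass_id = 1L)
  attr(tab, "n_frames") <- n_frames
  attr(tab, "pixel_nm") <- pixel_nm
  tab
}

# Events from labels on a structure turned into an ideal localization table
# (true positions plus isotropic fitting scatter) - used where the test
# targets a postprocessing stage rather than the fitter.
events_to_table <- function(events, emitters, scatter = 8, n_frames,
                            seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  m <- match(events$emitter_id, emitters$emitter_id)
  withr_seed({
    make_loc_table(
      frame = events$frame,
      x = emitters$x_nm[m] + stats::rnorm(nrow(events), 0, scatter),
      y = emitters$y_nm[m] + stats::rnorm(nrow(events), 0, scatter),
      z = emitters$z_nm[m],
      photons = events$photons,
      n_frames = n_frames)
  })
}
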