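# Ground-truth structure generation: fluorescent labels placed by a Poisson
# point process on the membrane surface of tubular "neurites" (or flat
# patches), mimicking membrane-targeted labeling of thin neural processes.

#' Specify a ground-truth labeled structure
#'
#' @param kind one of `"tube"`, `"x_junction"`, `"y_junction"`, `"flat_patch"`.
#' @param tube_radius tube radius in nm (membrane shell radius).
#' @param axis for `tube`: matrix of 3D polyline vertices (nm, columns x,y,z).
#'   For junctions: the center of the junction (length-3). For `flat_patch`: a
#'   2-row matrix giving two opposite corners of an axis-aligned rectangle.
#' @param z_separation axial distance between the two tube axes at a junction,
#'   nm (junctions only).
#' @param label_density labels per square micrometre of membrane surface.
#' @param arm_length junction arm length, nm.
#' @return A `structure_spec` list.
#' @export
structure_spec <- function(kind = c("tube", "x_junction", "y_junction",
                                    "flat_patch"),
                           tube_radius = 75, axis = NULL, z_separation = 0,
                           label_density = 2500, arm_length = 2000) {
  kind <- match.arg(kind)
  stopifnot_scalar(tube_radius, "tube_radius", positive = TRUE)
  if (label_density < 0) stop("label_density must be >= 0")
  if (z_separation < 0) stop("z_separation must be >= 0")
  structure(list(kind = kind, tube_radius = tube_radius, axis = axis,
                 z_separation = z_separation, label_density = label_density,
                 arm_length = arm_length),
            class = "structure_spec")
}

# Orthonormal frame (n1, n2) perpendicular to a direction vector.
perp_frame <- function(t) {
  t <- t / sqrt(sum(t^2))
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  n1 <- ref - sum(ref * t) * t
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(t[2] * n1[3] - t[3] * n1[2],
          t[3] * n1[1] - t[1] * n1[3],
          t[1] * n1[2] - t[2] * n1[1])
  list(t = t, n1 = n1, n2 = n2)
}

# Poisson sample of points on the surface of a tube around a polyline axis.
sample_tube_surface <- function(axis, radius, density_um2) {
  axis <- as.matrix(axis)
  if (nrow(axis) < 2) stop("degenerate polyline: need at least 2 vertices")
  seg <- diff(axis)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) <= 0) stop("degenerate polyline: zero total length")
  keep <- seg_len > 0
  seg <- seg[keep, , drop = FALSE]
  seg_len <- seg_len[keep]
  area_um2 <- 2 * pi * radius * sum(seg_len) * 1e-6   # nm^2 -> um^2
  n <- stats::rpois(1, area_um2 * density_um2)
  if (n == 0)
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  si <- sample.int(length(seg_len), n, replace = TRUE, prob = seg_len)
  u <- stats::runif(n)
  phi <- stats::runif(n, 0, 2 * pi)
  pts <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  starts <- axis[which(keep), , drop = FALSE]
  for (s in unique(si)) {
    idx <- which(si == s)
    fr <- perp_frame(seg[s, ])
    base <- matrix(starts[s, ], length(idx), 3, byrow = TRUE) +
      outer(u[idx] * seg_len[s], fr$t)
    pts[idx, ] <- base + outer(radius * cos(phi[idx]), fr$n1) +
      outer(radius * sin(phi[idx]), fr$n2)
  }
  pts
}

#' Generate ground-truth label positions for a structure
#'
#' Labels are placed by a homogeneous Poisson point process on the membrane
#' surface at the requested areal density (labels per square micrometre of
#' surface). Junction structures consist of two tubes whose axes cross in x/y
#' and are separated axially by `z_separation` nm.
#'
#' @param spec a [structure_spec()].
#' @param seed integer RNG seed (optional).
#' @param structure_id id recorded for every emitter.
#' @return data.frame (an "emitter set") with columns `emitter_id`, `x_nm`,
#'   `y_nm`, `z_nm`, `channel`, `structure_id`.
#' @export
make_structure <- function(spec, seed = NULL, structure_id = 1L) {
  stopifnot(inherits(spec, "structure_spec"))
  with_seed(seed, {
    pts <- switch(spec$kind,
      tube = {
        if (is.null(spec$axis)) stop("tube structure needs an axis polyline")
        sample_tube_surface(spec$axis, spec$tube_radius, spec$label_density)
      },
      x_junction = {
        ctr <- if (is.null(spec$axis)) c(0, 0, 0) else as.numeric(spec$axis)
        L <- spec$arm_length
        dz <- spec$z_separation
        a1 <- rbind(ctr + c(-L, 0, -dz / 2), ctr + c(L, 0, -dz / 2))
        a2 <- rbind(ctr + c(0, -L, dz / 2), ctr + c(0, L, dz / 2))
        rbind(sample_tube_surface(a1, spec$tube_radius, spec$label_density),
              sample_tube_surface(a2, spec$tube_radius, spec$label_density))
      },
      y_junction = {
        ctr <- if (is.null(spec$axis)) c(0, 0, 0) else as.numeric(spec$axis)
        L <- spec$arm_length
        dz <- spec$z_separation
        trunk <- rbind(ctr + c(-L, 0, 0), ctr)
        b1 <- rbind(ctr, ctr + c(L * 0.8, L * 0.6, 0))
        b2 <- rbind(ctr + c(0, 0, dz), ctr + c(L * 0.8, -L * 0.6, dz))
        rbind(sample_tube_surface(trunk, spec$tube_radius, spec$label_density),
              sample_tube_surface(b1, spec$tube_radius, spec$label_density),
              sample_tube_surface(b2, spec$tube_radius, spec$label_density))
      },
      flat_patch = {
        if (is.null(spec$axis) || nrow(spec$axis) != 2)
          stop("flat_patch needs a 2-row corner matrix")
        lo <- pmin(spec$axis[1, ], spec$axis[2, ])
        hi <- pmax(spec$axis[1, ], spec$axis[2, ])
        area_um2 <- (hi[1] - lo[1]) * (hi[2] - lo[2]) * 1e-6
        if (area_um2 <= 0) stop("degenerate patch: zero area")
        n <- stats::rpois(1, area_um2 * spec$label_density)
        cbind(x = stats::runif(n, lo[1], hi[1]),
              y = stats::runif(n, lo[2], hi[2]),
              z = rep(if (length(lo) >= 3) lo[3] else 0, n))
      })
    n <- nrow(pts)
    data.frame(emitter_id = seq_len(n),
               x_nm = pts[, 1], y_nm = pts[, 2], z_nm = pts[, 3],
               channel = rep("ch405", n),
               structure_id = rep(structure_id, n))
  })
}

#' Combine emitter sets and assign channels
#'
#' @param ... emitter data.frames from [make_structure()].
#' @param channels channel name per input set (recycled if length 1).
#' @return single emitter data.frame with unique `emitter_id`.
#' @export
combine_emitters <- function(..., channels = "ch405") {
  sets <- list(...)
  channels <- rep_len(channels, length(sets))
  for (i in seq_along(sets)) {
    sets[[i]]$channel <- channels[i]
    sets[[i]]$structure_id <- i
  }
  out <- do.call(rbind, sets)
  out$emitter_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
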