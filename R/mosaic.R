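# Alignment of focal planes within a field of view and stitching of
# overlapping fields of view into one mosaic, via cross-correlation offsets
# and equal-weight iterative relaxation.

# 3D count histogram (H x W x nz array).
hist3d <- function(tab, xy_pixel, z_pixel, xlim, ylim, zlim) {
  W <- max(1L, ceiling((xlim[2] - xlim[1]) / xy_pixel))
  H <- max(1L, ceiling((ylim[2] - ylim[1]) / xy_pixel))
  NZ <- max(1L, ceiling((zlim[2] - zlim[1]) / z_pixel))
  cx <- pmin(pmax(floor((tab$x_nm - xlim[1]) / xy_pixel), 0), W - 1)
  cy <- pmin(pmax(floor((tab$y_nm - ylim[1]) / xy_pixel), 0), H - 1)
  cz <- pmin(pmax(floor((tab$z_nm - zlim[1]) / z_pixel), 0), NZ - 1)
  array(tabulate(cy + H * cx + H * W * cz + 1, nbins = H * W * NZ),
        dim = c(H, W, NZ))
}

# Axial shift of `tj` relative to `ti` (in z pixels) by cross-correlating
# their 3D reconstructions along z only (x, y assumed already aligned). The
# voxel-wise product counts only co-located structure, so slanted or
# truncated structures are handled correctly.
zshift_overlap <- function(ti, tj, xy_pixel, z_pixel, max_shift_px = 12L) {
  xlim <- range(c(ti$x_nm, tj$x_nm)) + c(-1, 1) * xy_pixel
  ylim <- range(c(ti$y_nm, tj$y_nm)) + c(-1, 1) * xy_pixel
  zlim <- range(c(ti$z_nm, tj$z_nm)) + c(-1, 1) * z_pixel
  A <- hist3d(ti, xy_pixel, z_pixel, xlim, ylim, zlim)
  B <- hist3d(tj, xy_pixel, z_pixel, xlim, ylim, zlim)
  nz <- dim(A)[3]
  K <- min(max_shift_px, nz - 1L)
  shifts <- (-K):K
  cc <- vapply(shifts, function(s) {
    ia <- max(1, 1 - s):min(nz, nz - s)      # A slices
    ib <- ia + s                              # B holds A's content shifted +s
    sum(A[, , ia, drop = FALSE] * B[, , ib, drop = FALSE])
  }, numeric(1))
  j <- which.max(cc)
  off <- if (j > 1 && j < length(cc))
    parabolic_offset(cc[j - 1], cc[j], cc[j + 1]) else 0
  conf <- if (stats::sd(cc) > 0) (max(cc) - mean(cc)) / stats::sd(cc) else 0
  c(shift = shifts[j] + off, confidence = conf)
}

#' Align localization tables from multiple focal planes of one field of view
#'
#' Lateral (x, y) offsets of each plane are measured by cross-correlating its
#' 2D reconstruction against the reference plane (by default the middle focal
#' plane). Axial offsets are then measured by cross-correlating z histograms
#' (at `z_pixel` pitch) of the overlapping z slab between each plane and the
#' reference, exploiting that the focal stepping (300 nm) is smaller than the
#' astigmatic detection range (800 nm). Planes whose overlap holds too little
#' structure are flagged rather than silently aligned.
#'
#' @param tables list of 3D localization tables of the same FOV, one per focal
#'   plane, with absolute `z_nm` (plane focal position already included).
#' @param z_pixel z reconstruction pixel, nm.
#' @param xy_pixel lateral reconstruction pixel, nm.
#' @param reference index of the reference plane (default: middle).
#' @param min_confidence minimal correlation confidence before a plane is
#'   flagged (`flagged = TRUE`, offsets left at 0 for manual override).
#' @param min_overlap_locs minimal localizations in the z-overlap slab.
#' @return list with `table` (merged master table, plane recorded in the
#'   `plane` column) and `offsets` (per-plane `dx_nm`, `dy_nm`, `dz_nm`,
#'   `confidence`, `flagged`).
#' @export
align_focal_planes <- function(tables, z_pixel = 50, xy_pixel = 25,
                               reference = NULL, min_confidence = 4,
                               min_overlap_locs = 50) {
  np <- length(tables)
  if (is.null(reference)) reference <- (np + 1L) %/% 2L
  xlim <- range(unlist(lapply(tables, function(t) t$x_nm))) +
    c(-2, 2) * xy_pixel
  ylim <- range(unlist(lapply(tables, function(t) t$y_nm))) +
    c(-2, 2) * xy_pixel
  ref2d <- render_hist2d(tables[[reference]]$x_nm, tables[[reference]]$y_nm,
                         xy_pixel, xlim, ylim)
  refz <- range(tables[[reference]]$z_nm)
  rows <- vector("list", np)
  aligned <- vector("list", np)
  for (p in seq_len(np)) {
    tab <- tables[[p]]
    if (p == reference) {
      rows[[p]] <- data.frame(plane = p, dx_nm = 0, dy_nm = 0, dz_nm = 0,
                              confidence = Inf, flagged = FALSE)
    } else {
      s <- xcorr_shift(ref2d, render_hist2d(tab$x_nm, tab$y_nm, xy_pixel,
                                            xlim, ylim))
      dx <- s[["dx"]] * xy_pixel; dy <- s[["dy"]] * xy_pixel
      flagged <- s[["confidence"]] < min_confidence
      dz <- 0
      # z overlap slab between this plane's and the reference's z coverage
      slab <- c(max(refz[1], min(tab$z_nm)), min(refz[2], max(tab$z_nm)))
      nref <- sum(tables[[reference]]$z_nm >= slab[1] &
                  tables[[reference]]$z_nm <= slab[2])
      ntab <- sum(tab$z_nm >= slab[1] & tab$z_nm <= slab[2])
      if (!flagged && slab[2] > slab[1] &&
          min(nref, ntab) >= min_overlap_locs) {
        shifted <- tab
        shifted$x_nm <- tab$x_nm - dx
        shifted$y_nm <- tab$y_nm - dy
        sz <- zshift_overlap(tables[[reference]], shifted, xy_pixel, z_pixel)
        if (sz[["confidence"]] > 0) dz <- sz[["shift"]] * z_pixel
        else flagged <- TRUE
      } else if (!flagged) {
        flagged <- TRUE          # structure-free overlap: leave to manual
      }
      rows[[p]] <- data.frame(plane = p, dx_nm = dx, dy_nm = dy, dz_nm = dz,
                              confidence = s[["confidence"]],
                              flagged = flagged)
      tab$x_nm <- tab$x_nm - dx
      tab$y_nm <- tab$y_nm - dy
      tab$z_nm <- tab$z_nm - dz
    }
    tab$plane <- p
    aligned[[p]] <- as.data.frame(tab)
  }
  master <- do.call(rbind, aligned)
  rownames(master) <- NULL
  master <- copy_table_meta(master, tables[[reference]])
  list(table = master, offsets = do.call(rbind, rows))
}

# Measured 3D shift of table j's content relative to table i's over their
# nominal overlap region.
measure_tile_shift <- function(ti, tj, xy_pixel, z_pixel) {
  xb <- c(max(min(ti$x_nm), min(tj$x_nm)), min(max(ti$x_nm), max(tj$x_nm)))
  yb <- c(max(min(ti$y_nm), min(tj$y_nm)), min(max(ti$y_nm), max(tj$y_nm)))
  if (xb[2] <= xb[1] || yb[2] <= yb[1])
    return(c(dx = 0, dy = 0, dz = 0, confidence = 0))
  pad <- 5 * xy_pixel
  xb <- xb + c(-pad, pad); yb <- yb + c(-pad, pad)
  si <- ti[ti$x_nm >= xb[1] & ti$x_nm <= xb[2] &
           ti$y_nm >= yb[1] & ti$y_nm <= yb[2], ]
  sj <- tj[tj$x_nm >= xb[1] & tj$x_nm <= xb[2] &
           tj$y_nm >= yb[1] & tj$y_nm <= yb[2], ]
  if (nrow(si) < 20 || nrow(sj) < 20)
    return(c(dx = 0, dy = 0, dz = 0, confidence = 0))
  s <- xcorr_shift(render_hist2d(si$x_nm, si$y_nm, xy_pixel, xb, yb),
                   render_hist2d(sj$x_nm, sj$y_nm, xy_pixel, xb, yb))
  dz <- 0
  if (!all(is.na(si$z_nm)) && !all(is.na(sj$z_nm))) {
    sj2 <- sj
    sj2$x_nm <- sj$x_nm - s[["dx"]] * xy_pixel
    sj2$y_nm <- sj$y_nm - s[["dy"]] * xy_pixel
    sz <- zshift_overlap(si, sj2, xy_pixel, z_pixel)
    if (sz[["confidence"]] > 0) dz <- sz[["shift"]] * z_pixel
  }
  c(dx = s[["dx"]] * xy_pixel, dy = s[["dy"]] * xy_pixel, dz = dz,
    confidence = s[["confidence"]])
}

#' Measure pairwise offsets between adjacent fields of view
#'
#' For each declared adjacent pair, reconstructs the nominal overlap region of
#' both tiles and measures the residual translation of tile `j` relative to
#' tile `i` by cross-correlation (x/y first, then z). Tables must be in
#' nominal global coordinates (stage position already added).
#'
#' @param tables named list of master localization tables, one per FOV.
#' @param adjacency data.frame with columns `i`, `j` (names or indices of
#'   adjacent tiles).
#' @param xy_pixel,z_pixel reconstruction pixels, nm.
#' @return data.frame of tile offsets: `fov_i`, `fov_j`, `dx_nm`, `dy_nm`,
#'   `dz_nm`, `confidence`, `source` (`"auto"`). Each unordered pair is
#'   measured once; the reverse direction is its negation. Self pairs get zero
#'   offset and infinite confidence.
#' @export
pairwise_tile_offsets <- function(tables, adjacency, xy_pixel = 25,
                                  z_pixel = 50) {
  if (is.null(names(tables))) names(tables) <- as.character(seq_along(tables))
  key <- function(i, j) paste(i, j, sep = "\r")
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(adjacency)), function(r) {
    i <- as.character(adjacency$i[r]); j <- as.character(adjacency$j[r])
    if (i == j)
      return(data.frame(fov_i = i, fov_j = j, dx_nm = 0, dy_nm = 0, dz_nm = 0,
                        confidence = Inf, source = "auto"))
    a <- min(i, j); b <- max(i, j)
    k <- key(a, b)
    if (!exists(k, envir = cache))
      assign(k, measure_tile_shift(tables[[a]], tables[[b]], xy_pixel,
                                   z_pixel), envir = cache)
    s <- get(k, envir = cache)
    sgn <- if (i == a) 1 else -1
    data.frame(fov_i = i, fov_j = j, dx_nm = sgn * s[["dx"]],
               dy_nm = sgn * s[["dy"]], dz_nm = sgn * s[["dz"]],
               confidence = s[["confidence"]], source = "auto")
  })
  do.call(rbind, rows)
}

#' Solve tile positions from pairwise offsets
#'
#' Iterative equal-weight relaxation: each field of view is repeatedly moved
#' to the mean of the positions implied by its neighbors' positions and the
#' measured pairwise offsets, until the maximum per-iteration movement falls
#' below `tol` (the fixed point is the least-squares solution of the offset
#' system). One anchor tile is fixed at the origin. Offsets with
#' `source = "manual"` are honored as hard constraints: tiles connected by
#' manual edges move as one rigid group.
#'
#' @param offsets data.frame as from [pairwise_tile_offsets()]; `dx_nm` etc.
#'   give the measured shift of `fov_j`'s content relative to `fov_i`'s.
#' @param anchor tile fixed at position zero (default: first tile named).
#' @param tol convergence tolerance on the maximum movement per iteration, nm.
#'   The default iterates essentially to the fixed point, so consistent offset
#'   graphs solve exactly; each sweep is cheap even for hundreds of tiles.
#' @param max_iter iteration cap.
#' @return A `mosaic_layout`: data.frame (`fov`, `X_nm`, `Y_nm`, `Z_nm`) with
#'   convergence diagnostics (`iterations`, `max_residual_nm`, `converged`)
#'   and per-edge residuals as attributes.
#' @export
solve_layout <- function(offsets, anchor = NULL, tol = 1e-9,
                         max_iter = 10000) {
  off <- offsets[as.character(offsets$fov_i) != as.character(offsets$fov_j), ]
  nodes <- unique(c(as.character(off$fov_i), as.character(off$fov_j),
                    as.character(offsets$fov_i)))
  n <- length(nodes)
  if (is.null(anchor)) anchor <- nodes[1]
  d <- as.matrix(off[, c("dx_nm", "dy_nm", "dz_nm")])
  ii <- match(as.character(off$fov_i), nodes)
  jj <- match(as.character(off$fov_j), nodes)

  # connectivity over all edges
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in seq_along(ii)) {
      m <- min(comp[ii[e]], comp[jj[e]])
      if (comp[ii[e]] != m || comp[jj[e]] != m) {
        comp[comp == comp[ii[e]] | comp == comp[jj[e]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    parts <- split(nodes, comp)
    stop("offset graph is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = ","), collapse = " | "))
  }

  # rigid groups from manual edges
  grp <- seq_len(n)
  man <- which(off$source == "manual")
  repeat {
    changed <- FALSE
    for (e in man) {
      m <- min(grp[ii[e]], grp[jj[e]])
      if (grp[ii[e]] != m || grp[jj[e]] != m) {
        grp[grp == grp[ii[e]] | grp == grp[jj[e]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # internal offsets within each rigid group (BFS over manual edges)
  internal <- matrix(0, n, 3)
  for (g in unique(grp)) {
    members <- which(grp == g)
    if (length(members) == 1) next
    root <- members[1]
    seen <- root
    queue <- root
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (e in man) {
        if (ii[e] == u && !(jj[e] %in% seen)) {
          internal[jj[e], ] <- internal[u, ] + d[e, ]
          seen <- c(seen, jj[e]); queue <- c(queue, jj[e])
        } else if (jj[e] == u && !(ii[e] %in% seen)) {
          internal[ii[e], ] <- internal[u, ] - d[e, ]
          seen <- c(seen, ii[e]); queue <- c(queue, ii[e])
        }
      }
    }
  }
  groups <- unique(grp)
  gpos <- matrix(0, length(groups), 3)
  gof <- match(grp, groups)
  # auto edges expressed between groups: g[J] - g[I] = d - (int_j - int_i)
  auto <- setdiff(seq_along(ii), man)
  gi <- gof[ii[auto]]; gj <- gof[jj[auto]]
  gd <- d[auto, , drop = FALSE] -
    (internal[jj[auto], , drop = FALSE] - internal[ii[auto], , drop = FALSE])
  anchor_g <- gof[match(anchor, nodes)]
  iterations <- 0L
  converged <- TRUE
  if (length(groups) > 1 && length(auto)) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      moved <- 0
      for (g in seq_along(groups)) {
        if (g == anchor_g) next
        sel_out <- which(gi == g & gj != g)   # g is i: pos_g = pos_j - d
        sel_in <- which(gj == g & gi != g)    # g is j: pos_g = pos_i + d
        if (!length(sel_out) && !length(sel_in)) next
        est <- rbind(gpos[gj[sel_out], , drop = FALSE] -
                       gd[sel_out, , drop = FALSE],
                     gpos[gi[sel_in], , drop = FALSE] +
                       gd[sel_in, , drop = FALSE])
        newp <- colMeans(est)
        moved <- max(moved, max(abs(newp - gpos[g, ])))
        gpos[g, ] <- newp
      }
      iterations <- it
      if (moved < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning(sprintf("layout relaxation did not converge in %d iterations",
                      max_iter))
  }
  pos <- gpos[gof, , drop = FALSE] + internal
  pos <- sweep(pos, 2, pos[match(anchor, nodes), ])   # anchor at origin
  res <- if (length(ii))
    sqrt(rowSums((pos[jj, , drop = FALSE] - pos[ii, , drop = FALSE] - d)^2))
  else numeric(0)
  layout <- data.frame(fov = nodes, X_nm = pos[, 1], Y_nm = pos[, 2],
                       Z_nm = pos[, 3])
  structure(layout, iterations = iterations, converged = converged,
            max_residual_nm = if (length(res)) max(res) else 0,
            edge_residuals = res, class = c("mosaic_layout", "data.frame"))
}

#' Merge tile tables into one mosaic using a solved layout
#'
#' Each tile's localizations are shifted by minus the tile's solved position
#' (its placement error), mapping all tiles into the anchor's frame.
#' Provenance (`fov_id`, `pass_id`, `plane`) is retained per localization.
#'
#' @param tables named list of master tables in nominal global coordinates.
#' @param layout a `mosaic_layout` covering every table.
#' @return single merged localization table.
#' @export
merge_mosaic <- function(tables, layout) {
  stopifnot(inherits(layout, "mosaic_layout"))
  if (is.null(names(tables))) names(tables) <- as.character(seq_along(tables))
  parts <- lapply(names(tables), function(nm) {
    k <- match(nm, as.character(layout$fov))
    if (is.na(k)) stop("layout has no entry for tile ", nm)
    tab <- as.data.frame(tables[[nm]])
    tab$x_nm <- tab$x_nm - layout$X_nm[k]
    tab$y_nm <- tab$y_nm - layout$Y_nm[k]
    if (!all(is.na(tab$z_nm))) tab$z_nm <- tab$z_nm - layout$Z_nm[k]
    tab$fov_id <- nm
    tab
  })
  cols <- Reduce(intersect, lapply(parts, names))
  out <- do.call(rbind, lapply(parts, function(p) p[, cols]))
  rownames(out) <- NULL
  copy_table_meta(out, tables[[1]])
}

#' Write / read a tile-offsets CSV
#'
#' The CSV (`fov_i,fov_j,dx_nm,dy_nm,dz_nm,confidence,source`) can be edited
#' to override automatic offsets: set `source` to `manual` to make an edge a
#' hard constraint in [solve_layout()].
#' @param offsets offsets data.frame.
#' @param path file path.
#' @export
write_tile_offsets <- function(offsets, path) {
  utils::write.csv(offsets, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tile_offsets
#' @export
read_tile_offsets <- function(path) {
  off <- utils::read.csv(path)
  need <- c("fov_i", "fov_j", "dx_nm", "dy_nm", "dz_nm", "confidence",
            "source")
  missing <- setdiff(need, names(off))
  if (length(missing))
    stop("offsets CSV missing columns: ", paste(missing, collapse = ", "))
  off
}
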