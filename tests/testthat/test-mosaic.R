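# Focal-plane alignment, pairwise tile offsets, layout solving, merging.

tube_emitters <- function(x0, x1, seed, density = 700, z_slope = FALSE) {
  z0 <- if (z_slope) c(-150, 150) else c(0, 0)
  spec <- structure_spec("tube", tube_radius = 40,
                         axis = rbind(c(x0, 1800, z0[1]), c(x1, 2600, z0[2])),
                         label_density = density)
  make_structure(spec, seed = seed)
}

ideal_table <- function(em, err = c(0, 0, 0), reps = 5, seed = 1,
                        scatter = 8) {
  set.seed(seed)
  i <- rep(seq_len(nrow(em)), reps)
  n <- length(i)
  make_loc_table(frame = sample.int(1000, n, TRUE),
                 x = em$x_nm[i] + rnorm(n, 0, scatter) + err[1],
                 y = em$y_nm[i] + rnorm(n, 0, scatter) + err[2],
                 z = em$z_nm[i] + rnorm(n, 0, 20) + err[3],
                 n_frames = 1000)
}

test_that("focal planes with known shifts are re-aligned", {
  em <- make_structure(structure_spec("tube", tube_radius = 40,
      axis = rbind(c(500, 1000, -250), c(7500, 2000, 250)),
      label_density = 900), seed = 31)
  plane_tab <- function(focal, err) {
    sub <- em[abs(em$z_nm - focal) < 350, ]
    ideal_table(sub, err, seed = 32 + round(focal))
  }
  planes <- list(plane_tab(-300, c(80, -40, 150)),
                 plane_tab(0, c(0, 0, 0)),
                 plane_tab(300, c(-30, 50, -90)))
  al <- align_focal_planes(planes, z_pixel = 50, xy_pixel = 25)
  off <- al$offsets
  expect_false(any(off$flagged))
  expect_lt(max(abs(off$dx_nm - c(80, 0, -30))), 12.5)
  expect_lt(max(abs(off$dy_nm - c(-40, 0, 50))), 12.5)
  expect_lt(max(abs(off$dz_nm - c(150, 0, -90))), 25)
  expect_equal(nrow(al$table), sum(vapply(planes, nrow, numeric(1))))
  expect_true(all(c(1, 2, 3) %in% al$table$plane))

  # zero shift gives zero offsets
  al0 <- align_focal_planes(list(planes[[2]], planes[[2]]))
  expect_lt(max(abs(as.matrix(
    al0$offsets[, c("dx_nm", "dy_nm", "dz_nm")]))), 12.5)
})

test_that("planes without z overlap are flagged, not silently aligned", {
  emA <- tube_emitters(500, 7000, seed = 33)
  tabA <- ideal_table(emA, seed = 34)
  tabA$z_nm <- runif(nrow(tabA), -300, -60)
  tabB <- ideal_table(emA, seed = 35)
  tabB$z_nm <- runif(nrow(tabB), 60, 300)   # empty overlap slab
  al <- align_focal_planes(list(tabA, tabB), reference = 1)
  expect_true(al$offsets$flagged[2])
  expect_equal(al$offsets$dz_nm[2], 0)
})

test_that("pairwise tile offsets recover stage errors and are antisymmetric", {
  em <- tube_emitters(500, 23500, seed = 36, z_slope = TRUE)
  clip <- function(x0, x1, err, seed)
    ideal_table(em[em$x_nm >= x0 & em$x_nm <= x1, ], err, seed = seed)
  tiles <- list(A = clip(0, 9000, c(0, 0, 0), 37),
                B = clip(8000, 17000, c(60, -35, 40), 38))
  adj <- data.frame(i = c("A", "B", "A"), j = c("B", "A", "A"))
  off <- pairwise_tile_offsets(tiles, adj)
  expect_lt(max(abs(off[1, c("dx_nm", "dy_nm")] - c(60, -35))), 12.5)
  expect_lt(abs(off$dz_nm[1] - 40), 25)
  # reverse direction is the exact negation (computed once)
  expect_identical(off$dx_nm[2], -off$dx_nm[1])
  expect_identical(off$dz_nm[2], -off$dz_nm[1])
  # self pair
  expect_equal(unlist(off[3, c("dx_nm", "dy_nm", "dz_nm")]),
               c(dx_nm = 0, dy_nm = 0, dz_nm = 0))
  expect_equal(off$confidence[3], Inf)
})

test_that("consistent offset chains solve exactly", {
  off <- data.frame(fov_i = c("A", "B"), fov_j = c("B", "C"),
                    dx_nm = c(100, -50), dy_nm = c(20, 30),
                    dz_nm = c(0, 10), confidence = 10, source = "auto")
  lay <- solve_layout(off, anchor = "A")
  expect_equal(lay$X_nm, c(0, 100, 50))
  expect_equal(lay$Y_nm, c(0, 20, 50))
  expect_equal(lay$Z_nm, c(0, 0, 10))
  expect_lt(attr(lay, "max_residual_nm"), 1e-6)

  single <- solve_layout(data.frame(fov_i = "A", fov_j = "A", dx_nm = 0,
                                    dy_nm = 0, dz_nm = 0, confidence = Inf,
                                    source = "auto"))
  expect_equal(unlist(single[1, c("X_nm", "Y_nm", "Z_nm")]),
               c(X_nm = 0, Y_nm = 0, Z_nm = 0))
})

test_that("inconsistent cycles converge to the least-squares optimum", {
  # triangle with a 30 nm cycle inconsistency injected on one edge
  off <- data.frame(fov_i = c("A", "B", "A"), fov_j = c("B", "C", "C"),
                    dx_nm = c(100, 50, 180), dy_nm = c(0, 0, -30),
                    dz_nm = c(10, 10, 50), confidence = 10, source = "auto")
  lay <- solve_layout(off, anchor = "A")
  orc <- layout_ls_oracle(off, anchor = "A")
  got <- as.matrix(lay[match(rownames(orc), lay$fov),
                       c("X_nm", "Y_nm", "Z_nm")])
  expect_lt(max(abs(got - orc)), 1)
})

test_that("relaxation equals least squares on random connected graphs", {
  set.seed(39)
  for (k in 1:8) {
    n <- sample(4:12, 1)
    truth <- matrix(rnorm(3 * n, sd = 400), n, 3)
    # random spanning tree plus extra edges
    edges <- cbind(2:n, vapply(2:n, function(i) sample(i - 1, 1), numeric(1)))
    extra <- matrix(sample(n, 2 * 4, replace = TRUE), ncol = 2)
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    edges <- rbind(edges, extra)
    d <- truth[edges[, 2], , drop = FALSE] - truth[edges[, 1], , drop = FALSE] +
      matrix(rnorm(3 * nrow(edges), sd = 15), ncol = 3)
    off <- data.frame(fov_i = paste0("n", edges[, 1]),
                      fov_j = paste0("n", edges[, 2]),
                      dx_nm = d[, 1], dy_nm = d[, 2], dz_nm = d[, 3],
                      confidence = 10, source = "auto")
    lay <- solve_layout(off, anchor = "n1", tol = 0.01)
    orc <- layout_ls_oracle(off, anchor = "n1")
    got <- as.matrix(lay[match(rownames(orc), lay$fov),
                         c("X_nm", "Y_nm", "Z_nm")])
    expect_lt(max(abs(got - orc)), 1)
  }
})

test_that("layout is translation-gauge invariant and rejects disconnected
           graphs", {
  off <- data.frame(fov_i = c("A", "B", "C"), fov_j = c("B", "C", "A"),
                    dx_nm = c(90, 10, -110), dy_nm = c(5, -10, 2),
                    dz_nm = 0, confidence = 10, source = "auto")
  layA <- solve_layout(off, anchor = "A")
  layB <- solve_layout(off, anchor = "B")
  relA <- as.matrix(layA[, c("X_nm", "Y_nm", "Z_nm")])
  relB <- as.matrix(layB[, c("X_nm", "Y_nm", "Z_nm")])
  shift <- relA[match("B", layA$fov), ] - relB[match("B", layB$fov), ]
  expect_lt(max(abs(sweep(relB, 2, -shift) -
                      relA[match(layB$fov, layA$fov), ])), 1e-6)

  disc <- data.frame(fov_i = c("A", "C"), fov_j = c("B", "D"),
                     dx_nm = 0, dy_nm = 0, dz_nm = 0, confidence = 1,
                     source = "auto")
  expect_error(solve_layout(disc), "disconnected")
})

test_that("manual offsets are honored as hard constraints", {
  off <- data.frame(fov_i = c("A", "B", "A"), fov_j = c("B", "C", "C"),
                    dx_nm = c(100, 50, 200), dy_nm = 0, dz_nm = 0,
                    confidence = 10, source = c("auto", "manual", "auto"))
  lay <- solve_layout(off, anchor = "A")
  # the manual B->C edge is satisfied exactly even though the auto edges
  # disagree
  expect_equal(lay$X_nm[lay$fov == "C"] - lay$X_nm[lay$fov == "B"], 50,
               tolerance = 1e-9)
})

test_that("merging conserves localizations and keeps tubes continuous", {
  em <- tube_emitters(500, 15500, seed = 40, density = 900)
  clip <- function(x0, x1, err, seed)
    ideal_table(em[em$x_nm >= x0 & em$x_nm <= x1, ], err, seed = seed)
  tiles <- list(A = clip(0, 8500, c(0, 0, 0), 41),
                B = clip(7500, 16000, c(55, -40, 0), 42))
  off <- pairwise_tile_offsets(tiles, data.frame(i = "A", j = "B"))
  lay <- solve_layout(off, anchor = "A")
  merged <- merge_mosaic(tiles, lay)
  expect_equal(nrow(merged), nrow(tiles$A) + nrow(tiles$B))

  # seam continuity: clip the tiles to disjoint halves (equal density
  # everywhere), merge with the solved layout, and compare nearest-neighbor
  # gaps in a strip across the seam against an interior strip (two-sample
  # comparison at the 5% level)
  clipped <- list(A = tiles$A[tiles$A$x_nm < 8000, ],
                  B = tiles$B[tiles$B$x_nm >= 8000, ])
  mclip <- merge_mosaic(clipped, lay)
  nn_gap <- function(pts, xlo, xhi) {
    p <- pts[pts$x_nm >= xlo & pts$x_nm <= xhi, ]
    d <- as.matrix(dist(cbind(p$x_nm, p$y_nm)))
    diag(d) <- Inf
    apply(d, 1, min)
  }
  seam <- nn_gap(mclip, 7600, 8400)
  interior <- nn_gap(mclip, 3000, 3800)
  expect_gt(stats::wilcox.test(seam, interior)$p.value, 0.05)

  one <- merge_mosaic(tiles["A"],
                      solve_layout(data.frame(fov_i = "A", fov_j = "A",
                                              dx_nm = 0, dy_nm = 0,
                                              dz_nm = 0, confidence = Inf,
                                              source = "auto")))
  expect_equal(one$x_nm, tiles$A$x_nm)
  expect_error(merge_mosaic(tiles, solve_layout(
    data.frame(fov_i = "A", fov_j = "A", dx_nm = 0, dy_nm = 0, dz_nm = 0,
               confidence = Inf, source = "auto"))), "no entry")
})
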