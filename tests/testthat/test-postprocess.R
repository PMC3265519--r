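# Drift correction, color coding, crosstalk estimation and subtraction.

test_that("a zero drift trace leaves the table untouched", {
  tab <- make_loc_table(frame = 1:100, x = runif(100, 0, 3000),
                        y = runif(100, 0, 3000), n_frames = 100)
  tr <- drift_trace(data.frame(bin_start = c(1, 51), bin_end = c(50, 100),
                               dx_nm = 0, dy_nm = 0))
  out <- apply_drift(tab, tr)
  expect_identical(out$x_nm, tab$x_nm)
  expect_identical(out$y_nm, tab$y_nm)
})

test_that("drift interpolation is exact at bin centers and clamps at ends", {
  tab <- make_loc_table(frame = c(25, 75, 125, 1, 149), x = rep(1000, 5),
                        y = rep(1000, 5), n_frames = 149)
  tr <- drift_trace(data.frame(bin_start = c(1, 51, 101),
                               bin_end = c(49, 99, 149),
                               dx_nm = c(0, 10, 30), dy_nm = c(0, -5, -15)))
  out <- apply_drift(tab, tr)
  expect_equal(out$x_nm[1:3], 1000 - c(0, 10, 30))   # bin centers 25/75/125
  expect_equal(out$x_nm[4], 1000)                    # clamped before first
  expect_equal(out$x_nm[5], 1000 - 30)               # clamped after last
  expect_error(apply_drift(make_loc_table(200, 0, 0, n_frames = 200), tr),
               "cover")
})

test_that("drift correction never changes counts, photons or z", {
  tab <- make_loc_table(frame = 1:200, x = runif(200, 0, 2000),
                        y = runif(200, 0, 2000), z = runif(200, -100, 100),
                        photons = rpois(200, 4000), n_frames = 200)
  tr <- drift_trace(data.frame(bin_start = c(1, 101), bin_end = c(100, 200),
                               dx_nm = c(0, 40), dy_nm = c(0, -20)))
  out <- apply_drift(tab, tr)
  expect_equal(nrow(out), nrow(tab))
  expect_identical(out$photons, tab$photons)
  expect_identical(out$z_nm, tab$z_nm)
})

sim_drift_table <- function(drift_total = 100, n_frames = 10000, seed = 20) {
  spec <- structure_spec("tube", tube_radius = 40,
                         axis = rbind(c(500, 1500, 0), c(7500, 2500, 0)),
                         label_density = 800)
  em <- make_structure(spec, seed = seed)
  set.seed(seed + 1)
  n <- nrow(em) * 6
  i <- rep(seq_len(nrow(em)), 6)
  fr <- sample.int(n_frames, n, replace = TRUE)
  tab <- make_loc_table(frame = fr,
                        x = em$x_nm[i] + rnorm(n, 0, 8) +
                          drift_total * (fr - 1) / (n_frames - 1),
                        y = em$y_nm[i] + rnorm(n, 0, 8),
                        n_frames = n_frames)
  tab
}

test_that("injected linear drift is recovered bin by bin", {
  tab <- sim_drift_table(drift_total = 100)
  suppressWarnings(
    tr <- estimate_drift(tab, bin_frames = 1000, render_pixel = 25,
                         min_per_bin = 100))
  true_rel <- 100 * (tr$frame_center - tr$frame_center[1]) / 9999
  expect_lt(max(abs(tr$dx_nm - true_rel)), 12.5)     # half a render pixel
  expect_lt(max(abs(tr$dy_nm)), 12.5)
  expect_equal(tr$dx_nm[1], 0)                        # reference bin

  # fixed point: correcting then re-estimating leaves < half-pixel residuals
  corrected <- apply_drift(tab, tr)
  suppressWarnings(
    tr2 <- estimate_drift(corrected, bin_frames = 1000, render_pixel = 25,
                          min_per_bin = 100))
  expect_lt(max(abs(tr2$dx_nm)), 12.5)
  expect_lt(max(abs(tr2$dy_nm)), 12.5)
})

test_that("a drift-free movie yields sub-pixel offsets everywhere", {
  tab <- sim_drift_table(drift_total = 0, seed = 22)
  suppressWarnings(
    tr <- estimate_drift(tab, bin_frames = 1000, render_pixel = 25,
                         min_per_bin = 100))
  expect_lt(max(abs(tr$dx_nm)), 12.5)
  expect_lt(max(abs(tr$dy_nm)), 12.5)
})

test_that("color assignment follows the schedule and is a pure function of
           frame index", {
  sch <- activation_schedule()
  tab <- make_loc_table(frame = c(2, 4, 6, 3), x = 1:4, y = 1:4,
                        n_frames = 8)
  out <- assign_colors(tab, sch)
  expect_equal(out$channel, c("ch405", "nonspecific", "ch405",
                              "nonspecific"))
  empty <- assign_colors(tab[0, ], sch)
  expect_equal(nrow(empty), 0)

  # property: over random schedules the channel depends only on frame %% cycle
  set.seed(23)
  for (k in 1:5) {
    roles <- sample(c("imaging", "activation:ch405", "activation:ch457"),
                    sample(4:8, 1), replace = TRUE)
    if (!any(roles == "imaging")) roles[1] <- "imaging"
    schk <- activation_schedule(roles)
    L <- length(roles)
    n_frames <- 6 * L
    fr <- seq_len(n_frames)
    got <- assign_colors(make_loc_table(fr, fr, fr, n_frames = n_frames),
                         schk)$channel
    # independent recomputation from the cycle definition
    want <- vapply(fr, function(f) {
      if (f == 1) return("nonspecific")
      cur <- roles[((f - 1) %% L) + 1]
      prev <- roles[((f - 2) %% L) + 1]
      if (cur == "imaging" && prev != "imaging")
        sub("activation:", "", prev) else "nonspecific"
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("crosstalk estimate implements the stated subtraction arithmetic", {
  set.seed(30)
  sch <- activation_schedule()     # act, img, img, img
  n_cycles <- 100
  n_frames <- 4 * n_cycles
  # 120 localizations spread over the post-activation frame positions and 20
  # over each of the two other imaging frame positions
  fr <- c(sample(seq(2, n_frames, by = 4), 120, replace = TRUE),
          sample(seq(3, n_frames, by = 4), 20, replace = TRUE),
          sample(seq(4, n_frames, by = 4), 20, replace = TRUE))
  tab <- assign_colors(make_loc_table(fr, seq_along(fr), seq_along(fr),
                                      n_frames = n_frames), sch)
  est <- estimate_crosstalk(tab)
  expect_equal(est$apparent, 120)
  # nonspecific rate = 40 events / 200 other imaging frames = 0.2 per frame;
  # expected contamination of the 100 post-activation frames = 20
  expect_equal(attr(est, "nonspecific_rate"), 0.2)
  expect_equal(est$actual, 100)
})

test_that("crosstalk estimate limits: clean and purely nonspecific tables", {
  sch <- activation_schedule()
  clean <- assign_colors(make_loc_table(seq(2, 400, by = 4), 1:100, 1:100,
                                        n_frames = 400), sch)
  est <- estimate_crosstalk(clean)
  expect_equal(est$actual, est$apparent)

  flat_fr <- c(seq(2, 400, by = 4), seq(3, 400, by = 4), seq(4, 400, by = 4))
  flat <- assign_colors(make_loc_table(flat_fr, seq_along(flat_fr),
                                       seq_along(flat_fr), n_frames = 400),
                        sch)
  expect_equal(estimate_crosstalk(flat)$actual, 0)

  all_post <- activation_schedule(c("activation:ch405", "imaging"))
  tab <- assign_colors(make_loc_table(c(2, 4), 1:2, 1:2, n_frames = 4),
                       all_post)
  expect_error(estimate_crosstalk(tab), "cannot be estimated")
})

test_that("crosstalk subtraction is seeded, deterministic and count-unbiased", {
  sch <- activation_schedule()
  n_frames <- 8000
  em <- data.frame(emitter_id = 1:300, x_nm = runif(300, 0, 4000),
                   y_nm = runif(300, 0, 4000), z_nm = 0, channel = "ch405",
                   structure_id = 1L)
  bl <- blink_model(mean_localizations_per_label = 4,
                    nonspecific_rate = 4 / (0.75 * n_frames))
  ev <- schedule_blinking(em, sch, bl, n_frames, seed = 24)
  tab <- assign_colors(events_to_table(ev, em, n_frames = n_frames), sch)
  est <- estimate_crosstalk(tab)
  out1 <- subtract_crosstalk(tab, est, seed = 7)
  out2 <- subtract_crosstalk(tab, est, seed = 7)
  expect_identical(out1$x_nm, out2$x_nm)

  true_specific <- sum(ev$origin == "specific")
  post <- sum(out1$channel == "ch405")
  expect_lt(abs(post - true_specific) / true_specific, 0.05)

  # zero estimate leaves the table unchanged
  zero <- est
  zero$expected_nonspecific <- 0
  out0 <- subtract_crosstalk(tab, zero, seed = 7)
  expect_equal(nrow(out0), nrow(tab))

  # impossible removals remove everything with a warning
  huge <- est
  huge$expected_nonspecific <- 1e6
  expect_warning(outh <- subtract_crosstalk(tab, huge, seed = 7), "exceed")
  expect_equal(sum(outh$channel == "ch405"), 0)
})
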