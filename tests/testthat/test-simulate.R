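# Synthetic-data generator: structures, blinking schedules, frame rendering.

test_that("membrane label counts follow the Poisson surface process", {
  spec <- structure_spec("tube", tube_radius = 75,
                         axis = rbind(c(0, 0, 0), c(10000, 0, 0)),
                         label_density = 2500)
  lambda <- 2 * pi * 0.075 * 10 * 2500       # cylinder area x density
  n <- nrow(make_structure(spec, seed = 1))
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))

  empty <- make_structure(structure_spec("tube", tube_radius = 75,
                                         axis = rbind(c(0, 0, 0),
                                                      c(10000, 0, 0)),
                                         label_density = 0), seed = 1)
  expect_equal(nrow(empty), 0)

  # all emitters sit on the membrane shell, not in the volume
  em <- make_structure(spec, seed = 2)
  r <- sqrt(em$y_nm^2 + em$z_nm^2)
  expect_lt(max(abs(r - 75)), 1e-6)
})

test_that("degenerate geometry is rejected with a diagnostic", {
  bad <- structure_spec("tube", tube_radius = 75,
                        axis = rbind(c(1, 2, 3), c(1, 2, 3)),
                        label_density = 100)
  expect_error(make_structure(bad, seed = 1), "degenerate polyline")
  expect_error(structure_spec("tube", tube_radius = -1), "tube_radius")
  expect_error(structure_spec("tube", label_density = -5), "label_density")
})

test_that("x-junction tubes are separated axially by the requested distance", {
  spec <- structure_spec("x_junction", tube_radius = 25, z_separation = 300,
                         axis = c(0, 0, 0), label_density = 500,
                         arm_length = 1500)
  em <- make_structure(spec, seed = 3)
  lo <- em$z_nm[em$z_nm < 0]
  hi <- em$z_nm[em$z_nm > 0]
  # shell means coincide with the two tube axes at -150 and +150 nm
  expect_equal(mean(lo), -150, tolerance = 5)
  expect_equal(mean(hi), 150, tolerance = 5)
  expect_lt(max(abs(abs(em$z_nm) - 150)), 25 + 1e-6)
})

test_that("blinking produces the configured mean events per label", {
  em <- data.frame(emitter_id = 1:2000,
                   x_nm = runif(2000, 0, 5000), y_nm = runif(2000, 0, 5000),
                   z_nm = 0, channel = "ch405", structure_id = 1L)
  sch <- activation_schedule()
  bl <- blink_model(mean_localizations_per_label = 4)
  ev <- schedule_blinking(em, sch, bl, n_frames = 40000, seed = 4)
  per_label <- nrow(ev) / nrow(em)
  se <- sqrt(4 / nrow(em))          # near-Poisson counting error
  expect_lt(abs(per_label - 4), 4 * se)
})

test_that("event timing follows the activation schedule exactly", {
  em <- data.frame(emitter_id = 1:50, x_nm = 0, y_nm = 0, z_nm = 0,
                   channel = "ch405", structure_id = 1L)
  sch <- activation_schedule()   # act405, img, img, img
  bl <- blink_model(mean_localizations_per_label = 10)
  ev <- schedule_blinking(em, sch, bl, n_frames = 4000, seed = 5)
  # with zero nonspecific and cross rates every event is in the imaging frame
  # immediately after its own channel's activation frame
  expect_true(all(ev$frame %% 4 == 2))
  expect_true(all(ev$origin == "specific"))

  off <- blink_model(specific_activation_prob = 0, nonspecific_rate = 0)
  expect_equal(nrow(schedule_blinking(em, sch, off, 4000, seed = 5)), 0)
  expect_equal(nrow(schedule_blinking(em[0, ], sch, bl, 4000, seed = 5)), 0)
})

test_that("nonspecific events are uniform over imaging frames", {
  em <- data.frame(emitter_id = 1:400, x_nm = 0, y_nm = 0, z_nm = 0,
                   channel = "ch405", structure_id = 1L)
  sch <- activation_schedule()
  bl <- blink_model(specific_activation_prob = 0, nonspecific_rate = 5e-3)
  ev <- schedule_blinking(em, sch, bl, n_frames = 8000, seed = 6)
  expect_true(all(ev$origin == "nonspecific"))
  roles <- ev$frame %% 4       # 1 = activation frame slot
  expect_true(all(roles != 1))
  counts <- table(factor(roles, levels = c(2, 3, 0)))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("multicolor cycles route events to their own activator slots", {
  em <- data.frame(emitter_id = 1:60, x_nm = 0, y_nm = 0, z_nm = 0,
                   channel = rep(c("ch405", "ch457", "ch532"), each = 20),
                   structure_id = 1L)
  sch <- multicolor_schedule()       # (2 act + 3 img) x 3 channels
  bl <- blink_model(mean_localizations_per_label = 6)
  ev <- schedule_blinking(em, sch, bl, n_frames = 6000, seed = 7)
  slot <- ev$frame %% 15
  ch <- em$channel[match(ev$emitter_id, em$emitter_id)]
  expect_true(all(slot[ch == "ch405"] == 3))
  expect_true(all(slot[ch == "ch457"] == 8))
  expect_true(all(slot[ch == "ch532"] == 13))
})

test_that("a rendered spot conserves photons in the noiseless limit", {
  em <- data.frame(emitter_id = 1L, x_nm = 1650, y_nm = 1700, z_nm = 0,
                   channel = "ch405", structure_id = 1L)
  ev <- data.frame(emitter_id = 1L, frame = 1L, photons = 7500,
                   activating_laser = "ch405", origin = "specific")
  geo <- stack_geometry(width_px = 20, height_px = 20, n_frames = 1)
  cam <- camera_model(offset = 50, read_noise = 0, shot_noise = FALSE)
  st <- render_frames(ev, em, test_calibration(), cam, geo)
  signal <- sum(st$frames[, , 1]) - 50 * 20 * 20
  expect_lt(abs(signal - 7500) / 7500, 0.005)

  blank <- render_frames(ev[0, ], em, test_calibration(), cam, geo)
  expect_equal(max(abs(blank$frames - 50)), 0)
})

test_that("events outside the detectable z-range are dropped silently", {
  em <- data.frame(emitter_id = 1:2, x_nm = c(1000, 2200), y_nm = 1600,
                   z_nm = c(0, 900), channel = "ch405", structure_id = 1L)
  ev <- data.frame(emitter_id = 1:2, frame = 1L, photons = 5000,
                   activating_laser = "ch405", origin = "specific")
  geo <- stack_geometry(width_px = 20, height_px = 20, n_frames = 1)
  cam <- camera_model(offset = 0, read_noise = 0, shot_noise = FALSE)
  st <- render_frames(ev, em, test_calibration(), cam, geo)
  expect_lt(abs(sum(st$frames) - 5000) / 5000, 0.005)
  expect_error(camera_model(gain = -1), "gain")
  expect_error(camera_model(read_noise = -2), "read noise")
})

test_that("label density is recovered from perfectly localized emitters", {
  spec <- structure_spec("tube", tube_radius = 50,
                         axis = rbind(c(0, 0, 0), c(20000, 0, 0)),
                         label_density = 1500)
  em <- make_structure(spec, seed = 8)
  tab <- make_loc_table(frame = seq_len(nrow(em)), x = em$x_nm, y = em$y_nm,
                        z = em$z_nm)
  edges <- seq(1000, 19000, length.out = 21)       # 20 interior regions
  regs <- data.frame(xmin = edges[-21], xmax = edges[-1],
                     ymin = -60, ymax = 60,
                     measure_um = 2 * pi * 0.05 * diff(edges) / 1000)
  dd <- label_density(tab, regs, d = 2, n_locs_per_label = 1)
  se <- dd$sd / sqrt(dd$n_regions)
  expect_lt(abs(dd$mean - 1500), 3 * se)
})

test_that("frame stacks survive a TIFF round trip", {
  em <- data.frame(emitter_id = 1L, x_nm = 1600, y_nm = 1600, z_nm = 0,
                   channel = "ch405", structure_id = 1L)
  ev <- data.frame(emitter_id = 1L, frame = 2L, photons = 3000,
                   activating_laser = "ch405", origin = "specific")
  geo <- stack_geometry(width_px = 16, height_px = 16, n_frames = 3,
                        fov_id = 7L, pass_id = 2L)
  st <- render_frames(ev, em, 160, camera_model(), geo,
                      schedule = activation_schedule(), seed = 9)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(st, path, seed = 9)
  back <- read_frame_stack(path)
  expect_equal(back$frames, round(st$frames), tolerance = 1e-6)
  expect_equal(back$pixel_nm, st$pixel_nm)
  expect_equal(back$fov_id, 7L)
  expect_equal(back$schedule$cycle, activation_schedule()$cycle)
})
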