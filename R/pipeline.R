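# End-to-end orchestration with reproducible configuration and manifests.

#' Simulate a movie and localize it in one streaming pass
#'
#' Renders frames in chunks and localizes each chunk immediately, so long
#' movies never need to be held in memory. Identical inputs and seed yield
#' identical tables.
#'
#' @param emitters emitter data.frame.
#' @param schedule an [activation_schedule()].
#' @param blink a [blink_model()].
#' @param geometry a [stack_geometry()].
#' @param psf a `storm_calibration` or numeric PSF sigma(s), nm.
#' @param camera a [camera_model()].
#' @param cal calibration used for analysis (defaults to `psf` when that is a
#'   calibration).
#' @param params [localize_params()].
#' @param mode `"2d"` or `"3d"`.
#' @param drift optional [drift_trace()] or function injected into rendering.
#' @param chunk frames per chunk.
#' @param seed RNG seed governing blinking and noise.
#' @return localization table; the simulated events are attached as the
#'   `"events"` attribute for ground-truth comparisons.
#' @export
sim_localize <- function(emitters, schedule, blink, geometry, psf,
                         camera = camera_model(), cal = NULL,
                         params = localize_params(), mode = "2d",
                         drift = NULL, chunk = 2000L, seed = 1L) {
  if (is.null(cal) && inherits(psf, "storm_calibration")) cal <- psf
  events <- schedule_blinking(emitters, schedule, blink, geometry$n_frames,
                              seed = seed)
  tabs <- list()
  rej <- NULL
  starts <- seq(1L, geometry$n_frames, by = chunk)
  for (k in seq_along(starts)) {
    f0 <- starts[k]
    f1 <- min(f0 + chunk - 1L, geometry$n_frames)
    stack <- render_frames(events, emitters, psf, camera, geometry,
                           drift = drift, schedule = schedule,
                           frame_range = c(f0, f1), seed = seed + k)
    tab <- localize_movie(stack, cal = cal, params = params, mode = mode)
    r <- attr(tab, "rejections")
    rej <- if (is.null(rej)) r else rej + r
    if (nrow(tab)) tabs[[length(tabs) + 1L]] <- as.data.frame(tab)
  }
  out <- if (length(tabs)) do.call(rbind, tabs) else
    localize_movie(render_frames(events[0, ], emitters, psf, camera, geometry,
                                 frame_range = c(1L, 1L)),
                   cal = cal, params = params, mode = mode)[0, ]
  rownames(out) <- NULL
  attr(out, "pixel_nm") <- geometry$pixel_nm
  attr(out, "n_frames") <- geometry$n_frames
  attr(out, "schedule") <- schedule
  attr(out, "focal_z") <- geometry$focal_z
  attr(out, "origin_nm") <- geometry$origin_nm
  attr(out, "rejections") <- rej
  attr(out, "events") <- events
  out
}

#' Pipeline configuration
#'
#' A single serializable list of per-stage parameters; every run writes the
#' resolved configuration and a manifest beside its outputs.
#'
#' @param simulate list: `structures` (list of [structure_spec()]), `channels`
#'   per structure, `cycle`, `blink` parameters, `geometry` parameters,
#'   `camera` parameters, `psf` (calibration parameters for
#'   [astig_calibration()], or a sigma).
#' @param localize list: [localize_params()] arguments plus `mode`.
#' @param drift list: `bin_frames`, `render_pixel`, or `NULL` to skip.
#' @param crosstalk list: `cross_fractions`, or `NULL` to skip.
#' @param resolution list: `d`, `n_locs_per_label`, `regions`.
#' @param render list: `pitch`, `width_mode`, or `NULL` to skip.
#' @param seed master seed.
#' @param out_dir output directory.
#' @export
pipeline_config <- function(simulate = list(), localize = list(),
                            drift = NULL, crosstalk = NULL,
                            resolution = NULL, render = NULL,
                            seed = 1L, out_dir = tempfile("storm_run_")) {
  structure(list(simulate = simulate, localize = localize, drift = drift,
                 crosstalk = crosstalk, resolution = resolution,
                 render = render, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the pipeline end-to-end
#'
#' Executes the configured stages in order - simulate+localize, drift
#' correction, color assignment, crosstalk subtraction, resolution report,
#' rendering - writing molecule lists, reports and a manifest (stage counts,
#' seeds, configuration) to the output directory. A failing stage halts the
#' run with the stage named; outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return list with the final `table`, the per-stage `counts`, the
#'   `resolution` report (if configured) and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("stormtrace")), seed = config$seed, counts = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  sim <- config$simulate
  mode <- config$localize$mode %||% "2d"
  psf <- stage("simulate", {
    if (is.numeric(sim$psf %||% 160)) sim$psf %||% 160
    else do.call(astig_calibration, sim$psf)
  })
  if (mode == "3d" && !inherits(psf, "storm_calibration"))
    stop("pipeline stage 'localize': 3D mode requires a calibration ",
         "(simulate$psf must be calibration parameters)", call. = FALSE)

  as_spec <- function(s) {
    if (inherits(s, "structure_spec")) return(s)
    if (!is.null(s$axis) && is.list(s$axis))
      s$axis <- if (all(lengths(s$axis) > 1))
        do.call(rbind, lapply(s$axis, unlist)) else unlist(s$axis)
    do.call(structure_spec, s)
  }
  tab <- stage("simulate+localize", {
    specs <- lapply(sim$structures, as_spec)
    emitters <- do.call(combine_emitters, c(
      lapply(seq_along(specs), function(i)
        make_structure(specs[[i]], seed = config$seed + i)),
      list(channels = sim$channels %||% "ch405")))
    schedule <- activation_schedule(
      sim$cycle %||% c("activation:ch405", "imaging", "imaging", "imaging"))
    blink <- do.call(blink_model, sim$blink %||% list())
    geometry <- do.call(stack_geometry, sim$geometry %||% list())
    camera <- do.call(camera_model, sim$camera %||% list())
    lp_args <- config$localize
    lp_args$mode <- NULL
    params <- do.call(localize_params, lp_args)
    sim_localize(emitters, schedule, blink, geometry, psf,
                 camera = camera, params = params, mode = mode,
                 drift = sim$drift, seed = config$seed)
  })
  manifest$counts$localized <- nrow(tab)
  manifest$rejections <- as.list(attr(tab, "rejections"))
  write_molecule_list(tab, file.path(config$out_dir, "localizations.csv"))

  if (!is.null(config$drift)) {
    trace <- stage("drift", do.call(estimate_drift,
                                    c(list(table = tab), config$drift)))
    tab <- stage("drift", apply_drift(tab, trace))
    utils::write.csv(as.data.frame(trace)[, c("bin_start", "bin_end", "dx_nm",
                                              "dy_nm")],
                     file.path(config$out_dir, "drift.csv"),
                     row.names = FALSE)
  }

  tab <- stage("colors", assign_colors(tab, attr(tab, "schedule")))
  manifest$counts$nonspecific <- sum(tab$channel == "nonspecific")

  if (!is.null(config$crosstalk)) {
    est <- stage("crosstalk", estimate_crosstalk(tab))
    tab <- stage("crosstalk", subtract_crosstalk(
      tab, est, cross_fractions = config$crosstalk$cross_fractions,
      seed = config$seed))
    yaml::write_yaml(list(
      estimate = as.list(as.data.frame(est)),
      report = lapply(attr(tab, "crosstalk_report")$channels, as.vector)),
      file.path(config$out_dir, "crosstalk.yaml"))
  }
  manifest$counts$final <- nrow(tab)
  write_molecule_list(tab, file.path(config$out_dir, "molecules.csv"))

  res <- NULL
  if (!is.null(config$resolution)) {
    res <- stage("resolution", {
      r <- config$resolution
      dens <- label_density(tab, r$regions, d = r$d %||% 2,
                            n_locs_per_label = r$n_locs_per_label %||% 4)
      resolution_report(dens$mean, d = r$d %||% 2,
                        precision_xy = r$precision_xy,
                        precision_z = r$precision_z %||% NA,
                        n_locs_per_label = r$n_locs_per_label %||% 4)
    })
    yaml::write_yaml(unclass(res),
                     file.path(config$out_dir, "resolution.yaml"))
  }

  if (!is.null(config$render)) {
    img <- stage("render", render_storm(
      tab, pitch = config$render$pitch %||% 10,
      mode = config$render$mode %||% "2d",
      width_mode = config$render$width_mode %||% "theoretical"))
    write_storm_image(img, file.path(config$out_dir, "render.tif"))
  }

  cfg <- rapply(unclass(config), function(x)
    if (inherits(x, "structure_spec")) unclass(x) else x, how = "replace")
  yaml::write_yaml(cfg, file.path(config$out_dir, "config.yaml"))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  list(table = tab, counts = manifest$counts, resolution = res,
       out_dir = config$out_dir)
}
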