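# Activation schedules and stochastic blinking of labels.
#
# STORM acquisition interleaves activation frames (a short-wavelength pulse
# reactivates a sparse subset of reporters) with imaging frames in a fixed
# repeating cycle. A label activated by its own activator appears in the first
# imaging frame after that activator's pulse; nonspecific activations by the
# imaging laser appear uniformly across imaging frames; wrong-laser activations
# appear after another channel's pulse.

#' Define an activation/imaging frame cycle
#'
#' @param cycle character vector of frame roles, each `"imaging"` or
#'   `"activation:<channel>"`, e.g.
#'   `c("activation:ch405", "imaging", "imaging", "imaging")`.
#' @param frame_rate acquisition frame rate, Hz.
#' @return An `activation_schedule`.
#' @export
activation_schedule <- function(cycle = c("activation:ch405", "imaging",
                                          "imaging", "imaging"),
                                frame_rate = 60) {
  if (!length(cycle)) stop("cycle must be non-empty")
  ok <- cycle == "imaging" | grepl("^activation:.+$", cycle)
  if (!all(ok)) stop("cycle roles must be 'imaging' or 'activation:<channel>'")
  stopifnot_scalar(frame_rate, "frame_rate", positive = TRUE)
  chans <- unique(sub("^activation:", "", cycle[cycle != "imaging"]))
  structure(list(cycle = cycle, frame_rate = frame_rate, channels = chans),
            class = "activation_schedule")
}

#' Standard three-color activation cycle
#'
#' Two activation frames followed by three imaging frames per activator
#' (405 nm, 457 nm, 532 nm), the multicolor pattern used with
#' activator-reporter dye pairs.
#' @param channels activator channel names.
#' @param frame_rate Hz.
#' @export
multicolor_schedule <- function(channels = c("ch405", "ch457", "ch532"),
                                frame_rate = 60) {
  cycle <- unlist(lapply(channels, function(ch)
    c(rep(paste0("activation:", ch), 2), rep("imaging", 3))))
  activation_schedule(cycle, frame_rate)
}

# Role of each frame 1..n under the repeating cycle.
frame_roles <- function(schedule, n_frames) {
  schedule$cycle[((seq_len(n_frames) - 1L) %% length(schedule$cycle)) + 1L]
}

# For each frame, the channel whose activation pulse immediately precedes it
# (only imaging frames directly after an activation frame qualify); NA else.
post_activation_channel <- function(schedule, n_frames) {
  roles <- frame_roles(schedule, n_frames)
  out <- rep(NA_character_, n_frames)
  if (n_frames < 2) return(out)
  prev <- roles[-n_frames]
  cur <- roles[-1]
  hit <- which(cur == "imaging" & prev != "imaging") + 1L
  out[hit] <- sub("^activation:", "", roles[hit - 1L])
  out
}

#' Define the stochastic blinking model of a label
#'
#' @param mean_localizations_per_label mean number of switching events each
#'   label contributes over the whole movie (the divisor `n` of the label
#'   density calculus; default 4). Used to derive the per-cycle activation
#'   probability when `specific_activation_prob` is `NULL`.
#' @param specific_activation_prob probability that a label turns on in the
#'   imaging frame right after its own activator's pulse, per cycle. `NULL`
#'   (default) derives it from `mean_localizations_per_label` and movie length.
#' @param nonspecific_rate per-label, per-imaging-frame probability of a
#'   nonspecific (imaging-laser-induced) activation.
#' @param cross_activation named list like `list("ch457" = c(ch532 = 0.01))`:
#'   probability per cycle that a label of the named channel is falsely
#'   activated by the listed activator's pulse.
#' @param photons_mean mean photons detected per switching event.
#' @return A `blink_model`.
#' @export
blink_model <- function(mean_localizations_per_label = 4,
                        specific_activation_prob = NULL,
                        nonspecific_rate = 0,
                        cross_activation = list(),
                        photons_mean = 5000) {
  stopifnot_scalar(mean_localizations_per_label, "mean_localizations_per_label",
                   positive = TRUE)
  stopifnot_scalar(photons_mean, "photons_mean", positive = TRUE)
  if (nonspecific_rate < 0 || nonspecific_rate > 1)
    stop("nonspecific_rate must be in [0, 1]")
  if (!is.null(specific_activation_prob) &&
      (specific_activation_prob < 0 || specific_activation_prob > 1))
    stop("specific_activation_prob must be in [0, 1]")
  structure(list(mean_localizations_per_label = mean_localizations_per_label,
                 specific_activation_prob = specific_activation_prob,
                 nonspecific_rate = nonspecific_rate,
                 cross_activation = cross_activation,
                 photons_mean = photons_mean),
            class = "blink_model")
}

draw_photons <- function(n, mean) {
  # Gamma-distributed event brightness (shape 4): broad but strictly positive,
  # a reasonable stand-in for switching-event photon yields.
  stats::rgamma(n, shape = 4, rate = 4 / mean)
}

#' Simulate switching events for a set of labels
#'
#' Specific events are placed in the imaging frame immediately following the
#' emitter's own activator pulse; wrong-laser events after another channel's
#' pulse; nonspecific events uniformly over all imaging frames. Every event of
#' a label occurs at the label's true position (localization scatter arises
#' later from photon-limited fitting).
#'
#' @param emitters emitter data.frame from [make_structure()] /
#'   [combine_emitters()].
#' @param schedule an [activation_schedule()].
#' @param blink a [blink_model()].
#' @param n_frames movie length in frames (>= one full cycle).
#' @param seed RNG seed.
#' @return data.frame with columns `emitter_id`, `frame`, `photons`,
#'   `activating_laser` (`"imaging"` for nonspecific events), `origin`
#'   (`"specific"`, `"nonspecific"`, `"cross"`).
#' @export
schedule_blinking <- function(emitters, schedule, blink, n_frames,
                              seed = NULL) {
  stopifnot(inherits(schedule, "activation_schedule"),
            inherits(blink, "blink_model"))
  if (n_frames < length(schedule$cycle))
    stop("n_frames must cover at least one full cycle")
  empty <- data.frame(emitter_id = integer(0), frame = integer(0),
                      photons = numeric(0), activating_laser = character(0),
                      origin = character(0))
  if (!nrow(emitters)) return(empty)

  post_ch <- post_activation_channel(schedule, n_frames)
  roles <- frame_roles(schedule, n_frames)
  imaging_frames <- which(roles == "imaging")

  with_seed(seed, {
    out <- list()
    for (ch in unique(emitters$channel)) {
      ids <- emitters$emitter_id[emitters$channel == ch]
      slots <- which(post_ch == ch)       # candidate frames for specific events
      if (length(slots)) {
        p <- blink$specific_activation_prob
        if (is.null(p))
          p <- min(1, blink$mean_localizations_per_label / length(slots))
        n_ev <- stats::rbinom(length(ids), length(slots), p)
        tot <- sum(n_ev)
        if (tot > 0) {
          fr <- unlist(lapply(n_ev[n_ev > 0], function(k)
            slots[sample.int(length(slots), k)]), use.names = FALSE)
          out[[length(out) + 1L]] <- data.frame(
            emitter_id = rep(ids[n_ev > 0], n_ev[n_ev > 0]), frame = fr,
            photons = draw_photons(tot, blink$photons_mean),
            activating_laser = ch, origin = "specific")
        }
      }
      # wrong-laser (cross) activations of this channel's labels
      for (laser in names(blink$cross_activation)) {
        rates <- blink$cross_activation[[laser]]
        if (is.null(rates[[ch]]) || rates[[ch]] <= 0) next
        lslots <- which(post_ch == laser)
        if (!length(lslots)) next
        n_ev <- stats::rbinom(length(ids), length(lslots), rates[[ch]])
        tot <- sum(n_ev)
        if (tot > 0) {
          fr <- unlist(lapply(n_ev[n_ev > 0], function(k)
            lslots[sample.int(length(lslots), k)]), use.names = FALSE)
          out[[length(out) + 1L]] <- data.frame(
            emitter_id = rep(ids[n_ev > 0], n_ev[n_ev > 0]), frame = fr,
            photons = draw_photons(tot, blink$photons_mean),
            activating_laser = laser, origin = "cross")
        }
      }
    }
    # nonspecific activations: uniform over imaging frames, all labels
    if (blink$nonspecific_rate > 0 && length(imaging_frames)) {
      n_ev <- stats::rbinom(nrow(emitters), length(imaging_frames),
                            blink$nonspecific_rate)
      tot <- sum(n_ev)
      if (tot > 0) {
        fr <- unlist(lapply(n_ev[n_ev > 0], function(k)
          imaging_frames[sample.int(length(imaging_frames), k)]),
          use.names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          emitter_id = rep(emitters$emitter_id[n_ev > 0], n_ev[n_ev > 0]),
          frame = fr, photons = draw_photons(tot, blink$photons_mean),
          activating_laser = "imaging", origin = "nonspecific")
      }
    }
    if (!length(out)) return(empty)
    ev <- do.call(rbind, out)
    ev <- ev[order(ev$frame, ev$emitter_id), ]
    rownames(ev) <- NULL
    ev
  })
}
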