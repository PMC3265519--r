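# Activation-frame color coding and statistical crosstalk subtraction.
#
# With activator-reporter dye pairs, the color of a switching event is encoded
# by which activation pulse immediately preceded it. Events in any other
# imaging frame are "non-specific" (imaging-laser induced). Because
# nonspecific activations occur at a constant per-frame rate, their expected
# contamination of the post-activation frames can be estimated from the other
# imaging frames and removed statistically.

#' Color-code localizations by activation frame
#'
#' A localization in the first imaging frame after an activation pulse gets
#' that activator's channel; localizations in all other frames are coded
#' `"nonspecific"`.
#'
#' @param table localization table.
#' @param schedule the movie's [activation_schedule()].
#' @return table with the `channel` column set (metadata preserved).
#' @export
assign_colors <- function(table, schedule) {
  stopifnot(inherits(schedule, "activation_schedule"))
  n_frames <- attr(table, "n_frames") %||%
    (if (nrow(table)) max(table$frame) else 0L)
  if (n_frames < length(schedule$cycle))
    stop("schedule cycle is longer than the movie")
  if (nrow(table) && max(table$frame) > n_frames)
    stop("table frames exceed the movie length")
  out <- table
  if (nrow(table)) {
    post <- post_activation_channel(schedule, n_frames)
    ch <- post[table$frame]
    ch[is.na(ch)] <- "nonspecific"
    out$channel <- ch
  }
  out <- copy_table_meta(out, table)
  attr(out, "schedule") <- schedule
  out
}

#' Estimate specific and nonspecific activation counts
#'
#' Per channel, the "apparent specific" count is the number of localizations
#' in the imaging frames immediately following that channel's activation
#' pulse. The nonspecific rate is the mean count per frame over the remaining
#' imaging frames; assuming it is constant across all frames, the "actual
#' specific" count is the apparent count minus the expected nonspecific
#' contamination of the post-activation frames (floored at zero).
#'
#' @param table localization table with colors assigned.
#' @param schedule the [activation_schedule()] (defaults to the table's).
#' @return A `crosstalk_estimate`: data.frame with one row per channel
#'   (`channel`, `apparent`, `n_post_frames`, `expected_nonspecific`,
#'   `actual`), with the per-frame `nonspecific_rate` as an attribute.
#' @export
estimate_crosstalk <- function(table, schedule = attr(table, "schedule")) {
  stopifnot(inherits(schedule, "activation_schedule"))
  if (all(table$channel == "unassigned"))
    stop("assign colors before estimating crosstalk")
  n_frames <- attr(table, "n_frames") %||% max(table$frame)
  post <- post_activation_channel(schedule, n_frames)
  roles <- frame_roles(schedule, n_frames)
  other <- which(roles == "imaging" & is.na(post))
  if (!length(other))
    stop("cycle has no imaging frames outside the post-activation slots; ",
         "the nonspecific rate cannot be estimated")
  rate <- sum(table$frame %in% other) / length(other)
  rows <- lapply(schedule$channels, function(ch) {
    slots <- which(post == ch)
    apparent <- sum(table$channel == ch)
    expected <- rate * length(slots)
    data.frame(channel = ch, apparent = apparent,
               n_post_frames = length(slots),
               expected_nonspecific = expected,
               actual = max(0, apparent - expected))
  })
  structure(do.call(rbind, rows), nonspecific_rate = rate,
            class = c("crosstalk_estimate", "data.frame"))
}

#' Statistically subtract crosstalk from color-coded localizations
#'
#' Within each channel, removes the expected number of crosstalk
#' localizations - the nonspecific contamination estimated by
#' [estimate_crosstalk()], plus an optional wrong-laser contribution - by
#' seeded uniform random thinning of that channel's localizations. The
#' correction is unbiased in counts: the expected corrected count equals the
#' actual-specific estimate.
#'
#' @param table color-coded localization table.
#' @param estimate a `crosstalk_estimate`.
#' @param cross_fractions optional named numeric: for each channel, the
#'   fraction of its apparent-specific count attributed to false activation by
#'   the wrong activation laser (e.g. `c(ch532 = 0.05)` for Cy3 false-activated
#'   by the 457 nm laser); removed in addition to the nonspecific estimate.
#' @param seed RNG seed for the thinning (recorded in the report).
#' @return corrected table, with a `"crosstalk_report"` attribute giving per
#'   channel the pre/post counts, removed count and estimated residual
#'   crosstalk fraction.
#' @export
subtract_crosstalk <- function(table, estimate, cross_fractions = NULL,
                               seed = NULL) {
  stopifnot(inherits(estimate, "crosstalk_estimate"))
  out <- table
  report <- list(seed = seed)
  with_seed(seed, {
    drop_idx <- integer(0)
    rep_rows <- lapply(seq_len(nrow(estimate)), function(i) {
      ch <- estimate$channel[i]
      idx <- which(out$channel == ch)
      n_ns <- estimate$expected_nonspecific[i]
      n_cross <- if (!is.null(cross_fractions) && ch %in% names(cross_fractions))
        cross_fractions[[ch]] * estimate$apparent[i] else 0
      n_remove <- round(n_ns + n_cross)
      if (n_remove > length(idx)) {
        warning(sprintf(
          "channel %s: expected removals (%d) exceed localizations (%d)",
          ch, n_remove, length(idx)))
        n_remove <- length(idx)
      }
      if (n_remove > 0)
        drop_idx <<- c(drop_idx, idx[sample.int(length(idx), n_remove)])
      residual <- if (length(idx) - n_remove > 0)
        max(0, n_ns + n_cross - n_remove) / (length(idx) - n_remove) else 0
      data.frame(channel = ch, pre = length(idx), removed = n_remove,
                 post = length(idx) - n_remove,
                 residual_fraction = residual)
    })
    report$channels <- do.call(rbind, rep_rows)
    if (length(drop_idx)) out <- out[-drop_idx, , drop = FALSE]
  })
  rownames(out) <- NULL
  out <- copy_table_meta(out, table)
  attr(out, "crosstalk_report") <- report
  out
}
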