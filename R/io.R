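# Molecule-list CSV I/O.
#
# Dialect: comment lines starting with '#' carry metadata, then a CSV with
# header frame,x_nm,y_nm,z_nm,photons,wx_nm,wy_nm,residual,channel,fov_id,
# pass_id. Coordinates are continuous nm from the FOV corner; the center of
# pixel (1,1) is at (0.5 px, 0.5 px). z_nm is empty in 2D mode.

MOLECULE_COLUMNS <- c("frame", "x_nm", "y_nm", "z_nm", "photons", "wx_nm",
                      "wy_nm", "residual", "channel", "fov_id", "pass_id")

#' Write a localization table as a molecule-list CSV
#'
#' @param table localization table (see [localize_movie()]).
#' @param path output path.
#' @export
write_molecule_list <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# stormtrace molecule list",
    "# coordinates: nm, continuous, origin at FOV corner;",
    "#   center of pixel (1,1) at (0.5 px, 0.5 px)",
    sprintf("# pixel_nm: %s", attr(table, "pixel_nm") %||% NA),
    sprintf("# n_frames: %s", attr(table, "n_frames") %||% NA)), con)
  tab <- as.data.frame(table)[, MOLECULE_COLUMNS]
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_molecule_list
#' @export
read_molecule_list <- function(path) {
  hdr <- readLines(path, n = 20)
  meta <- hdr[startsWith(hdr, "#")]
  tab <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(MOLECULE_COLUMNS, names(tab))
  if (length(missing))
    stop("molecule list missing columns: ", paste(missing, collapse = ", "))
  grab <- function(key) {
    ln <- grep(sprintf("^# %s:", key), meta, value = TRUE)
    if (length(ln)) suppressWarnings(as.numeric(sub(".*: *", "", ln[1])))
    else NA_real_
  }
  attr(tab, "pixel_nm") <- grab("pixel_nm")
  attr(tab, "n_frames") <- grab("n_frames")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Carry metadata attributes from `from` onto `to` (used after subsetting /
# transforming tables so downstream stages keep pixel size, schedule, ...).
copy_table_meta <- function(to, from) {
  for (a in c("pixel_nm", "n_frames", "schedule", "focal_z", "origin_nm",
              "rejections"))
    attr(to, a) <- attr(from, a)
  to
}
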