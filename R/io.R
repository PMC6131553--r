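#' Write / read a velocity-field stack
#'
#' Stores a list of [velocity_field()]s as plain text: per frame, CSV
#' rasters `frame%03d_U.csv`, `frame%03d_V.csv` and `frame%03d_mask.csv`
#' (0/1), plus a `meta.json` sidecar with the grid shape, window spacing,
#' frame interval and units.
#'
#' @param stack a list of [velocity_field()]s.
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_velocity_stack <- function(stack, dir) {
  stopifnot(is.list(stack), length(stack) >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- stack[[1]]
  meta <- list(n_frames = length(stack), rows = nrow(f1$U), cols = ncol(f1$U),
               window_spacing_um = f1$window_spacing,
               frame_interval_min = f1$frame_interval, units = f1$units)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  for (i in seq_along(stack)) {
    f <- stack[[i]]
    utils::write.table(f$U, file.path(dir, sprintf("frame%03d_U.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(f$V, file.path(dir, sprintf("frame%03d_V.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(f$mask * 1L,
                       file.path(dir, sprintf("frame%03d_mask.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_velocity_stack
#' @return `read_velocity_stack` returns the list of [velocity_field()]s.
#' @export
read_velocity_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lapply(seq_len(meta$n_frames), function(i) {
    rd <- function(tag) as.matrix(utils::read.table(
      file.path(dir, sprintf("frame%03d_%s.csv", i, tag)), sep = ","))
    velocity_field(U = unname(rd("U")), V = unname(rd("V")),
                   mask = unname(rd("mask")) > 0,
                   window_spacing = meta$window_spacing_um,
                   frame_interval = meta$frame_interval_min,
                   units = meta$units)
  })
}

#' Track, angle, inheritance and nuclear-series CSV formats
#'
#' Thin readers/writers for the package's plain-text exchange formats:
#' tracks as `track_id,frame,t_min,x_um,y_um`; angles as `angle_deg`;
#' inheritance as `division_id,count1,count2`; nuclear series as
#' `frame,cx,cy,xx,xy,yx,yy`.
#'
#' @param x the object to write.
#' @param path CSV file path.
#' @param frame_interval frame interval in minutes (for readers).
#' @return Readers return the corresponding package object; writers return
#'   `path` invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_tracks_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("track_id", "frame", "t_min",
                                        "x_um", "y_um")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_tracks_csv <- function(path, frame_interval) {
  track_set(utils::read.csv(path), frame_interval = frame_interval)
}

#' @rdname csv_io
#' @export
write_angles_csv <- function(x, path) {
  utils::write.csv(data.frame(angle_deg = as.numeric(x)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_angles_csv <- function(path) {
  out <- utils::read.csv(path)$angle_deg
  attr(out, "axial") <- FALSE
  class(out) <- "direction_sample"
  out
}

#' @rdname csv_io
#' @export
write_inheritance_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("division_id", "count1", "count2")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_inheritance_csv <- function(path) {
  d <- utils::read.csv(path)
  daughter_pair_counts(d$count1, d$count2, division_id = d$division_id)
}

#' @rdname csv_io
#' @export
write_nuclear_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("frame", "cx", "cy", "xx", "xy",
                                        "yx", "yy")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_nuclear_csv <- function(path, frame_interval = 2) {
  out <- utils::read.csv(path)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("nuclear_series", "data.frame")
  out
}

#' Write a simulation summary to CSV with a JSON run manifest
#'
#' Writes the observable time series as `summary.csv`
#' (`t,mean_speed,iop`) and a `manifest.json` recording every model
#' parameter, the protocol (steps, stride) and the seed, so a run can be
#' reproduced exactly.
#'
#' @param x a `sim_summary` from [simulate_sheet()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_summary <- function(x, dir) {
  stopifnot(inherits(x, "sim_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(data.frame(t = x$time, mean_speed = x$mean_speed,
                              iop = x$iop),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  manifest <- c(unclass(x$params),
                list(n_equil = x$n_equil, n_prod = x$n_prod,
                     stride = x$stride, seed = x$seed,
                     steady_speed = x$steady_speed,
                     steady_iop = x$steady_iop,
                     package_version = as.character(
                       utils::packageVersion("spvflock"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
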