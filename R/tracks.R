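#' Track table constructor
#'
#' Validates and classes a table of cell (nucleus) tracks: one row per spot,
#' columns `track_id`, `frame`, `t_min`, `x_um`, `y_um`. Frames within a
#' track must be strictly increasing with no gaps (gap closing with maximal
#' frame gap 0), and `t_min` must equal `frame * frame_interval` up to
#' round-off.
#'
#' @param df data.frame with the five columns above.
#' @param frame_interval time between frames (min).
#' @return The data.frame with class `track_set` and the frame interval as
#'   attribute.
#' @export
track_set <- function(df, frame_interval) {
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  stopifnot(all(need %in% names(df)), frame_interval > 0)
  df <- df[order(df$track_id, df$frame), need]
  stopifnot(all(is.finite(df$x_um)), all(is.finite(df$y_um)))
  by_track <- split(df$frame, df$track_id)
  if (!all(vapply(by_track, function(f) all(diff(f) == 1L), logical(1))))
    stop("frames within a track must be consecutive (no gaps)")
  attr(df, "frame_interval") <- frame_interval
  class(df) <- c("track_set", "data.frame")
  df
}

frame_interval <- function(tracks) attr(tracks, "frame_interval")

#' Fixed-lag mean square displacement
#'
#' For every time point `t`, averages the squared displacement between `t`
#' and `t + lag` over all tracks that span both times (tracks ending within
#' the lag of `t` are excluded). Tracks with fewer than `min_spots` spots are
#' discarded up front. The default lag of 300 min (5 h) and minimum of 19
#' spots match a 16-min frame interval where 19 spots cover 5 h of tracking.
#'
#' @param tracks a [track_set()].
#' @param lag_min lag in minutes; must be a multiple of the frame interval.
#' @param min_spots minimal number of spots per retained track.
#' @return A data.frame with `t_min`, `msd_um2` and the number of
#'   contributing tracks `n`; time points with no eligible track are absent.
#' @examples
#' tr <- gen_tracks(track_spec(kind = "ballistic", n_tracks = 2, n_frames = 40,
#'                             frame_interval = 16, speed = 10, seed = 1))
#' msd <- fixed_lag_msd(tr, lag_min = 320)
#' # ballistic: (10 um/h * 320/60 h)^2
#' all.equal(msd$msd_um2, rep((10 * 320 / 60)^2, nrow(msd)))
#' @export
fixed_lag_msd <- function(tracks, lag_min = 300, min_spots = 19) {
  stopifnot(inherits(tracks, "track_set"))
  fi <- frame_interval(tracks)
  lag_frames <- lag_min / fi
  if (abs(lag_frames - round(lag_frames)) > 1e-6)
    stop("lag must be a multiple of the frame interval")
  lag_frames <- as.integer(round(lag_frames))
  if (lag_frames < 1) stop("lag must be at least one frame")
  keep <- names(which(table(tracks$track_id) >= min_spots))
  tr <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  if (nrow(tr) == 0) return(data.frame(t_min = numeric(0),
                                       msd_um2 = numeric(0), n = integer(0)))
  sq <- do.call(rbind, lapply(split(tr, tr$track_id), function(d) {
    m <- nrow(d)
    if (m <= lag_frames) return(NULL)
    i <- seq_len(m - lag_frames)
    data.frame(t_min = d$t_min[i],
               d2 = (d$x_um[i + lag_frames] - d$x_um[i])^2 +
                    (d$y_um[i + lag_frames] - d$y_um[i])^2)
  }))
  if (is.null(sq)) return(data.frame(t_min = numeric(0),
                                     msd_um2 = numeric(0), n = integer(0)))
  agg <- do.call(rbind, lapply(split(sq$d2, sq$t_min), function(v)
    data.frame(msd_um2 = mean(v), n = length(v))))
  out <- data.frame(t_min = as.numeric(rownames(agg)), agg)
  out <- out[order(out$t_min), ]
  rownames(out) <- NULL
  out
}

#' Migration persistency index along a track
#'
#' Slides a window of `window` successive frames along one track; within
#' each window the unit vectors of the consecutive displacements are
#' averaged and the MPI is the magnitude of that mean. An MPI of 1 means
#' persistent straight-line migration; random turning gives values near 0.
#' Zero-length displacements have no direction and are skipped; windows with
#' fewer than 2 usable displacements return `NA`.
#'
#' @param track a two-column matrix/data.frame of x, y positions (one track,
#'   time-ordered), or a single-track [track_set()].
#' @param window window width in frames (default 10, i.e. 9 displacements).
#' @return Numeric vector of MPI values, one per window position
#'   (`length = n_frames - window + 1`).
#' @export
mpi_series <- function(track, window = 10) {
  xy <- .track_xy(track)
  n <- nrow(xy)
  stopifnot(window >= 2)
  if (n < window) stop("track shorter than the window")
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 0
  ux <- ifelse(ok, dx / len, NA_real_)
  uy <- ifelse(ok, dy / len, NA_real_)
  k <- window - 1  # displacements per window
  vapply(seq_len(n - window + 1), function(i) {
    sel <- i:(i + k - 1)
    use <- ok[sel]
    if (sum(use) < 2) return(NA_real_)
    sqrt(mean(ux[sel][use])^2 + mean(uy[sel][use])^2)
  }, numeric(1))
}

.track_xy <- function(track) {
  if (inherits(track, "track_set") || is.data.frame(track)) {
    if (all(c("x_um", "y_um") %in% names(track))) {
      if (!is.null(track$track_id) && length(unique(track$track_id)) > 1)
        stop("supply a single track")
      return(cbind(track$x_um, track$y_um))
    }
    return(as.matrix(track[, 1:2]))
  }
  as.matrix(track)[, 1:2, drop = FALSE]
}

#' Per-track motility summary
#'
#' For each track with at least two frames: mean velocity (total path length
#' divided by elapsed time, um/h) and the Euclidean (straight line,
#' start-to-end) distance traveled (um). Single-spot tracks are dropped.
#'
#' @param tracks a [track_set()].
#' @return A data.frame with `track_id`, `mean_velocity_um_h`,
#'   `euclidean_um`, `path_um` and `duration_min`.
#' @export
track_motility_summary <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  res <- lapply(split(tracks, tracks$track_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    steps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    dur <- d$t_min[nrow(d)] - d$t_min[1]
    data.frame(track_id = d$track_id[1],
               mean_velocity_um_h = sum(steps) / (dur / 60),
               euclidean_um = sqrt((d$x_um[nrow(d)] - d$x_um[1])^2 +
                                   (d$y_um[nrow(d)] - d$y_um[1])^2),
               path_um = sum(steps), duration_min = dur)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Circular order statistics of direction samples
#'
#' Treats each of `n` measured directions (cell divisions, nucleus-to-Golgi
#' axes, ...) as a unit vector `d_n = (cos theta_n, sin theta_n)` and
#' returns the component means `<x>`, `<y>`, the magnitude
#' `||<d>|| = sqrt(<x>^2 + <y>^2)` of the average vector, and the mean angle
#' (two-argument arctangent, quadrant-correct). A magnitude of 1 indicates
#' completely consistent direction, 0 no common direction.
#'
#' In axial mode directions `theta` and `theta + 180` degrees are treated as
#' equivalent (orientation axes): angles are doubled before averaging and
#' the mean angle halved afterwards.
#'
#' @param angles_deg numeric vector of angles in degrees, or a
#'   `direction_sample` from [gen_division_angles()].
#' @param axial logical; treat the sample as axial data.
#' @return A list of class `order_stats`: `mean_x`, `mean_y`, `magnitude`,
#'   `mean_angle_deg` (NA when the magnitude is below 1e-12), `n`, `axial`.
#' @examples
#' direction_order_stats(c(0, 90))$magnitude # sqrt(2)/2
#' @export
direction_order_stats <- function(angles_deg, axial = FALSE) {
  if (inherits(angles_deg, "direction_sample")) {
    if (missing(axial)) axial <- isTRUE(attr(angles_deg, "axial"))
    angles_deg <- as.numeric(angles_deg)
  }
  stopifnot(length(angles_deg) >= 1, all(is.finite(angles_deg)))
  th <- (angles_deg %% 360) * pi / 180
  if (axial) th <- 2 * th
  mx <- mean(cos(th)); my <- mean(sin(th))
  mag <- sqrt(mx^2 + my^2)
  ang <- if (mag < 1e-12) NA_real_ else atan2(my, mx) * 180 / pi
  if (!is.na(ang)) {
    if (axial) ang <- ang / 2
    ang <- ang %% 360
  }
  out <- list(mean_x = mx, mean_y = my, magnitude = mag,
              mean_angle_deg = ang, n = length(angles_deg), axial = axial)
  class(out) <- "order_stats"
  out
}

#' @export
print.order_stats <- function(x, ...) {
  cat(sprintf("%s order statistics over n = %d directions\n",
              if (x$axial) "Axial" else "Vector", x$n))
  cat(sprintf("  ||<d>|| = %.4f, mean angle = %s deg\n", x$magnitude,
              if (is.na(x$mean_angle_deg)) "undefined"
              else sprintf("%.2f", x$mean_angle_deg)))
  invisible(x)
}

#' Unity-normalized rose histogram
#'
#' Bins angles into `n_bins` equal sectors of the circle and applies
#' unity-based (min-max) normalization so the smallest count maps to 0 and
#' the largest to 1; a flat histogram (all counts equal) maps to all zeros.
#'
#' @param angles_deg angles in degrees (reduced modulo 360).
#' @param n_bins number of sectors (>= 2). Bin k covers
#'   `[(k-1), k) * 360/n_bins` degrees.
#' @return A data.frame with `bin_start_deg`, `bin_mid_deg`, `count`,
#'   `height` (normalized).
#' @export
rose_histogram <- function(angles_deg, n_bins = 12) {
  stopifnot(n_bins >= 2, length(angles_deg) >= 1)
  a <- angles_deg %% 360
  width <- 360 / n_bins
  bin <- pmin(floor(a / width) + 1, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  rng <- range(counts)
  height <- if (rng[1] == rng[2]) rep(0, n_bins)
            else (counts - rng[1]) / (rng[2] - rng[1])
  data.frame(bin_start_deg = (seq_len(n_bins) - 1) * width,
             bin_mid_deg = (seq_len(n_bins) - 0.5) * width,
             count = counts, height = height)
}

#' Relative nuclear position over time
#'
#' Quantifies pre-mitotic nuclear migration: for each frame the nucleus
#' centre `c`, the nearest plasma-membrane point `x` and the opposite
#' membrane point `y` define the relative position
#' `p = |c - x| / |y - x|` (0 = nucleus at the near membrane, 0.5 = cell
#' midpoint, 1 = at the far membrane). The series is aligned so the last
#' frame (the final time point before mitosis entry) has time 0 and earlier
#' frames have negative times, matching reversed traversal of a time-lapse.
#'
#' @param series a data.frame with columns `frame`, `cx`, `cy`, `xx`, `xy`,
#'   `yx`, `yy` (nucleus centre, near membrane point, far membrane point),
#'   or a `nuclear_series` from [gen_premitotic_track()].
#' @param frame_interval minutes between frames (default taken from the
#'   series attribute, else 2).
#' @param tol minimal `|y - x|`; frames below it are marked invalid (`NA`).
#' @return A data.frame with `frame`, `t_min` (<= 0) and `p`.
#' @export
relative_nuclear_position <- function(series, frame_interval = NULL,
                                      tol = 1e-9) {
  if (is.null(frame_interval))
    frame_interval <- attr(series, "frame_interval")
  if (is.null(frame_interval)) frame_interval <- 2
  need <- c("frame", "cx", "cy", "xx", "xy", "yx", "yy")
  stopifnot(all(need %in% names(series)))
  s <- series[order(series$frame), ]
  span <- sqrt((s$yx - s$xx)^2 + (s$yy - s$xy)^2)
  p <- sqrt((s$cx - s$xx)^2 + (s$cy - s$xy)^2) / span
  p[span < tol] <- NA_real_
  n <- nrow(s)
  data.frame(frame = s$frame, t_min = (seq_len(n) - n) * frame_interval,
             p = p)
}
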