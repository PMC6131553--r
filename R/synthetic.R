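#' Specification of a synthetic gridded flow
#'
#' Parameters of the synthetic PIV-type velocity fields produced by
#' [gen_gridded_flow()]: vectors of deterministic magnitude `speed_mean`
#' whose angles are a spatially smoothed Gaussian field around `base_angle`.
#'
#' @param grid_shape integer vector `c(rows, cols)` of PIV windows.
#' @param base_angle mean flow direction (degrees).
#' @param angular_noise_sd SD of the per-window angular noise (degrees).
#' @param correlation_scale spatial smoothing length of the angle field,
#'   in windows (SD of the Gaussian kernel); 0 = no smoothing.
#' @param speed_mean vector magnitude (um/h), identical for every vector.
#' @param n_frames number of frames to generate.
#' @param window_spacing physical window spacing (um).
#' @param frame_interval frame interval (min).
#' @param seed integer seed; the generator is a pure function of the spec.
#' @return A list of class `flow_spec`.
#' @export
flow_spec <- function(grid_shape = c(64, 64), base_angle = 0,
                      angular_noise_sd = 30, correlation_scale = 4,
                      speed_mean = 20, n_frames = 1, window_spacing = 90,
                      frame_interval = 12, seed = 1) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1),
            angular_noise_sd >= 0, correlation_scale >= 0, speed_mean >= 0,
            n_frames >= 1)
  s <- list(grid_shape = as.integer(grid_shape), base_angle = base_angle,
            angular_noise_sd = angular_noise_sd,
            correlation_scale = correlation_scale, speed_mean = speed_mean,
            n_frames = as.integer(n_frames),
            window_spacing = window_spacing,
            frame_interval = frame_interval, seed = as.integer(seed))
  class(s) <- "flow_spec"
  s
}

#' Generate synthetic gridded velocity fields
#'
#' Emulates PIV output with controllable spatial order. Per frame, each
#' window receives an angle `base_angle + N(0, angular_noise_sd)`; the unit
#' heading components (not the raw angles, avoiding wrap-around artefacts)
#' are then smoothed with an isotropic Gaussian kernel of SD
#' `correlation_scale` windows and re-normalized, and every vector is given
#' magnitude `speed_mean` exactly. Larger `correlation_scale` yields longer
#' velocity correlation lengths.
#'
#' @param spec a [flow_spec()].
#' @return A list of [velocity_field()]s of length `n_frames`.
#' @export
gen_gridded_flow <- function(spec) {
  stopifnot(inherits(spec, "flow_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  lapply(seq_len(spec$n_frames), function(f) {
    ang <- (spec$base_angle +
            matrix(stats::rnorm(nr * nc, 0, spec$angular_noise_sd), nr, nc)) *
           pi / 180
    cx <- cos(ang); sx <- sin(ang)
    if (spec$correlation_scale > 0) {
      cx <- gauss_smooth2d(cx, spec$correlation_scale)
      sx <- gauss_smooth2d(sx, spec$correlation_scale)
    }
    mag <- sqrt(cx^2 + sx^2)
    zero <- mag < 1e-12
    cx[zero] <- cos(spec$base_angle * pi / 180)
    sx[zero] <- sin(spec$base_angle * pi / 180)
    mag[zero] <- 1
    velocity_field(U = spec$speed_mean * cx / mag,
                   V = spec$speed_mean * sx / mag,
                   window_spacing = spec$window_spacing,
                   frame_interval = spec$frame_interval)
  })
}

# Separable Gaussian smoothing with reflective borders.
gauss_smooth2d <- function(M, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect_fold <- function(i, n) {  # fold indices into 1..n by reflection
    j <- (i - 1) %% (2 * n)
    ifelse(j >= n, 2 * n - 1 - j, j) + 1
  }
  smooth1 <- function(X) {  # along rows (first dim)
    n <- nrow(X)
    idx <- lapply(-r:r, function(d) reflect_fold(seq_len(n) + d, n))
    out <- matrix(0, nrow(X), ncol(X))
    for (j in seq_along(idx)) out <- out + k[j] * X[idx[[j]], , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(M))))
}

#' Generate Vicsek point-particle flow fields
#'
#' Runs the classic Vicsek flocking model (each particle adopts the mean
#' heading of all particles within `radius`, itself included, plus uniform
#' angular noise in `[-noise_width/2, +noise_width/2]`) and rasterizes the
#' particle velocities of every step onto a grid by per-bin averaging, with
#' empty bins masked. Noise width 0 with global coupling collapses all
#' headings within a few steps; radius 0 gives independent angular random
#' walks.
#'
#' @param n number of particles (>= 1).
#' @param box side of the periodic square box.
#' @param speed particle speed (box length per frame).
#' @param radius interaction radius (>= 0).
#' @param noise_width full width of the uniform angular noise (degrees).
#' @param n_steps number of steps (frames returned).
#' @param seed integer seed.
#' @param grid_shape `c(rows, cols)` of the rasterization grid.
#' @return A list of [velocity_field()]s, one per step, with units
#'   "box/frame" and `window_spacing = box / cols`.
#' @export
gen_vicsek_particles <- function(n, box, speed = 0.03, radius = 1,
                                 noise_width = 0, n_steps = 10, seed = 1,
                                 grid_shape = c(16, 16)) {
  stopifnot(n >= 1, box > 0, radius >= 0, speed >= 0, n_steps >= 1,
            noise_width >= 0)
  set.seed(seed)
  pos <- cbind(stats::runif(n, 0, box), stats::runif(n, 0, box))
  th <- stats::runif(n, -pi, pi)
  nw <- noise_width * pi / 180
  nr <- grid_shape[1]; nc <- grid_shape[2]
  frames <- vector("list", n_steps)
  for (s in seq_len(n_steps)) {
    # mean neighbour heading (self included, classic update)
    if (radius > 0) {
      dx <- outer(pos[, 1], pos[, 1], "-"); dx <- dx - box * round(dx / box)
      dy <- outer(pos[, 2], pos[, 2], "-"); dy <- dy - box * round(dy / box)
      nb <- (dx^2 + dy^2) <= radius^2
      sn <- nb %*% sin(th); cs <- nb %*% cos(th)
      th_new <- atan2(sn, cs)[, 1]
    } else {
      th_new <- th
    }
    if (nw > 0) th_new <- th_new + stats::runif(n, -nw / 2, nw / 2)
    th <- th_new
    vel <- speed * cbind(cos(th), sin(th))
    pos <- (pos + vel) %% box
    # rasterize
    br <- pmin(floor(pos[, 2] / box * nr) + 1, nr)  # row from y
    bc <- pmin(floor(pos[, 1] / box * nc) + 1, nc)
    key <- (bc - 1) * nr + br
    U <- matrix(0, nr, nc); V <- matrix(0, nr, nc)
    cnt <- matrix(0, nr, nc)
    su <- tapply(vel[, 1], key, sum)
    sv <- tapply(vel[, 2], key, sum)
    ct <- tapply(rep(1, n), key, sum)
    ii <- as.integer(names(su))
    U[ii] <- su / ct; V[ii] <- sv / ct; cnt[ii] <- ct
    frames[[s]] <- velocity_field(U = U, V = V, mask = cnt > 0,
                                  window_spacing = box / nc,
                                  frame_interval = 1, units = "box/frame")
  }
  frames
}

#' Specification of synthetic cell tracks
#'
#' @param kind one of `"ballistic"`, `"persistent"`, `"brownian"`,
#'   `"alternating"`, `"stationary"`.
#' @param n_tracks number of tracks.
#' @param n_frames frames per track (>= 2).
#' @param frame_interval minutes between frames.
#' @param speed cell speed (um/h); the per-frame step length is
#'   `speed * frame_interval / 60`.
#' @param persistence in `[0, 1]`; for persistent tracks the per-step
#'   turning angle is wrapped-normal with SD `(1 - persistence) * 180`
#'   degrees (1 = straight line, 0 = nearly uncorrelated headings).
#' @param field_size side of the square region start points are drawn from
#'   (um).
#' @param seed integer seed.
#' @return A list of class `track_spec`.
#' @export
track_spec <- function(kind = c("ballistic", "persistent", "brownian",
                                "alternating", "stationary"),
                       n_tracks = 10, n_frames = 20, frame_interval = 16,
                       speed = 10, persistence = 0.5, field_size = 1000,
                       seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_tracks >= 1, n_frames >= 2, frame_interval > 0, speed >= 0,
            persistence >= 0, persistence <= 1)
  s <- list(kind = kind, n_tracks = as.integer(n_tracks),
            n_frames = as.integer(n_frames),
            frame_interval = frame_interval, speed = speed,
            persistence = persistence, field_size = field_size,
            seed = as.integer(seed))
  class(s) <- "track_spec"
  s
}

#' Generate synthetic cell tracks
#'
#' Produces a [track_set()] emulating tracking output, with motion models of
#' known statistics: `ballistic` moves on a straight line at constant speed,
#' `persistent` is a correlated random walk, `brownian` draws an independent
#' direction every step, `alternating` retraces its previous step exactly
#' (end-to-end displacement 0 over even step counts), `stationary` does not
#' move. Each track uses its own RNG substream (derived from the spec seed),
#' so tracks are reproducible under reordering.
#'
#' @param spec a [track_spec()].
#' @return A [track_set()].
#' @export
gen_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, spec$n_tracks)
  step <- spec$speed * spec$frame_interval / 60
  n <- spec$n_frames
  rows <- lapply(seq_len(spec$n_tracks), function(i) {
    set.seed(sub_seeds[i])
    start <- stats::runif(2, 0, spec$field_size)
    head0 <- stats::runif(1, -pi, pi)
    headings <- switch(spec$kind,
      ballistic = rep(head0, n - 1),
      persistent = head0 + cumsum(c(0, stats::rnorm(n - 2, 0,
                     (1 - spec$persistence) * pi))),
      brownian = stats::runif(n - 1, -pi, pi),
      alternating = head0 + pi * (seq_len(n - 1) - 1),
      stationary = rep(head0, n - 1))
    sl <- if (spec$kind == "stationary") 0 else step
    x <- start[1] + cumsum(c(0, sl * cos(headings)))
    y <- start[2] + cumsum(c(0, sl * sin(headings)))
    data.frame(track_id = i, frame = seq_len(n) - 1L,
               t_min = (seq_len(n) - 1) * spec$frame_interval,
               x_um = x, y_um = y)
  })
  track_set(do.call(rbind, rows), frame_interval = spec$frame_interval)
}

#' Generate division / polarity angles
#'
#' Draws `n` directions from a von Mises distribution around `mean_angle`
#' with the given concentration (`kappa`); concentration 0 gives the uniform
#' circular distribution. Sampling uses the Best-Fisher rejection algorithm.
#'
#' @param n number of angles (>= 1).
#' @param mean_angle mean direction (degrees).
#' @param concentration von Mises concentration `kappa >= 0`.
#' @param seed integer seed.
#' @return A numeric vector of angles in degrees in `[0, 360)`, of class
#'   `direction_sample` with attribute `axial = FALSE`.
#' @export
gen_division_angles <- function(n, mean_angle = 0, concentration = 1,
                                seed = 1) {
  stopifnot(n >= 1, concentration >= 0)
  set.seed(seed)
  mu <- mean_angle * pi / 180
  th <- if (concentration == 0) {
    stats::runif(n, 0, 2 * pi)
  } else {
    rvonmises(n, mu, concentration)
  }
  out <- (th * 180 / pi) %% 360
  attr(out, "axial") <- FALSE
  class(out) <- "direction_sample"
  out
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Specification of synthetic organelle partitioning
#'
#' @param n_divisions number of divisions.
#' @param body_count_law named probability table over per-division total
#'   body counts (names = integer totals); must sum to 1. The default is
#'   uniform over 1..6.
#' @param p_sym per-body assignment probability in (0, 1).
#' @param seed integer seed.
#' @return A list of class `partition_spec`.
#' @export
partition_spec <- function(n_divisions = 100,
                           body_count_law = stats::setNames(rep(1 / 6, 6),
                                                            1:6),
                           p_sym = 0.5, seed = 1) {
  stopifnot(n_divisions >= 1, length(body_count_law) >= 1,
            abs(sum(body_count_law) - 1) < 1e-9, all(body_count_law >= 0),
            p_sym > 0, p_sym < 1)
  totals <- as.integer(names(body_count_law))
  stopifnot(!anyNA(totals), all(totals >= 0))
  s <- list(n_divisions = as.integer(n_divisions),
            body_count_law = body_count_law, p_sym = p_sym,
            seed = as.integer(seed))
  class(s) <- "partition_spec"
  s
}

#' Generate daughter-pair body counts
#'
#' For each division, a total body count is drawn from the spec's count law
#' and each body is assigned independently to daughter 1 with probability
#' `p_sym`; the pair `(count1, count2)` always sums to the drawn total.
#'
#' @param spec a [partition_spec()].
#' @return A [daughter_pair_counts()].
#' @export
gen_inheritance_counts <- function(spec) {
  stopifnot(inherits(spec, "partition_spec"))
  set.seed(spec$seed)
  support <- as.integer(names(spec$body_count_law))
  totals <- if (length(support) == 1) rep(support, spec$n_divisions)
            else sample(support, spec$n_divisions, replace = TRUE,
                        prob = spec$body_count_law)
  c1 <- stats::rbinom(spec$n_divisions, totals, spec$p_sym)
  daughter_pair_counts(c1, totals - c1)
}

#' Generate a pre-mitotic nuclear position series
#'
#' Emulates the coordinate triplets digitised from time-lapse movies of
#' cells approaching mitosis: the nucleus centre `c` sits at the cell
#' midpoint with Gaussian jitter, then drifts linearly toward the nearest
#' membrane point `x` during the final `drift_onset` minutes (active
#' pre-mitotic nuclear migration); the membrane points `x` and `y` are
#' fixed. The last frame is the final time point before mitosis entry.
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_interval minutes between frames.
#' @param drift_onset minutes before the end at which the drift starts; must
#'   be smaller than the series duration. 0 = no drift.
#' @param jitter_sd SD of the positional jitter (um).
#' @param cell_length distance between the membrane points `x` and `y` (um).
#' @param drift_fraction fraction of the midpoint-to-x distance covered by
#'   the final frame (1 = nucleus reaches `x`).
#' @param seed integer seed.
#' @return A data.frame of class `nuclear_series` with columns `frame`,
#'   `cx`, `cy`, `xx`, `xy`, `yx`, `yy` and the frame interval as attribute.
#' @export
gen_premitotic_track <- function(n_frames = 60, frame_interval = 2,
                                 drift_onset = 30, jitter_sd = 0.3,
                                 cell_length = 30, drift_fraction = 1,
                                 seed = 1) {
  stopifnot(n_frames >= 2, frame_interval > 0, drift_onset >= 0,
            drift_onset < n_frames * frame_interval, jitter_sd >= 0,
            cell_length > 0, drift_fraction >= 0, drift_fraction <= 1)
  set.seed(seed)
  t_min <- (seq_len(n_frames) - 1) * frame_interval
  t_end <- t_min[n_frames]
  mid <- cell_length / 2
  # drift from the midpoint toward x (at 0) over the final drift_onset min
  frac <- if (drift_onset > 0)
    pmax(0, (t_min - (t_end - drift_onset)) / drift_onset) else 0
  cx <- mid * (1 - drift_fraction * frac) +
    stats::rnorm(n_frames, 0, jitter_sd)
  cy <- stats::rnorm(n_frames, 0, jitter_sd)
  out <- data.frame(frame = seq_len(n_frames) - 1L, cx = cx, cy = cy,
                    xx = 0, xy = 0, yx = cell_length, yy = 0)
  attr(out, "frame_interval") <- frame_interval
  class(out) <- c("nuclear_series", "data.frame")
  out
}
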