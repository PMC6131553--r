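#' Angle-distance correlation curve of a velocity field
#'
#' Estimates how well velocity vectors stay aligned over distance. Seeds are
#' the vectors along the main (top-left to bottom-right) diagonal of the
#' grid; from each seed the four cardinal directions are walked one window at
#' a time, and at every integer grid distance the angle between the seed
#' vector and the vector there is recorded
#' (`theta = acos(v0 . vr / (|v0| |vr|))`, in degrees). Masked,
#' out-of-bounds, and zero-magnitude positions are skipped. Angles are
#' averaged per distance over all seeds and directions, with the standard
#' error of the mean over the same samples.
#'
#' @param field a [velocity_field()].
#' @return A data.frame of class `correlation_curve` with columns
#'   `r_windows`, `r_um`, `theta_mean_deg`, `theta_sem_deg`, `n`; the window
#'   spacing is kept as an attribute.
#' @export
angle_correlation_curve <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  U <- field$U; V <- field$V
  sp <- sqrt(U^2 + V^2)
  valid <- field$mask & sp > 0
  if (sum(valid) < 2) stop("need at least 2 unmasked nonzero vectors")
  nr <- nrow(U); nc <- ncol(U)
  n_seed <- min(nr, nc)
  seeds <- cbind(seq_len(n_seed), seq_len(n_seed))
  dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  r_max <- max(nr, nc) - 1
  .curve_accumulate(U, V, sp, valid, seeds, dirs, r_max,
                    field$window_spacing)
}

.curve_accumulate <- function(U, V, sp, valid, seeds, dirs, r_max,
                              window_spacing) {
  nr <- nrow(U); nc <- ncol(U)
  n_acc <- integer(r_max); s_acc <- numeric(r_max); s2_acc <- numeric(r_max)
  seed_ok <- valid[seeds]
  for (d in seq_len(nrow(dirs))) {
    for (r in seq_len(r_max)) {
      tr <- seeds[, 1] + dirs[d, 1] * r
      tc <- seeds[, 2] + dirs[d, 2] * r
      inb <- seed_ok & tr >= 1 & tr <= nr & tc >= 1 & tc <= nc
      if (!any(inb)) next
      ti <- cbind(tr[inb], tc[inb])
      ok <- valid[ti]
      if (!any(ok)) next
      si <- seeds[inb, , drop = FALSE][ok, , drop = FALSE]
      ti <- ti[ok, , drop = FALSE]
      cosang <- (U[si] * U[ti] + V[si] * V[ti]) / (sp[si] * sp[ti])
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      n_acc[r] <- n_acc[r] + length(ang)
      s_acc[r] <- s_acc[r] + sum(ang)
      s2_acc[r] <- s2_acc[r] + sum(ang^2)
    }
  }
  keep <- which(n_acc > 0)
  n <- n_acc[keep]
  m <- s_acc[keep] / n
  varr <- ifelse(n > 1, pmax(0, (s2_acc[keep] - n * m^2) / (n - 1)), NA_real_)
  sem <- ifelse(n > 1, sqrt(varr / n), NA_real_)
  out <- data.frame(r_windows = keep, r_um = keep * window_spacing,
                    theta_mean_deg = m, theta_sem_deg = sem, n = n)
  attr(out, "window_spacing") <- window_spacing
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' All-pairs correlation curve (exhaustive reference estimator)
#'
#' Averages the angle between every pair of unmasked nonzero vectors at each
#' axis-aligned separation (along rows and along columns). Exhaustive and
#' O(grid^2 * r), intended for small grids as an independent reference for
#' [angle_correlation_curve()].
#'
#' @param field a [velocity_field()]; grids up to 32 x 32.
#' @return A `correlation_curve` data.frame (same format as
#'   [angle_correlation_curve()]).
#' @export
allpairs_correlation_oracle <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  nr <- nrow(field$U); nc <- ncol(field$U)
  if (nr > 32 || nc > 32) stop("oracle restricted to grids up to 32 x 32")
  U <- field$U; V <- field$V
  sp <- sqrt(U^2 + V^2)
  valid <- field$mask & sp > 0
  r_max <- max(nr, nc) - 1
  n_acc <- integer(r_max); s_acc <- numeric(r_max); s2_acc <- numeric(r_max)
  idx <- which(valid, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    for (r in seq_len(r_max)) {
      tgt <- rbind(if (i + r <= nr) c(i + r, j),
                   if (j + r <= nc) c(i, j + r))
      if (is.null(tgt)) next
      ok <- valid[tgt]
      if (!any(ok)) next
      tgt <- tgt[ok, , drop = FALSE]
      cosang <- (U[i, j] * U[tgt] + V[i, j] * V[tgt]) / (sp[i, j] * sp[tgt])
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      n_acc[r] <- n_acc[r] + length(ang)
      s_acc[r] <- s_acc[r] + sum(ang)
      s2_acc[r] <- s2_acc[r] + sum(ang^2)
    }
  }
  keep <- which(n_acc > 0)
  n <- n_acc[keep]
  m <- s_acc[keep] / n
  varr <- ifelse(n > 1, pmax(0, (s2_acc[keep] - n * m^2) / (n - 1)), NA_real_)
  sem <- ifelse(n > 1, sqrt(varr / n), NA_real_)
  out <- data.frame(r_windows = keep, r_um = keep * field$window_spacing,
                    theta_mean_deg = m, theta_sem_deg = sem, n = n)
  attr(out, "window_spacing") <- field$window_spacing
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' n-sigma velocity correlation length
#'
#' The correlation length `C_vv` is the largest distance `r` at which
#' vectors still point, on average, within 90 degrees of each other with
#' n-sigma confidence:
#' `C_vv = max r : mean(theta)(r) + n_sigma * SEM(theta(r)) < 90 deg`.
#' Distances with fewer than 2 angle samples are ineligible (their SEM is
#' undefined). If the criterion fails at every distance, `C_vv = 0`.
#'
#' By default the maximum is taken over all passing distances even if an
#' intermediate distance fails; `contiguous = TRUE` instead stops at the
#' first failure.
#'
#' @param x a [velocity_field()] or a precomputed `correlation_curve`.
#' @param n_sigma significance level in standard errors (default 5).
#' @param contiguous require the criterion to hold at every smaller distance.
#' @return A list with `c_vv_um`, `c_vv_windows` and the `curve` used.
#' @examples
#' f <- velocity_field(U = matrix(1, 16, 16), V = matrix(0, 16, 16),
#'                     window_spacing = 90)
#' correlation_length(f)$c_vv_windows # 15: uniform flow passes everywhere
#' @export
correlation_length <- function(x, n_sigma = 5, contiguous = FALSE) {
  curve <- if (inherits(x, "correlation_curve")) x
           else angle_correlation_curve(x)
  spacing <- attr(curve, "window_spacing")
  eligible <- curve$n >= 2 & is.finite(curve$theta_sem_deg)
  pass <- eligible &
    (curve$theta_mean_deg + n_sigma * curve$theta_sem_deg < 90)
  if (!any(pass)) {
    cw <- 0
  } else if (contiguous) {
    # largest r such that every eligible distance up to r passes
    fail_r <- curve$r_windows[eligible & !pass]
    first_fail <- if (length(fail_r)) min(fail_r) else Inf
    ok <- pass & curve$r_windows < first_fail
    cw <- if (any(ok)) max(curve$r_windows[ok]) else 0
  } else {
    cw <- max(curve$r_windows[pass])
  }
  list(c_vv_um = cw * spacing, c_vv_windows = cw, curve = curve)
}

#' Correlation length of every frame in a stack
#'
#' @param stack a list of [velocity_field()]s.
#' @inheritParams correlation_length
#' @return A data.frame with `frame` and `c_vv_um`.
#' @export
correlation_length_series <- function(stack, n_sigma = 5,
                                      contiguous = FALSE) {
  stopifnot(is.list(stack), length(stack) >= 1)
  data.frame(frame = seq_along(stack),
             c_vv_um = vapply(stack, function(f)
               correlation_length(f, n_sigma, contiguous)$c_vv_um,
               numeric(1)))
}
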