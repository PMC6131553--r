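#' Vicsek-type polarization update
#'
#' Advances the polarization angles by one time step:
#' `theta_i(t+dt) = theta_i(t) + (dt/tau_V) * <phi_j - theta_i> + eta_i`,
#' where the average runs over all cells `j != i` within centre-to-centre
#' distance `R_V` (minimum image) whose previous-step displacement is nonzero
#' (their velocity angle `phi_j` is otherwise undefined and they are
#' skipped). Each difference is wrapped into `(-pi, pi]` before averaging;
#' an empty neighbourhood contributes no alignment. `eta_i` is Gaussian with
#' variance `2 * D_r * dt` (Brownian-rotation discretization).
#'
#' @param state a `sheet_state` (uses `positions`, `disp`, `theta`).
#' @param params a [model_params()] object.
#' @param noise optional vector of N noise increments (radians); by default
#'   drawn as `rnorm(N, 0, sqrt(2 * D_r * dt))` from the current RNG.
#' @return The new angle vector, wrapped into `(-pi, pi]`.
#' @export
alignment_update <- function(state, params, noise = NULL) {
  N <- nrow(state$positions)
  if (is.null(noise))
    noise <- stats::rnorm(N, 0, sqrt(2 * params$D_r * params$dt))
  inc <- cpp_alignment_increment(state$positions, state$disp, state$theta,
                                 state$L, params$R_V, params$tau_V, params$dt)
  wrap_angle(state$theta + inc + noise)
}

#' Wrap angles into (-pi, pi]
#' @param a angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  a <- a %% (2 * pi)
  ifelse(a > pi, a - 2 * pi, a)
}

#' Advance the sheet by one time step
#'
#' Performs one update of the equations of motion: the polarization angles
#' are updated first ([alignment_update()]), then positions advance as
#' `r_i(t+dt) = r_i(t) + (mu * F_i(t) + v0 * n_i(t+dt)) * dt`
#' with `n_i = (cos theta_i, sin theta_i)` evaluated at the new angles and
#' `F_i` the analytic shape forces at the current positions. Positions are
#' re-wrapped into the box and the step displacement is stored in `disp`
#' (it defines the neighbour velocity angles of the next alignment update).
#'
#' @inheritParams alignment_update
#' @return The updated `sheet_state`.
#' @export
spv_step <- function(state, params, noise = NULL) {
  theta_new <- alignment_update(state, params, noise)
  f <- sheet_forces(state$positions, params)
  n_hat <- cbind(cos(theta_new), sin(theta_new))
  disp <- (params$mu * f$force + params$v0 * n_hat) * params$dt
  if (!all(is.finite(disp))) stop("non-finite displacement in spv_step")
  state$positions <- (state$positions + disp) %% state$L
  state$disp <- disp
  state$theta <- theta_new
  state$t <- state$t + params$dt
  state
}

#' Run the full monolayer simulation
#'
#' Initializes `N` cells at random positions with random polarizations,
#' equilibrates the passive tissue (`v0 = R_V = 0`) for `n_equil` steps, then
#' runs `n_prod` production steps with the full parameter set. Unwrapped cell
#' positions are recorded every `stride` steps and summarised into time
#' series of mean cell speed (lagged displacements over one recording stride,
#' in `r0/tau0`) and the instantaneous order parameter (IOP, the magnitude of
#' the mean unit-velocity vector). Steady-state means are taken over the
#' final half of the production run.
#'
#' @param params a [model_params()] object.
#' @param n_equil number of passive equilibration steps.
#' @param n_prod number of production steps.
#' @param seed optional integer seed (same seed, same summary).
#' @param stride recording stride in steps; also the speed lag, matching a
#'   100-step lag at the default `stride = 100`.
#' @return An object of class `sim_summary`: list with `time` (production
#'   time of each speed sample), `mean_speed`, `iop`, steady-state means
#'   `steady_speed` and `steady_iop`, the trajectory array `traj`
#'   (samples x N x 2, unwrapped), `params` and bookkeeping fields.
#' @examples
#' \donttest{
#' s <- simulate_sheet(model_params(N = 64), n_equil = 200, n_prod = 400,
#'                     seed = 1)
#' s$steady_speed
#' }
#' @export
simulate_sheet <- function(params, n_equil = 10000, n_prod = 20000,
                           seed = NULL, stride = 100) {
  stopifnot(n_equil >= 0, n_prod >= stride, stride >= 1)
  if (!is.null(seed)) set.seed(seed)
  state <- init_sheet_state(params)
  if (n_equil > 0) {
    eq <- cpp_spv_run(state$positions, state$disp, state$theta, params$L,
                      params$K_A, params$K_p, params$A0, params$p0,
                      params$mu, 0, params$tau_V, 0, params$D_r, params$dt,
                      n_equil, 0L)
    state$positions <- eq$positions
    state$disp <- eq$disp
    state$theta <- eq$theta
  }
  pr <- cpp_spv_run(state$positions, state$disp, state$theta, params$L,
                    params$K_A, params$K_p, params$A0, params$p0,
                    params$mu, params$v0, params$tau_V, params$R_V,
                    params$D_r, params$dt, n_prod, as.integer(stride))
  n_samples <- nrow(pr$traj)
  N <- params$N
  # prepend production-start positions so speeds cover the whole run
  traj <- array(rbind(c(state$positions[, 1], state$positions[, 2]), pr$traj),
                dim = c(n_samples + 1, N, 2))
  sample_dt <- stride * params$dt
  speed <- avg_speed(traj, sample_dt)
  iop <- iop_sim(traj, sample_dt)
  time <- (seq_len(n_samples)) * sample_dt  # time of each lagged sample
  steady <- time > (n_prod * params$dt) / 2
  out <- list(time = time, mean_speed = speed, iop = iop,
              steady_speed = mean(speed[steady]),
              steady_iop = mean(iop[steady], na.rm = TRUE),
              traj = traj, sample_dt = sample_dt, params = params,
              n_equil = n_equil, n_prod = n_prod, stride = stride,
              seed = seed)
  class(out) <- "sim_summary"
  out
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Voronoi-Vicsek run: N = %d, R_V = %g, v0 = %g\n",
              x$params$N, x$params$R_V, x$params$v0))
  cat(sprintf("  %d equilibration + %d production steps (dt = %g)\n",
              x$n_equil, x$n_prod, x$params$dt))
  cat(sprintf("  steady-state mean speed = %.4f r0/tau0, mean IOP = %.4f\n",
              x$steady_speed, x$steady_iop))
  invisible(x)
}

#' Mean cell speed from a trajectory
#'
#' Computes `v_i(t) = (r_i(t + lag) - r_i(t)) / lag` from unwrapped sampled
#' positions and averages the per-cell speed magnitudes, in `r0/tau0`.
#'
#' @param traj samples x N x 2 array of unwrapped positions.
#' @param sample_dt time between consecutive samples.
#' @param lag_samples displacement lag in samples (default 1, i.e. one
#'   recording stride).
#' @return Vector of mean speeds, one per lagged sample.
#' @export
avg_speed <- function(traj, sample_dt, lag_samples = 1) {
  S <- dim(traj)[1]
  if (lag_samples >= S) stop("lag exceeds trajectory length")
  idx <- seq_len(S - lag_samples)
  dx <- matrix(traj[idx + lag_samples, , 1] - traj[idx, , 1], nrow = length(idx))
  dy <- matrix(traj[idx + lag_samples, , 2] - traj[idx, , 2], nrow = length(idx))
  rowMeans(sqrt(dx^2 + dy^2)) / (lag_samples * sample_dt)
}

#' Instantaneous order parameter of a simulated trajectory
#'
#' The IOP at each sample is the magnitude of the mean unit-velocity vector
#' over all cells whose lagged speed exceeds `eps`; it lies in `[0, 1]`
#' (1 = all cells move in the same direction). Frames with no eligible cell
#' return `NA`.
#'
#' @inheritParams avg_speed
#' @param eps minimal speed (r0/tau0) for a cell's direction to be defined.
#' @return Vector of IOP values, one per lagged sample.
#' @export
iop_sim <- function(traj, sample_dt, lag_samples = 1, eps = 1e-9) {
  S <- dim(traj)[1]
  if (lag_samples >= S) stop("lag exceeds trajectory length")
  idx <- seq_len(S - lag_samples)
  vapply(idx, function(s) {
    dx <- traj[s + lag_samples, , 1] - traj[s, , 1]
    dy <- traj[s + lag_samples, , 2] - traj[s, , 2]
    sp <- sqrt(dx^2 + dy^2) / (lag_samples * sample_dt)
    ok <- sp > eps
    if (!any(ok)) return(NA_real_)
    sqrt(mean(dx[ok] / (sp[ok] * lag_samples * sample_dt))^2 +
         mean(dy[ok] / (sp[ok] * lag_samples * sample_dt))^2)
  }, numeric(1))
}

#' Sweep the Vicsek radius
#'
#' Runs independent seeded simulations for each value of the Vicsek radius
#' and summarises the steady-state mean speed and mean IOP per radius
#' (steady state = final half of production).
#'
#' @param params a [model_params()] object; `R_V` is overridden per run.
#' @param rv_values vector of Vicsek radii.
#' @param n_runs independent runs per radius.
#' @param seed integer seed controlling the whole sweep.
#' @param n_equil,n_prod,stride passed to [simulate_sheet()].
#' @return An object of class `rv_sweep`: list with `runs` (one row per run:
#'   `R_V`, `run`, `seed`, `mean_speed`, `mean_iop`) and `summary` (per
#'   radius: mean and sd of both observables over runs).
#' @export
rv_sweep <- function(params, rv_values, n_runs = 3, seed = 1,
                     n_equil = 10000, n_prod = 20000, stride = 100) {
  stopifnot(length(rv_values) >= 1, n_runs >= 1)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 length(rv_values) * n_runs),
                      nrow = length(rv_values))
  rows <- list()
  for (k in seq_along(rv_values)) {
    pk <- params
    pk$R_V <- rv_values[k]
    for (r in seq_len(n_runs)) {
      s <- simulate_sheet(pk, n_equil = n_equil, n_prod = n_prod,
                          seed = run_seeds[k, r], stride = stride)
      rows[[length(rows) + 1]] <-
        data.frame(R_V = rv_values[k], run = r, seed = run_seeds[k, r],
                   mean_speed = s$steady_speed, mean_iop = s$steady_iop)
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(runs, runs$R_V), function(d) {
    data.frame(R_V = d$R_V[1],
               mean_speed = mean(d$mean_speed), sd_speed = stats::sd(d$mean_speed),
               mean_iop = mean(d$mean_iop), sd_iop = stats::sd(d$mean_iop))
  }))
  summ <- summ[order(summ$R_V), ]
  rownames(summ) <- NULL
  out <- list(runs = runs, summary = summ)
  class(out) <- "rv_sweep"
  out
}

#' @export
print.rv_sweep <- function(x, ...) {
  cat("Vicsek-radius sweep (steady-state means over runs)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
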