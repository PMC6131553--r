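#' Model parameters for the hybrid Voronoi-Vicsek monolayer simulation
#'
#' Collects the parameters of the active confluent-tissue model: cells are
#' Voronoi regions of their centres in a periodic square box, interact through
#' an area/perimeter shape energy, self-propel along a polarization vector,
#' and align their polarization with the velocities of neighbouring cells
#' through a Vicsek-type rule.
#'
#' Lengths are measured in units of `r0 = sqrt(A0)` and times in units of
#' `tau0 = 1/(mu * K_A * A0)`; with the defaults (`A0 = 1`, `mu = 1`,
#' `K_A = 1`) both units are 1 and all quantities are dimensionless.
#' The box side is `L = sqrt(N * A0)`, so the mean cell area is always `A0`.
#'
#' @param N number of cells.
#' @param K_A area stiffness (energy / length^4).
#' @param K_p perimeter stiffness (energy / length^2).
#' @param A0 preferred cell area (length^2).
#' @param p0 preferred cell perimeter (length). The default gives the shape
#'   index `p0 / sqrt(A0) = 4.0`.
#' @param mu mobility (length^2 / (energy * time)).
#' @param v0 self-propulsion speed (length / time); 0 switches activity off.
#' @param tau_V alignment persistence time of the Vicsek coupling.
#' @param R_V Vicsek radius: centre-to-centre distance within which neighbour
#'   velocity directions are averaged. 0 disconnects the cells.
#' @param D_r rotational noise strength (1 / time). Each step the polarization
#'   angle receives a Gaussian increment of variance `2 * D_r * dt`.
#' @param dt integration time step.
#'
#' @return An object of class `model_params`: a list with the above fields
#'   plus the derived `r0`, `tau0` and box side `L`.
#' @examples
#' p <- model_params(N = 64)
#' p$L # sqrt(64) = 8
#' @export
model_params <- function(N = 1000, K_A = 1, K_p = 1, A0 = 1,
                         p0 = 4 * sqrt(A0), mu = 1, v0 = 0.5, tau_V = 1,
                         R_V = 0, D_r = 1.5, dt = 0.001) {
  stopifnot(N >= 3, K_A > 0, K_p > 0, A0 > 0, p0 > 0, mu >= 0, tau_V > 0,
            dt > 0, v0 >= 0, R_V >= 0, D_r >= 0)
  p <- list(N = as.integer(N), K_A = K_A, K_p = K_p, A0 = A0, p0 = p0,
            mu = mu, v0 = v0, tau_V = tau_V, R_V = R_V, D_r = D_r, dt = dt,
            r0 = sqrt(A0), tau0 = 1 / (mu * K_A * A0), L = sqrt(N * A0))
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Voronoi-Vicsek model parameters\n")
  cat(sprintf("  N = %d cells, box L = %.4g (periodic)\n", x$N, x$L))
  cat(sprintf("  K_A = %g, K_p = %g, A0 = %g, p0 = %g (p0/sqrt(A0) = %.3g)\n",
              x$K_A, x$K_p, x$A0, x$p0, x$p0 / sqrt(x$A0)))
  cat(sprintf("  mu = %g, v0 = %g, tau_V = %g, R_V = %g, D_r = %g, dt = %g\n",
              x$mu, x$v0, x$tau_V, x$R_V, x$D_r, x$dt))
  cat(sprintf("  units: r0 = %g, tau0 = %g\n", x$r0, x$tau0))
  invisible(x)
}

#' Initialize the simulation state
#'
#' Places `N` cells uniformly at random in the periodic box and draws uniform
#' random polarization angles, using the current RNG state. A tiny positional
#' jitter (1e-9 r0) is always included implicitly by the uniform draw; for
#' deterministic lattice configurations see [sheet_state()].
#'
#' @param params a [model_params()] object.
#' @return A `sheet_state` object: list with `positions` (N x 2, wrapped into
#'   `[0, L)`), `disp` (N x 2 displacements of the previous step, zero at
#'   start), `theta` (polarization angles, radians) and time `t`.
#' @export
init_sheet_state <- function(params) {
  N <- params$N
  sheet_state(cbind(stats::runif(N, 0, params$L), stats::runif(N, 0, params$L)),
              theta = stats::runif(N, -pi, pi), L = params$L)
}

#' Construct a simulation state from explicit positions
#'
#' @param positions N x 2 matrix of cell centres; wrapped into the box.
#' @param theta polarization angles in radians (default 0).
#' @param L periodic box side.
#' @param disp N x 2 matrix of previous-step displacements (defines the
#'   neighbour velocity angles of the alignment rule); zero by default, in
#'   which case the alignment term is absent on the first step.
#' @param t current time.
#' @return A `sheet_state` object.
#' @export
sheet_state <- function(positions, theta = NULL, L, disp = NULL, t = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, nrow(positions) >= 3, L > 0,
            all(is.finite(positions)))
  positions <- positions %% L
  N <- nrow(positions)
  if (is.null(theta)) theta <- numeric(N)
  if (is.null(disp)) disp <- matrix(0, N, 2)
  stopifnot(length(theta) == N, nrow(disp) == N, ncol(disp) == 2)
  s <- list(positions = positions, disp = as.matrix(disp),
            theta = as.numeric(theta), L = L, t = t)
  class(s) <- "sheet_state"
  s
}
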