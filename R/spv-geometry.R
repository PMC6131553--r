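#' Periodic Voronoi geometry of a cell sheet
#'
#' Computes, for every cell centre, the area, perimeter and neighbour list of
#' its Voronoi region on the torus `[0, L)^2`. Polygons are built by clipping
#' with perpendicular bisectors of nearby generators (including periodic
#' images), processed nearest-first with an exactness guarantee, so areas and
#' perimeters are exact for the returned polygons and the regions tile the
#' box: `sum(area) == L^2` up to round-off.
#'
#' @param positions N x 2 matrix of cell centres (N >= 3); wrapped into the
#'   box if outside.
#' @param L periodic box side.
#' @param polygons if `TRUE`, also return each cell's vertex list (CCW, in
#'   global coordinates relative to the cell centre's image).
#' @return A list of class `sheet_geometry` with `area`, `perimeter`,
#'   `neighbors` (list of integer vectors, 1-based) and optionally `polygons`.
#' @examples
#' # 2 x 2 square lattice in a box of side 2: unit-square cells
#' pos <- as.matrix(expand.grid(c(0.5, 1.5), c(0.5, 1.5)))
#' g <- periodic_voronoi_geometry(pos, L = 2)
#' g$area      # all 1
#' g$perimeter # all 4
#' @export
periodic_voronoi_geometry <- function(positions, L, polygons = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2, nrow(positions) >= 3, L > 0,
            all(is.finite(positions)))
  positions <- positions %% L
  .check_duplicates(positions, L)
  g <- cpp_voronoi_geometry(positions, L, polygons)
  g$L <- L
  class(g) <- "sheet_geometry"
  g
}

.check_duplicates <- function(positions, L, tol = 1e-12) {
  n <- nrow(positions)
  if (n > 4000) return(invisible())  # O(n^2) check only at analysis scale
  dx <- outer(positions[, 1], positions[, 1], "-")
  dy <- outer(positions[, 2], positions[, 2], "-")
  dx <- dx - L * round(dx / L)
  dy <- dy - L * round(dy / L)
  d2 <- dx^2 + dy^2
  diag(d2) <- Inf
  if (min(d2) < tol^2)
    stop("duplicate cell positions (coincident generators) are not allowed")
  invisible()
}

#' Area/perimeter shape energy of a cell sheet
#'
#' The tissue energy is the double-quadratic functional
#' `E = sum_j K_A (A_j - A0)^2 + K_p (p_j - p0)^2`
#' over all cells, penalising deviations of each Voronoi cell's area `A_j`
#' and perimeter `p_j` from the preferred values `A0` and `p0`.
#'
#' @param geometry a `sheet_geometry` from [periodic_voronoi_geometry()], or
#'   any list with `area` and `perimeter` vectors.
#' @param params a [model_params()] object (uses `K_A`, `K_p`, `A0`, `p0`).
#' @return The scalar energy.
#' @export
sheet_energy <- function(geometry, params) {
  stopifnot(length(geometry$area) == length(geometry$perimeter))
  sum(params$K_A * (geometry$area - params$A0)^2 +
      params$K_p * (geometry$perimeter - params$p0)^2)
}

#' Analytic forces on cell centres
#'
#' Returns `F_i = -grad_i E` for the shape energy of [sheet_energy()],
#' computed analytically by chaining the energy gradient with respect to the
#' Voronoi vertices through the circumcenter of each vertex's generating
#' triple of cell centres (minimum-image convention throughout). Forces sum
#' to zero by translation invariance.
#'
#' @param positions N x 2 matrix of cell centres, or a `sheet_state`.
#' @param params a [model_params()] object; the box side is `params$L`.
#' @return A list with `force` (N x 2), `area` and `perimeter`.
#' @export
sheet_forces <- function(positions, params) {
  if (inherits(positions, "sheet_state")) positions <- positions$positions
  positions <- as.matrix(positions) %% params$L
  stopifnot(nrow(positions) == params$N)
  .check_duplicates(positions, params$L)
  cpp_sheet_forces(positions, params$L, params$K_A, params$K_p,
                   params$A0, params$p0)
}
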