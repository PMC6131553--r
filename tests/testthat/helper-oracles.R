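# Shared independent oracles and fixture builders for the test suite.

# Central finite-difference gradient of the sheet energy; the independent
# reference for the analytic forces.
fd_forces <- function(positions, params, h = 1e-6) {
  E <- function(x) sheet_energy(periodic_voronoi_geometry(x, params$L), params)
  F <- matrix(0, nrow(positions), 2)
  for (i in seq_len(nrow(positions))) {
    for (d in 1:2) {
      xp <- positions; xp[i, d] <- xp[i, d] + h
      xm <- positions; xm[i, d] <- xm[i, d] - h
      F[i, d] <- -(E(xp) - E(xm)) / (2 * h)
    }
  }
  F
}

# Naive double-loop fixed-lag MSD, computed straight from the definition.
naive_msd <- function(tracks, lag_min, min_spots) {
  fi <- attr(tracks, "frame_interval")
  lagf <- as.integer(round(lag_min / fi))
  ids <- names(which(table(tracks$track_id) >= min_spots))
  acc <- list()
  for (id in ids) {
    d <- tracks[tracks$track_id == id, ]
    for (i in seq_len(nrow(d))) {
      j <- which(d$frame == d$frame[i] + lagf)
      if (length(j) == 1) {
        t0 <- as.character(d$t_min[i])
        acc[[t0]] <- c(acc[[t0]],
                       (d$x_um[j] - d$x_um[i])^2 + (d$y_um[j] - d$y_um[i])^2)
      }
    }
  }
  ts <- sort(as.numeric(names(acc)))
  data.frame(t_min = ts,
             msd_um2 = vapply(as.character(ts), function(k) mean(acc[[k]]),
                              numeric(1)))
}

# Monte-Carlo expectation of |mean of k iid random unit vectors|.
iid_resultant_mean <- function(k, n_rep = 2000) {
  mean(vapply(seq_len(n_rep), function(i) {
    a <- runif(k, -pi, pi)
    sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  }, numeric(1)))
}

# Square lattice of m x m cells filling a box of side m * a.
square_lattice <- function(m, a = 1) {
  g <- expand.grid(x = (seq_len(m) - 0.5) * a, y = (seq_len(m) - 0.5) * a)
  as.matrix(g)
}

# Patch of a triangular lattice whose Voronoi cells are unit-area regular
# hexagons (for interior points).  Returned with the indices of points at
# least two rows/columns away from the patch border.
hex_patch <- function(nx = 10, ny = 10) {
  ax <- sqrt(2 / sqrt(3))    # lattice constant giving unit cell area
  ay <- ax * sqrt(3) / 2
  pts <- do.call(rbind, lapply(seq_len(ny) - 1, function(r) {
    cbind(((seq_len(nx) - 1) + 0.5 * (r %% 2)) * ax, r * ay)
  }))
  row_id <- rep(seq_len(ny) - 1, each = nx)
  col_id <- rep(seq_len(nx) - 1, times = ny)
  interior <- which(row_id >= 2 & row_id <= ny - 3 &
                    col_id >= 2 & col_id <= nx - 3)
  list(positions = pts, interior = interior)
}
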