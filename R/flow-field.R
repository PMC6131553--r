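#' Gridded velocity field
#'
#' Container for one frame of PIV-type output: rasters of the two velocity
#' components on a regular grid of interrogation windows, a validity mask,
#' and the physical scales. Masked entries are excluded from every statistic
#' in the package.
#'
#' @param U,V numeric matrices of velocity components (rows x cols windows).
#' @param mask logical matrix, `TRUE` = valid window. Default all valid.
#' @param window_spacing physical distance between adjacent windows (um).
#' @param frame_interval time between the two frames the field was estimated
#'   from (min).
#' @param units unit label for U and V (recorded, not converted).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(U, V, mask = NULL, window_spacing = 1,
                           frame_interval = 1, units = "um/h") {
  U <- as.matrix(U); V <- as.matrix(V)
  stopifnot(all(dim(U) == dim(V)), window_spacing > 0, frame_interval > 0)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(U), ncol(U))
  mask <- as.matrix(mask)
  stopifnot(all(dim(mask) == dim(U)), is.logical(mask))
  f <- list(U = U, V = V, mask = mask, window_spacing = window_spacing,
            frame_interval = frame_interval, units = units)
  class(f) <- "velocity_field"
  f
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d windows (%d masked), spacing %g um, interval %g min\n",
              nrow(x$U), ncol(x$U), sum(!x$mask), x$window_spacing,
              x$frame_interval))
  invisible(x)
}

#' Temporal median filter over a frame stack
#'
#' Replaces each pixel by the median of its values in `bin` consecutive
#' frames (frames `n .. n + bin - 1`), removing impulse noise from
#' free-floating objects. The output stack has `length(frames) - bin + 1`
#' elements. For `velocity_field` input the filter is applied to both
#' components and the masks of the bin are intersected.
#'
#' @param frames a list of numeric matrices, or of [velocity_field()]s.
#' @param bin window width in frames (default 3).
#' @return A list of the same type as the input.
#' @export
temporal_median <- function(frames, bin = 3) {
  stopifnot(is.list(frames), bin >= 1)
  if (length(frames) < bin) stop("need at least `bin` frames")
  n_out <- length(frames) - bin + 1
  is_field <- inherits(frames[[1]], "velocity_field")
  med_stack <- function(mats) {
    a <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
    apply(a, c(1, 2), stats::median)
  }
  lapply(seq_len(n_out), function(i) {
    sel <- frames[i:(i + bin - 1)]
    if (!is_field) return(med_stack(sel))
    f <- sel[[1]]
    velocity_field(U = med_stack(lapply(sel, `[[`, "U")),
                   V = med_stack(lapply(sel, `[[`, "V")),
                   mask = Reduce(`&`, lapply(sel, `[[`, "mask")),
                   window_spacing = f$window_spacing,
                   frame_interval = f$frame_interval, units = f$units)
  })
}

#' Speed map of a velocity field
#'
#' Computes the magnitude raster `M = sqrt(U^2 + V^2)`, passes it through a
#' spatial median filter (masked entries ignored, default 5 x 5 window), and
#' reports the frame mean over unmasked windows.
#'
#' @param field a [velocity_field()].
#' @param size side of the square median-filter window (odd, default 5).
#' @return A list with `M` (raw magnitudes, masked entries `NA`),
#'   `M_filtered` (median-filtered magnitudes) and `frame_mean` (mean of the
#'   filtered speeds over unmasked windows; `NA` if fully masked).
#' @examples
#' f <- velocity_field(U = matrix(3, 8, 8), V = matrix(4, 8, 8))
#' speed_field(f)$frame_mean # 5
#' @export
speed_field <- function(field, size = 5) {
  stopifnot(inherits(field, "velocity_field"), size >= 1, size %% 2 == 1)
  M <- sqrt(field$U^2 + field$V^2)
  M[!field$mask] <- NA_real_
  Mf <- masked_median_filter(M, size)
  ok <- field$mask & is.finite(Mf)
  frame_mean <- if (any(ok)) mean(Mf[ok]) else NA_real_
  list(M = M, M_filtered = Mf, frame_mean = frame_mean)
}

# Spatial median filter that ignores NA (masked) entries; edges use the
# available part of the window.
masked_median_filter <- function(M, size) {
  r <- (size - 1) / 2
  nr <- nrow(M); nc <- ncol(M)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  vals <- matrix(NA_real_, nr * nc, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    src_r <- seq_len(nr) + dr
    src_c <- seq_len(nc) + dc
    ok_r <- src_r >= 1 & src_r <= nr
    ok_c <- src_c >= 1 & src_c <= nc
    shifted <- matrix(NA_real_, nr, nc)
    shifted[ok_r, ok_c] <- M[src_r[ok_r], src_c[ok_c]]
    vals[, k] <- as.vector(shifted)
  }
  out <- apply(vals, 1, stats::median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  matrix(out, nr, nc)
}

#' Instantaneous order parameter of a velocity field
#'
#' The IOP is the magnitude of the mean unit-velocity vector over all
#' unmasked windows with nonzero speed: 1 for perfectly aligned flow,
#' near `1/sqrt(n)` for disordered flow.
#'
#' @param field a [velocity_field()].
#' @return A scalar in `[0, 1]`, or `NA` if no eligible vector exists.
#' @export
iop_frame <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  sp <- sqrt(field$U^2 + field$V^2)
  ok <- field$mask & sp > 0
  if (!any(ok)) return(NA_real_)
  sqrt(mean(field$U[ok] / sp[ok])^2 + mean(field$V[ok] / sp[ok])^2)
}

#' Tail probability of an n-sigma significance level
#'
#' Upper-tail standard-normal probability at `z = n_sigma`; the significance
#' level attached to the 5-sigma correlation-length criterion
#' (`sigma_tail_prob(5)` is about 3e-7).
#'
#' @param n_sigma number of standard deviations.
#' @return The one-sided tail probability.
#' @export
sigma_tail_prob <- function(n_sigma = 5) {
  stats::pnorm(n_sigma, lower.tail = FALSE)
}
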