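#' Daughter-pair organelle counts
#'
#' Per-division counts of cytoplasmic PML/nucleoporin bodies (CyPNs) in the
#' two daughter cells. Divisions with zero total bodies carry no information
#' about partitioning and are excluded from the observed asymmetry fraction
#' and the model fit.
#'
#' @param count1,count2 non-negative integer vectors of equal length.
#' @param division_id optional identifiers.
#' @return A data.frame of class `daughter_pair_counts` with `division_id`,
#'   `count1`, `count2`, `total` and the indicator `complete_asym` (all
#'   bodies in one daughter).
#' @export
daughter_pair_counts <- function(count1, count2, division_id = NULL) {
  stopifnot(length(count1) == length(count2), all(count1 >= 0),
            all(count2 >= 0))
  if (is.null(division_id)) division_id <- seq_along(count1)
  d <- data.frame(division_id = division_id,
                  count1 = as.integer(count1), count2 = as.integer(count2))
  d$total <- d$count1 + d$count2
  d$complete_asym <- d$total > 0 & (d$count1 == 0 | d$count2 == 0)
  class(d) <- c("daughter_pair_counts", "data.frame")
  d
}

#' Probability of complete asymmetric inheritance
#'
#' Under the binomial partitioning model each of the `n` bodies of a
#' division is assigned independently to one fixed daughter with
#' probability `p_sym`; the probability that all of them end up in a single
#' daughter is `p_sym^n + (1 - p_sym)^n`. At `p_sym = 0.5` (unbiased,
#' completely symmetric partitioning) this is `2^(1 - n)`.
#'
#' @param n total body count per division (vectorized, `n >= 1`).
#' @param p_sym per-body assignment probability in (0, 1).
#' @return Probability of complete asymmetry for each `n`.
#' @examples
#' p_complete_asym(3, 0.5)  # 0.25
#' p_complete_asym(5, 0.2)  # 0.8^5 + 0.2^5 = 0.328
#' @export
p_complete_asym <- function(n, p_sym) {
  stopifnot(all(n >= 1), n == round(n), p_sym > 0, p_sym < 1)
  p_sym^n + (1 - p_sym)^n
}

#' Maximum-likelihood fit of the partition parameter
#'
#' Fits `p_sym` by maximizing the Bernoulli likelihood of the observed
#' complete-asymmetry indicators, each division contributing success
#' probability `p_complete_asym(n_i, p)` given its total body count.
#' The likelihood is symmetric under `p <-> 1 - p`; the reported estimate is
#' the branch with `p <= 0.5`. Zero-total divisions are excluded.
#'
#' @param data a [daughter_pair_counts()].
#' @param lower search floor for `p_sym` (boundary flagging threshold).
#' @return A list of class `partition_model`: `p_sym`, `log_lik`,
#'   `n_divisions`, `boundary` (estimate at the search floor),
#'   `identifiable` (`FALSE` when all totals are 1, where the likelihood is
#'   flat), and `curve`, the fitted `P(complete asymmetry | n)` for
#'   `n = 1..max(total)`.
#' @export
fit_psym <- function(data, lower = 1e-4) {
  stopifnot(inherits(data, "daughter_pair_counts"))
  d <- data[data$total > 0, ]
  if (nrow(d) == 0) stop("no division with at least one body")
  identifiable <- any(d$total > 1)
  nll <- function(p) {
    pr <- p_complete_asym(d$total, p)
    -sum(ifelse(d$complete_asym, log(pr), log1p(-pr)))
  }
  if (!identifiable) {
    est <- 0.5
    boundary <- FALSE
    warning("all totals are 1: p_sym is not identifiable")
  } else {
    opt <- stats::optimize(nll, c(lower, 0.5))
    est <- opt$minimum
    # optimize() never returns the exact endpoints; snap when the boundary
    # is at least as likely as the interior optimum
    if (nll(lower) <= opt$objective + 1e-10) est <- lower
    boundary <- est <= lower * (1 + 1e-6)
  }
  nmax <- max(d$total)
  out <- list(p_sym = est, log_lik = -nll(est), n_divisions = nrow(d),
              boundary = boundary, identifiable = identifiable,
              curve = data.frame(n = seq_len(nmax),
                                 p_complete = p_complete_asym(seq_len(nmax),
                                                              est)))
  class(out) <- "partition_model"
  out
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("Binomial partition model: p_sym = %.4f (n = %d divisions)\n",
              x$p_sym, x$n_divisions))
  if (x$boundary) cat("  note: estimate at the search boundary\n")
  if (!x$identifiable) cat("  note: non-identifiable (all totals = 1)\n")
  invisible(x)
}

#' Observed fraction of completely asymmetric divisions
#'
#' @param data a [daughter_pair_counts()].
#' @return A list with `fraction` (complete-asymmetric among divisions with
#'   at least one body), `se` (binomial standard error), `n_asym` and
#'   `n_eligible`.
#' @export
observed_asym_fraction <- function(data) {
  stopifnot(inherits(data, "daughter_pair_counts"))
  d <- data[data$total > 0, ]
  if (nrow(d) == 0) stop("no eligible division")
  f <- mean(d$complete_asym)
  list(fraction = f, se = sqrt(f * (1 - f) / nrow(d)),
       n_asym = sum(d$complete_asym), n_eligible = nrow(d))
}

#' Monte-Carlo test for excess complete asymmetry
#'
#' Tests whether the observed number of completely asymmetric divisions
#' exceeds what unbiased binomial partitioning predicts. Under the null each
#' division `i` is complete-asymmetric with probability
#' `p_complete_asym(n_i, p_null)` given its total `n_i`; the null
#' distribution of the asymmetric count is resampled `n_mc` times and the
#' exceedance probability is the add-one-corrected fraction of resamples
#' with a count at least as large as observed:
#' `(1 + #\{T_mc >= T_obs\}) / (n_mc + 1)`.
#'
#' @param data a [daughter_pair_counts()].
#' @param p_null partition probability under the null (default 0.5).
#' @param n_mc number of Monte-Carlo resamples (>= 100).
#' @param seed optional seed; same seed gives an identical exceedance.
#' @return A list with `p_value`, `observed` (asymmetric count),
#'   `expected` (null mean), `n_eligible`, `n_mc`.
#' @export
asym_excess_test <- function(data, p_null = 0.5, n_mc = 10000, seed = NULL) {
  stopifnot(inherits(data, "daughter_pair_counts"))
  if (n_mc < 100) stop("n_mc must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  d <- data[data$total > 0, ]
  if (nrow(d) == 0) stop("no eligible division")
  obs <- sum(d$complete_asym)
  # group by total: the null count is a sum of independent binomials
  tab <- table(d$total)
  sizes <- as.integer(tab)
  probs <- p_complete_asym(as.integer(names(tab)), p_null)
  t_mc <- rep(0L, n_mc)
  for (g in seq_along(sizes))
    t_mc <- t_mc + stats::rbinom(n_mc, sizes[g], probs[g])
  list(p_value = (1 + sum(t_mc >= obs)) / (n_mc + 1),
       observed = obs, expected = sum(sizes * probs),
       n_eligible = nrow(d), n_mc = n_mc)
}
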