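test_that("every generator is a pure function of its spec (seed determinism)", {
  f1 <- gen_gridded_flow(flow_spec(grid_shape = c(12, 12), n_frames = 2,
                                   seed = 5))
  f2 <- gen_gridded_flow(flow_spec(grid_shape = c(12, 12), n_frames = 2,
                                   seed = 5))
  expect_identical(f1, f2)
  v1 <- gen_vicsek_particles(50, 5, n_steps = 3, noise_width = 40, seed = 8)
  v2 <- gen_vicsek_particles(50, 5, n_steps = 3, noise_width = 40, seed = 8)
  expect_identical(v1, v2)
  t1 <- gen_tracks(track_spec(kind = "persistent", seed = 3))
  t2 <- gen_tracks(track_spec(kind = "persistent", seed = 3))
  expect_identical(t1, t2)
  a1 <- gen_division_angles(40, 30, 2, seed = 9)
  a2 <- gen_division_angles(40, 30, 2, seed = 9)
  expect_identical(a1, a2)
  i1 <- gen_inheritance_counts(partition_spec(seed = 11))
  i2 <- gen_inheritance_counts(partition_spec(seed = 11))
  expect_identical(i1, i2)
  n1 <- gen_premitotic_track(seed = 13)
  n2 <- gen_premitotic_track(seed = 13)
  expect_identical(n1, n2)
})

test_that("gridded flow: exact magnitude, zero-noise alignment, decorrelation at scale 0", {
  f <- gen_gridded_flow(flow_spec(grid_shape = c(16, 16), speed_mean = 20,
                                  angular_noise_sd = 45,
                                  correlation_scale = 2, seed = 1))[[1]]
  expect_lt(max(abs(sqrt(f$U^2 + f$V^2) - 20)), 1e-12)
  # zero noise: every vector exactly at the base angle
  f0 <- gen_gridded_flow(flow_spec(grid_shape = c(8, 8), base_angle = 30,
                                   angular_noise_sd = 0,
                                   correlation_scale = 3, speed_mean = 10,
                                   seed = 2))[[1]]
  ang <- atan2(f0$V, f0$U) * 180 / pi
  expect_equal(ang, matrix(30, 8, 8), tolerance = 1e-9)
  # scale 0, large noise: neighbouring angles uncorrelated
  fr <- gen_gridded_flow(flow_spec(grid_shape = c(100, 100),
                                   angular_noise_sd = 1e4,
                                   correlation_scale = 0, seed = 3))[[1]]
  a <- atan2(fr$V, fr$U)
  x <- cos(a[, -100]) * cos(a[, -1]) + sin(a[, -100]) * sin(a[, -1])
  expect_lt(abs(mean(x)), 3 / sqrt(length(x)) + 0.01)
  expect_error(gen_gridded_flow(flow_spec(grid_shape = c(0, 4))))
})

test_that("Vicsek particles: noiseless global coupling aligns, radius 0 stays disordered", {
  fr <- gen_vicsek_particles(n = 200, box = 10, speed = 0.05,
                             radius = 15, noise_width = 0, n_steps = 4,
                             seed = 1)
  expect_equal(iop_frame(fr[[4]]), 1, tolerance = 1e-9)
  # radius 0: headings independent; rasterized IOP at the n^-1/2 scale.
  # Oracle: iid headings pushed through the same rasterization.
  n <- 400
  iop_gen <- vapply(1:25, function(s) {
    f <- gen_vicsek_particles(n, 10, 0.05, radius = 0, noise_width = 360,
                              n_steps = 3, seed = 600 + s)
    iop_frame(f[[3]])
  }, numeric(1))
  set.seed(99)
  iop_iid <- vapply(1:25, function(s) {
    pos <- cbind(runif(n, 0, 10), runif(n, 0, 10))
    a <- runif(n, -pi, pi)
    br <- pmin(floor(pos[, 2]) + 1, 10); bc <- pmin(floor(pos[, 1]) + 1, 10)
    key <- (bc - 1) * 16 + br
    U <- tapply(cos(a), key, mean); V <- tapply(sin(a), key, mean)
    sqrt(mean(U / sqrt(U^2 + V^2))^2 + mean(V / sqrt(U^2 + V^2))^2)
  }, numeric(1))
  se <- sqrt(sd(iop_gen)^2 / 25 + sd(iop_iid)^2 / 25)
  expect_lt(abs(mean(iop_gen) - mean(iop_iid)), 4 * se + 0.02)
  expect_lt(mean(iop_gen), 0.3)
  expect_error(gen_vicsek_particles(10, 5, radius = -1), "radius")
})

test_that("track archetypes have their closed-form end-to-end displacements", {
  # ballistic: end-to-end distance = speed * duration exactly
  tb <- gen_tracks(track_spec(kind = "ballistic", n_tracks = 4,
                              n_frames = 25, frame_interval = 15,
                              speed = 20, seed = 5))
  sm <- track_motility_summary(tb)
  expect_equal(sm$euclidean_um, rep(20 * 24 * 15 / 60, 4), tolerance = 1e-9)
  # alternating: cancellation over an even number of steps
  ta <- gen_tracks(track_spec(kind = "alternating", n_tracks = 3,
                              n_frames = 21, frame_interval = 15,
                              speed = 20, seed = 6))
  expect_equal(track_motility_summary(ta)$euclidean_um, rep(0, 3),
               tolerance = 1e-9)
  expect_error(gen_tracks(structure(list(kind = "wiggly"),
                                    class = "track_spec")))
})

test_that("division angles: concentration limits and reduction to [0, 360)", {
  a_inf <- gen_division_angles(50, mean_angle = 120, concentration = 500,
                               seed = 1)
  s <- direction_order_stats(a_inf)
  expect_gt(s$magnitude, 0.99)
  expect_lt(abs(s$mean_angle_deg - 120), 3)
  # concentration 0: uniform; magnitude at the n^-1/2 scale
  mags <- vapply(1:30, function(k)
    direction_order_stats(gen_division_angles(400, 0, 0, seed = k))$magnitude,
    numeric(1))
  expect_lt(mean(mags), 3 * sqrt(pi) / (2 * sqrt(400)))
  expect_true(all(a_inf >= 0 & a_inf < 360))
  expect_error(gen_division_angles(0, 0, 1))
})

test_that("von Mises sampler matches the target distribution moments", {
  # mean resultant length of a von Mises sample estimates I1(k)/I0(k)
  k <- 2
  a <- gen_division_angles(20000, mean_angle = 40, concentration = k,
                           seed = 3)
  s <- direction_order_stats(a)
  expect_lt(abs(s$magnitude - besselI(k, 1) / besselI(k, 0)), 0.01)
  expect_lt(abs(s$mean_angle_deg - 40), 1.5)
})

test_that("inheritance counts conserve totals and recover the marginal p_sym", {
  sp <- partition_spec(n_divisions = 4000, p_sym = 0.3, seed = 21)
  d <- gen_inheritance_counts(sp)
  expect_true(all(d$count1 + d$count2 == d$total))
  expect_true(all(d$total %in% 1:6))
  frac <- sum(d$count1) / sum(d$total)
  se <- sqrt(0.3 * 0.7 / sum(d$total))
  expect_lt(abs(frac - 0.3), 3 * se)
  # single-body divisions are complete-asymmetric by construction
  d1 <- gen_inheritance_counts(partition_spec(
    n_divisions = 200, body_count_law = stats::setNames(1, 1), seed = 5))
  expect_true(all(d1$complete_asym))
  # totals of 3 at p = 0.5: asymmetric fraction near 2 * 0.5^3
  d3 <- gen_inheritance_counts(partition_spec(
    n_divisions = 8000, body_count_law = stats::setNames(1, 3),
    p_sym = 0.5, seed = 6))
  expect_lt(abs(mean(d3$complete_asym) - 0.25), 3 * sqrt(0.25 * 0.75 / 8000))
  expect_error(partition_spec(body_count_law = c()))
})

test_that("pre-mitotic series: midpoint rest, drift to the membrane, alignment", {
  # no jitter, no drift: relative position constant at 0.5
  s0 <- gen_premitotic_track(n_frames = 30, frame_interval = 2,
                             drift_onset = 0, jitter_sd = 0, seed = 1)
  p0 <- relative_nuclear_position(s0)
  expect_equal(p0$p, rep(0.5, 30))
  # full drift: reaches the membrane (p = 0) exactly at the final frame
  s1 <- gen_premitotic_track(n_frames = 30, frame_interval = 2,
                             drift_onset = 30, jitter_sd = 0, seed = 2)
  p1 <- relative_nuclear_position(s1)
  expect_equal(p1$p[30], 0)
  expect_equal(p1$p[1], 0.5)
  expect_equal(p1$t_min[30], 0)
  expect_true(all(diff(p1$p[p1$t_min >= -30]) < 0))
  expect_error(gen_premitotic_track(n_frames = 10, frame_interval = 2,
                                    drift_onset = 40))
})
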