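test_that("track_set validates structure and gap-free frames", {
  df <- data.frame(track_id = c(1, 1, 1), frame = c(0, 1, 3),
                   t_min = c(0, 16, 48), x_um = 0, y_um = 0)
  expect_error(track_set(df, 16), "consecutive")
  df$frame <- 0:2
  expect_s3_class(track_set(df, 16), "track_set")
})

test_that("fixed-lag MSD closed forms: ballistic and stationary", {
  tb <- gen_tracks(track_spec(kind = "ballistic", n_tracks = 3,
                              n_frames = 40, frame_interval = 16,
                              speed = 10, seed = 1))
  msd <- fixed_lag_msd(tb, lag_min = 320, min_spots = 19)
  # (10 um/h * 320/60 h)^2 at every time point
  expect_equal(msd$msd_um2, rep((10 * 320 / 60)^2, nrow(msd)),
               tolerance = 1e-9)
  ts <- gen_tracks(track_spec(kind = "stationary", n_tracks = 3,
                              n_frames = 40, frame_interval = 16, seed = 2))
  expect_equal(fixed_lag_msd(ts, 320, 19)$msd_um2,
               rep(0, nrow(msd)))
})

test_that("MSD matches the naive double-loop computation and filters short tracks", {
  set.seed(6)
  specs <- list(
    track_spec(kind = "brownian", n_tracks = 6, n_frames = 30,
               frame_interval = 16, speed = 12, seed = 31),
    track_spec(kind = "persistent", n_tracks = 5, n_frames = 25,
               frame_interval = 16, speed = 8, persistence = 0.6, seed = 32))
  for (sp in specs) {
    tr <- gen_tracks(sp)
    got <- fixed_lag_msd(tr, lag_min = 160, min_spots = 19)
    want <- naive_msd(tr, 160, 19)
    expect_equal(got$t_min, want$t_min)
    expect_equal(got$msd_um2, want$msd_um2, tolerance = 1e-12)
  }
  # tracks below min_spots are discarded entirely
  tr <- gen_tracks(track_spec(kind = "ballistic", n_tracks = 2,
                              n_frames = 10, frame_interval = 16, seed = 3))
  out <- fixed_lag_msd(tr, 32, min_spots = 19)
  expect_equal(nrow(out), 0)
})

test_that("Brownian MSD approaches 4 D lag", {
  # per-frame step s in a random direction: D = s^2 / (4 dt)
  sp <- track_spec(kind = "brownian", n_tracks = 800, n_frames = 24,
                   frame_interval = 16, speed = 12, seed = 77)
  tr <- gen_tracks(sp)
  s <- 12 * 16 / 60
  lag_frames <- 20
  want <- lag_frames * s^2            # = 4 * D * lag
  msd <- fixed_lag_msd(tr, lag_min = 320, min_spots = 19)
  expect_lt(abs(mean(msd$msd_um2) - want) / want, 0.15)
})

test_that("MPI closed forms: straight = 1, alternating = 1/9, window bounds", {
  tb <- gen_tracks(track_spec(kind = "ballistic", n_tracks = 1,
                              n_frames = 30, frame_interval = 8, seed = 4))
  expect_equal(mpi_series(tb, 10), rep(1, 21))
  ta <- gen_tracks(track_spec(kind = "alternating", n_tracks = 1,
                              n_frames = 30, frame_interval = 8, seed = 5))
  # 9 alternating unit vectors: |5 - 4| / 9
  expect_equal(mpi_series(ta, 10), rep(1 / 9, 21), tolerance = 1e-12)
  expect_error(mpi_series(tb[1:5, ], 10), "shorter")
  # stationary: all displacements zero, MPI undefined
  ts <- gen_tracks(track_spec(kind = "stationary", n_tracks = 1,
                              n_frames = 12, frame_interval = 8, seed = 6))
  expect_true(all(is.na(mpi_series(ts, 10))))
})

test_that("MPI is bounded by 1, equals 1 only for identical headings, and matches the iid oracle", {
  set.seed(42)
  vals <- c()
  for (k in 1:200) {
    xy <- apply(matrix(rnorm(22), 11, 2), 2, cumsum)
    m <- mpi_series(xy, 10)
    vals <- c(vals, m)
    expect_true(all(m <= 1 + 1e-12))
  }
  # iid headings, window 10 (9 steps): Monte-Carlo expectation ~ 0.28
  oracle <- iid_resultant_mean(9, 4000)
  expect_lt(abs(mean(vals) - oracle), 0.03)
  expect_lt(abs(oracle - 0.28), 0.03)
})

test_that("mean MPI increases with the persistence parameter", {
  med <- vapply(c(0.1, 0.5, 0.9), function(pers) {
    m <- vapply(1:20, function(s) {
      tr <- gen_tracks(track_spec(kind = "persistent", n_tracks = 1,
                                  n_frames = 40, frame_interval = 8,
                                  persistence = pers, seed = 300 + s))
      mean(mpi_series(tr, 10), na.rm = TRUE)
    }, numeric(1))
    median(m)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  # persistence 1 is exactly ballistic
  tr1 <- gen_tracks(track_spec(kind = "persistent", n_tracks = 1,
                               n_frames = 20, frame_interval = 8,
                               persistence = 1, seed = 9))
  expect_equal(mpi_series(tr1, 10), rep(1, 11))
})

test_that("motility summary: ballistic, alternating and stationary archetypes", {
  tb <- gen_tracks(track_spec(kind = "ballistic", n_tracks = 1,
                              n_frames = 31, frame_interval = 16,
                              speed = 10, seed = 7))
  sb <- track_motility_summary(tb)
  expect_equal(sb$mean_velocity_um_h, 10, tolerance = 1e-9)
  expect_equal(sb$euclidean_um, sb$path_um, tolerance = 1e-9)
  ta <- gen_tracks(track_spec(kind = "alternating", n_tracks = 1,
                              n_frames = 31, frame_interval = 16,
                              speed = 10, seed = 8))
  sa <- track_motility_summary(ta)
  expect_equal(sa$euclidean_um, 0, tolerance = 1e-9)
  expect_equal(sa$mean_velocity_um_h, 10, tolerance = 1e-9)
  ts <- gen_tracks(track_spec(kind = "stationary", n_tracks = 1,
                              n_frames = 31, frame_interval = 16, seed = 9))
  ss <- track_motility_summary(ts)
  expect_equal(ss$euclidean_um, 0)
  expect_equal(ss$mean_velocity_um_h, 0)
})

test_that("direction order statistics match hand-computed cases", {
  s <- direction_order_stats(rep(90, 7))
  expect_equal(s$magnitude, 1)
  expect_equal(s$mean_angle_deg, 90)
  expect_equal(direction_order_stats(c(0, 180))$magnitude, 0,
               tolerance = 1e-12)
  s2 <- direction_order_stats(c(0, 90))
  expect_equal(s2$magnitude, sqrt(2) / 2)
  expect_equal(s2$mean_angle_deg, 45)
  expect_equal(s2$magnitude^2, s2$mean_x^2 + s2$mean_y^2)
  # undefined mean angle at zero magnitude
  expect_true(is.na(direction_order_stats(c(0, 90, 180, 270))$mean_angle_deg))
})

test_that("order statistics: rotation equivariance and axial equivalence", {
  set.seed(14)
  a <- runif(25, 0, 360)
  base <- direction_order_stats(a)
  rot <- direction_order_stats(a + 38)
  expect_equal(rot$magnitude, base$magnitude, tolerance = 1e-12)
  expect_equal((rot$mean_angle_deg - base$mean_angle_deg) %% 360, 38,
               tolerance = 1e-9)
  # axial mode: theta and theta + 180 are the same axis
  ax1 <- direction_order_stats(a, axial = TRUE)
  flip <- a + 180 * rbinom(25, 1, 0.5)
  ax2 <- direction_order_stats(flip, axial = TRUE)
  expect_equal(ax1$magnitude, ax2$magnitude, tolerance = 1e-12)
  expect_equal(direction_order_stats(c(0, 180), axial = TRUE)$magnitude, 1)
})

test_that("rose histogram applies unity-based normalization", {
  r <- rose_histogram(rep(10, 5), n_bins = 4)
  expect_equal(r$height, c(1, 0, 0, 0))
  r2 <- rose_histogram(c(rep(10, 10), rep(200, 30)), n_bins = 2)
  expect_equal(r2$height, c(0, 1))
  expect_equal(sum(r2$count), 40)
  # flat histogram: all zeros by convention
  r3 <- rose_histogram(c(45, 135, 225, 315), n_bins = 4)
  expect_equal(r3$height, rep(0, 4))
})

test_that("relative nuclear position hits 0, 1/2 and 1 in canonical geometries", {
  ser <- data.frame(frame = 0:2, cx = c(0, 15, 30), cy = 0,
                    xx = 0, xy = 0, yx = 30, yy = 0)
  out <- relative_nuclear_position(ser, frame_interval = 2)
  expect_equal(out$p, c(0, 0.5, 1))
  expect_equal(out$t_min, c(-4, -2, 0))   # t = 0 at the last pre-mitotic frame
  # degenerate membrane points are flagged invalid
  bad <- data.frame(frame = 0, cx = 1, cy = 0, xx = 2, xy = 0, yx = 2, yy = 0)
  expect_true(is.na(relative_nuclear_position(bad)$p))
})
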