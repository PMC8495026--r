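test_that("plane enumeration admits coprime harmonics only", {
  expect_length(enumerate_planes(3), 1)
  p9 <- enumerate_planes(9)
  expect_equal(vapply(p9, `[[`, integer(1), "k"), c(1L, 2L, 4L))
  all20 <- enumerate_planes(c(3, 5, 7, 9, 11, 13))
  expect_length(all20, 20)
  expect_error(enumerate_planes(c(3, 4)), "odd")
  # deterministic order: N ascending then k ascending
  nk <- t(vapply(all20, function(p) c(p$N, p$k), integer(2)))
  expect_identical(nk, nk[order(nk[, 1], nk[, 2]), ])
})

test_that("the excluded (9,3) plane reduces to a 3-point construction", {
  # projection with gcd(k, N) = 3 equals 1/sqrt(3) times the 3-point
  # attractor of the period-averaged signal
  expect_lt(verify_plane_reduction(9, 3), 1e-10)
  expect_error(verify_plane_reduction(9, 2), "coprime")
})

test_that("plane bases are orthonormal and baseline-blind", {
  for (pl in enumerate_planes(c(5, 13))) {
    expect_equal(sum(pl$basis_c^2), 1, tolerance = 1e-12)
    expect_equal(sum(pl$basis_s^2), 1, tolerance = 1e-12)
    expect_equal(sum(pl$basis_c * pl$basis_s), 0, tolerance = 1e-12)
    expect_equal(sum(pl$basis_c), 0, tolerance = 1e-12)
    expect_equal(sum(pl$basis_s), 0, tolerance = 1e-12)
  }
})

test_that("delay embedding indexes the signal as specified", {
  dm <- embed_delays(rep(5, 50), 1, 1, 3)
  expect_true(all(dm$rows == 5))
  dm2 <- embed_delays(c(0, 1, 2, 3, 4, 5), 1, 1, 3)
  expect_equal(unname(dm2$rows),
               rbind(c(2, 1, 0), c(3, 2, 1), c(4, 3, 2), c(5, 4, 3)))
  # 10 s at 500 Hz, tau = 1/3 s: d = 167, rows = 5000 - 2*167
  dm3 <- embed_delays(numeric(5000), 500, 1 / 3, 3)
  expect_equal(dm3$d, 167L)
  expect_equal(nrow(dm3$rows), 4666)
  expect_error(embed_delays(numeric(10), 500, 1 / 3, 3), "too short")
})

test_that("projection maps constants to the origin and sinusoids to circles", {
  dm <- embed_delays(rep(2.5, 100), 1, 1, 3)
  cl <- project_attractor(dm, projection_plane(3, 1))
  expect_lt(max(abs(cl$points)), 1e-12)

  A <- 1.7
  for (N in c(3, 5, 9)) {
    fs <- N * 100
    x <- A * cos(2 * pi * (0:(10 * fs - 1)) / fs)
    dm <- embed_delays(x, fs, 1 / N, N)
    cl1 <- project_attractor(dm, projection_plane(N, 1))
    radii <- sqrt(rowSums(cl1$points^2))
    expect_lt(max(abs(radii - A * sqrt(N / 2))) / (A * sqrt(N / 2)), 1e-6)
    if (N >= 5) {
      cl2 <- project_attractor(dm, projection_plane(N, 2))
      expect_lt(max(abs(cl2$points)), 1e-6 * A)
    }
  }
  expect_error(
    project_attractor(embed_delays(rnorm(100), 10, 0.5, 3),
                      projection_plane(5, 1)), "mismatch")
})

test_that("baseline offsets leave the attractor exactly unchanged", {
  set.seed(4)
  x <- cumsum(rnorm(3000)) / 10
  for (pl in enumerate_planes(c(3, 7))) {
    a <- project_attractor(embed_delays(x, 500, 0.07, pl$N), pl)
    b <- project_attractor(embed_delays(x + 11.3, 500, 0.07, pl$N), pl)
    expect_lt(max(abs(a$points - b$points)), 1e-11)
  }
})

test_that("basis projection matches the brute-force trigonometric oracle", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(600)
    N <- sample(c(3, 5, 7), 1)
    k <- sample(seq_len((N - 1) / 2), 1)
    tau <- runif(1, 0.02, 0.1)
    fast <- project_attractor(embed_delays(x, 100, tau, N),
                              projection_plane(N, k))$points
    slow <- brute_force_projection(x, 100, tau, N, k)
    rel <- max(abs(fast - slow)) / max(abs(slow))
    expect_lt(rel, 1e-12)
  }
})

test_that("rasterization produces clipped, normalizable histograms", {
  cl0 <- cloud_from_points(rep(0, 50), rep(0, 50))
  img <- rasterize_attractor(cl0, 20, extent = 1)
  expect_equal(sum(img$grid), 1)
  expect_equal(img$grid[10, 10] + img$grid[11, 11] +
                 img$grid[10, 11] + img$grid[11, 10], 1)

  circ <- circle_cloud(rho = 0.8)
  img2 <- rasterize_attractor(circ, 64, extent = 1)
  expect_equal(sum(img2$grid), 1, tolerance = 1e-12)
  # annulus: center bins empty, occupied bins away from the center
  g <- 64
  centers <- seq(-1, 1, length.out = g + 1)
  centers <- (centers[-1] + centers[-(g + 1)]) / 2
  rad <- sqrt(outer(centers^2, centers^2, "+"))
  expect_equal(sum(img2$grid[rad < 0.5]), 0)
  expect_gt(sum(img2$grid[abs(rad - 0.8) < 0.1]), 0.99)
  # out-of-extent points are clipped into the boundary bins
  imgc <- rasterize_attractor(circle_cloud(rho = 5), 16, extent = 1,
                              normalize = FALSE)
  expect_equal(sum(imgc$grid), 1200)
  interior <- imgc$grid[2:15, 2:15]
  expect_equal(sum(interior), 0)
  expect_error(rasterize_attractor(circ, 8), "grid_size")
  expect_error(rasterize_attractor(cloud_from_points(numeric(0), numeric(0)),
                                   20), "empty")
})

test_that("periodic signals give N-fold rotationally symmetric densities", {
  # spot check one plane; the full 20-plane sweep runs in the acceptance suite
  N <- 5; fs <- N * 100
  p <- synth_params(rr_sd = 0, noise_sd = 0, baseline_amp = 0,
                    heart_rate_bpm = 60, duration = 30, sampling_rate = fs,
                    seed = 2)
  x <- record_lead(synthesize_record(p), "II")
  tcycle <- mean_cycle_length(detect_qrs(x, fs), fs)
  dm <- embed_delays(x, fs, delay_spacing(tcycle, N), N)
  cl <- project_attractor(dm, projection_plane(N, 2))
  ext <- max(abs(cl$points)) * 1.01
  g1 <- rasterize_attractor(cl, 200, ext)$grid
  g2 <- rasterize_attractor(rotate_cloud(cl, 2 * pi / N), 200, ext)$grid
  expect_lt(sum(abs(g1 - g2)), 0.05)
})

test_that("interbeat variability concentrates in the T-to-P sector", {
  p <- synth_params(rr_sd = 0.08, noise_sd = 0, baseline_amp = 0,
                    heart_rate_bpm = 70, duration = 10, seed = 13)
  rec <- synthesize_record(p)
  x <- record_lead(rec, "II")
  fs <- rec$sampling_rate
  tcycle <- mean_cycle_length(detect_qrs(x, fs), fs)
  dm <- embed_delays(x, fs, delay_spacing(tcycle, 3), 3)
  cl <- project_attractor(dm, projection_plane(3, 1))
  pts <- cl$points
  r <- sqrt(rowSums(pts^2))
  th <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  # times (s) of each embedded row, and the midpoints of T-to-P gaps
  t_row <- (seq_len(nrow(pts)) - 1 + 2 * dm$d) / fs
  tpl <- p$template
  gaps_mid <- rec$beat_onsets + (tpl$center[tpl$label == "T"] + 1.1) / 2 *
    (60 / p$heart_rate_bpm)
  in_gap <- vapply(t_row, function(t)
    any(abs(t - gaps_mid) < 0.08), logical(1))
  keep <- r > stats::quantile(r, 0.5)   # the arms, away from the core
  sector <- floor(th / (2 * pi) * 12) + 1
  gap_sector <- as.integer(names(which.max(table(sector[in_gap & keep]))))
  vars <- tapply(r[keep], sector[keep], stats::var)
  expect_gt(vars[[as.character(gap_sector)]], min(vars, na.rm = TRUE))
})
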