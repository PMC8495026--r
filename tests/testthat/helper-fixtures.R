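# Fixtures built in code: small clouds and cached cohorts shared by tests.

# attractor cloud lying exactly on a circle of radius rho
circle_cloud <- function(rho = 1, n = 1200, N = 3L, k = 1L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  structure(list(points = cbind(u = rho * cos(th), v = rho * sin(th)),
                 N = N, k = k, tau = 1 / N, lead = "II"),
            class = "attractor_cloud")
}

cloud_from_points <- function(u, v, N = 3L, k = 1L) {
  structure(list(points = cbind(u = u, v = v), N = N, k = k,
                 tau = 1 / N, lead = "II"),
            class = "attractor_cloud")
}

# independent brute-force projection oracle: explicit per-point
# trigonometric sums, no shared code with project_attractor()
brute_force_projection <- function(x, fs, tau, N, k) {
  d <- round(tau * fs)
  t_idx <- seq.int((N - 1) * d + 1, length(x))
  out <- matrix(NA_real_, length(t_idx), 2)
  for (ii in seq_along(t_idx)) {
    u <- 0; v <- 0
    for (j in 0:(N - 1)) {
      val <- x[t_idx[ii] - j * d]
      u <- u + val * sqrt(2 / N) * cos(2 * pi * j * k / N)
      v <- v + val * sqrt(2 / N) * sin(2 * pi * j * k / N)
    }
    out[ii, ] <- c(u, v)
  }
  out
}

# small labelled cohort with precomputed features, cached across tests
.fixture_env <- new.env(parent = emptyenv())

small_cohort_features <- function() {
  if (is.null(.fixture_env$feat)) {
    cohort <- synthesize_cohort(16, 0.5, seed = 101)
    .fixture_env$cohort <- cohort
    .fixture_env$feat <- cohort_features(
      cohort, leads = c("II", "V3"),
      planes = enumerate_planes(c(3, 5)))
  }
  .fixture_env$feat
}
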