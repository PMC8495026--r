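# Symmetric projection attractor reconstruction: N equally spaced points on
# the signal form an N-dimensional delay vector; projecting onto the plane
# spanned by the discrete-Fourier harmonic-k cosine/sine vectors (both
# orthogonal to the all-ones direction) gives a bounded two-dimensional
# "attractor" that is exactly invariant to baseline offsets.

#' Construct a symmetric projection plane
#'
#' The plane for point count `N` and harmonic `k` is spanned by the
#' orthonormal vectors with components `sqrt(2/N) cos(2 pi j k / N)` and
#' `sqrt(2/N) sin(2 pi j k / N)`, `j = 0..N-1`. Both are orthogonal to the
#' all-ones vector, which is what removes baseline offsets. Planes with
#' `gcd(k, N) > 1` duplicate the structure of a smaller point count (their
#' projection equals, up to scale, a lower-order attractor of a
#' period-averaged signal) and are flagged as not admitted.
#'
#' @param N Odd point count >= 3.
#' @param k Harmonic index in `1..(N-1)/2`.
#' @return A `projection_plane` with fields `N`, `k`, `basis_c`, `basis_s`,
#'   `admitted`.
#' @export
projection_plane <- function(N, k) {
  check_n_points(N)
  if (k < 1 || k > (N - 1) / 2)
    stop("k must be in 1..(N-1)/2, got ", k)
  j <- 0:(N - 1)
  structure(list(
    N = as.integer(N), k = as.integer(k),
    basis_c = sqrt(2 / N) * cos(2 * pi * j * k / N),
    basis_s = sqrt(2 / N) * sin(2 * pi * j * k / N),
    admitted = gcd_int(k, N) == 1L
  ), class = "projection_plane")
}

gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
print.projection_plane <- function(x, ...) {
  cat(sprintf("<projection_plane N=%d k=%d%s>\n", x$N, x$k,
              if (x$admitted) "" else " (not admitted)"))
  invisible(x)
}

#' Enumerate the standard set of projection planes
#'
#' For each odd `N`, planes `k = 1..(N-1)/2` with `gcd(k, N) = 1` are
#' admitted, in deterministic order (N ascending, k ascending). For the
#' default `N = 3, 5, ..., 13` this yields 20 planes — the only exclusion in
#' range is `(N, k) = (9, 3)`, whose projection reduces to the 3-point
#' attractor of a period-averaged signal.
#'
#' @param N_values Odd point counts (default `c(3, 5, 7, 9, 11, 13)`).
#' @return List of admitted `projection_plane` objects.
#' @export
enumerate_planes <- function(N_values = c(3, 5, 7, 9, 11, 13)) {
  planes <- list()
  for (N in sort(unique(as.integer(N_values)))) {
    check_n_points(N)
    for (k in seq_len((N - 1) / 2)) {
      pl <- projection_plane(N, k)
      if (pl$admitted) planes[[length(planes) + 1]] <- pl
    }
  }
  planes
}

#' Numerically verify that a non-coprime plane duplicates lower-order structure
#'
#' For `g = gcd(k, N) > 1` the `(N, k)` projection of a signal equals, up to
#' the scale `1/sqrt(g)`, the `(N/g, k/g)` projection of the period-averaged
#' signal `y(t) = sum_p x(t - p (N/g) tau)`. This is why such planes are not
#' admitted: their attractor carries no structure beyond a smaller point
#' count. The function checks the identity numerically on a supplied (or
#' random smoothed) test signal.
#'
#' @param N,k Plane indices with `gcd(k, N) > 1`.
#' @param samples Optional test signal; default is a seeded smoothed noise
#'   trace.
#' @param sampling_rate Hz (default 900).
#' @param tau Delay spacing in seconds (default `1/N` so the averaging
#'   period is `1/g` s).
#' @return Maximum absolute discrepancy between the two constructions
#'   (should be at numerical precision).
#' @export
verify_plane_reduction <- function(N, k, samples = NULL,
                                   sampling_rate = 900, tau = 1 / N) {
  g <- gcd_int(k, N)
  if (g <= 1) stop("plane (", N, ",", k, ") is coprime; nothing to verify")
  n2 <- N %/% g; k2 <- k %/% g
  if (is.null(samples))
    samples <- with_seed(42L, as.numeric(
      stats::filter(stats::rnorm(10 * sampling_rate), rep(1 / 20, 20),
                    circular = TRUE)))
  x <- as.numeric(samples)
  d_avg <- as.integer(round(n2 * tau * sampling_rate))
  cl_full <- project_attractor(
    embed_delays(x, sampling_rate, tau, N), projection_plane(N, k))
  shift <- function(v, s) c(rep(NA_real_, s), v[seq_len(length(v) - s)])
  y <- Reduce(`+`, lapply(0:(g - 1), function(p) shift(x, p * d_avg)))
  y <- y[!is.na(y)]
  cl_red <- project_attractor(
    embed_delays(y, sampling_rate, tau, n2), projection_plane(n2, k2))
  n_cmp <- min(nrow(cl_full$points), nrow(cl_red$points))
  a <- utils::tail(cl_full$points, n_cmp)
  b <- utils::tail(cl_red$points, n_cmp) / sqrt(g)
  max(abs(a - b))
}

#' Delay-coordinate embedding of a signal
#'
#' Places `N` equally spaced points on the signal: row `t` holds
#' `x[t], x[t - d], ..., x[t - (N-1) d]` with the delay realised as the
#' integer sample shift `d = round(tau * fs)`.
#'
#' @param samples Numeric voltage vector (mV).
#' @param sampling_rate Hz.
#' @param tau Delay spacing in seconds (> 0).
#' @param N Point count.
#' @return A `delay_matrix`: list with `rows` (matrix, one column per delay),
#'   `tau`, `d`, `N`, `sampling_rate`.
#' @export
embed_delays <- function(samples, sampling_rate, tau, N) {
  stopifnot(tau > 0)
  check_n_points(N)
  x <- as.numeric(samples)
  d <- max(1L, as.integer(round(tau * sampling_rate)))
  need <- (N - 1L) * d + 1L
  if (length(x) < need)
    stop("signal too short for embedding: need at least ", need,
         " samples (N=", N, ", d=", d, "), got ", length(x))
  t_idx <- seq.int((N - 1L) * d + 1L, length(x))
  rows <- vapply(0:(N - 1L), function(j) x[t_idx - j * d],
                 numeric(length(t_idx)))
  structure(list(rows = rows, tau = tau, d = d, N = as.integer(N),
                 sampling_rate = sampling_rate),
            class = "delay_matrix")
}

#' Project delay coordinates onto a symmetric plane
#'
#' @param delays A `delay_matrix`.
#' @param plane A `projection_plane` with matching `N`.
#' @param lead Optional lead label carried on the cloud.
#' @return An `attractor_cloud`: list with `points` (two-column matrix of
#'   `(u, v)` in mV), `N`, `k`, `tau`, `lead`.
#' @export
project_attractor <- function(delays, plane, lead = NA_character_) {
  stopifnot(inherits(delays, "delay_matrix"),
            inherits(plane, "projection_plane"))
  if (delays$N != plane$N)
    stop("dimension mismatch: delay matrix N=", delays$N,
         " vs plane N=", plane$N)
  pts <- delays$rows %*% cbind(u = plane$basis_c, v = plane$basis_s)
  structure(list(points = pts, N = plane$N, k = plane$k, tau = delays$tau,
                 lead = lead),
            class = "attractor_cloud")
}

#' @export
print.attractor_cloud <- function(x, ...) {
  cat(sprintf("<attractor_cloud N=%d k=%d lead=%s> %d points, tau=%.4g s\n",
              x$N, x$k, x$lead, nrow(x$points), x$tau))
  invisible(x)
}

#' All attractors for one lead of a record
#'
#' Estimates the average cardiac cycle on the lead (Pan-Tompkins detector,
#' with fallback to lead II), sets `tau = T/N` per point count, embeds once
#' per `N` and projects onto every admitted plane.
#'
#' @param record An `ecg_record`.
#' @param lead Lead label.
#' @param planes List of `projection_plane`s (default the standard 20).
#' @param cycle Optional precomputed `cycle_estimate` (or mean cycle length
#'   in seconds) to reuse.
#' @return Named list of `attractor_cloud`s, names `"N<k>"` as `"N3k1"` etc.
#' @export
lead_attractors <- function(record, lead, planes = enumerate_planes(),
                            cycle = NULL) {
  x <- record_lead(record, lead)
  tcycle <- if (is.null(cycle)) estimate_cycle(record, lead)$mean_cycle_length
            else if (is.numeric(cycle)) cycle
            else cycle$mean_cycle_length
  out <- list()
  for (N in unique(vapply(planes, `[[`, integer(1), "N"))) {
    dm <- embed_delays(x, record$sampling_rate, delay_spacing(tcycle, N), N)
    for (pl in planes[vapply(planes, `[[`, integer(1), "N") == N]) {
      out[[sprintf("N%dk%d", N, pl$k)]] <-
        project_attractor(dm, pl, lead = lead)
    }
  }
  out
}

#' Rasterize an attractor cloud to a density image
#'
#' @param cloud An `attractor_cloud`.
#' @param grid_size Number of bins per axis (>= 16, default 200).
#' @param extent Half-width R of the symmetric square `[-R, R]^2` in mV;
#'   default is the maximum absolute coordinate. Out-of-extent points are
#'   clipped to the boundary bins.
#' @param normalize If `TRUE` (default) the grid sums to 1.
#' @return An `attractor_image`: list with `grid`, `extent`, `normalized`.
#' @export
rasterize_attractor <- function(cloud, grid_size = 200, extent = NULL,
                                normalize = TRUE) {
  stopifnot(inherits(cloud, "attractor_cloud"))
  if (grid_size < 16) stop("grid_size must be >= 16")
  pts <- cloud$points
  if (nrow(pts) == 0) stop("empty attractor cloud")
  if (is.null(extent)) extent <- max(abs(pts), 1e-12)
  g <- as.integer(grid_size)
  ix <- pmin(pmax(floor((pts[, 1] + extent) / (2 * extent) * g) + 1L, 1L), g)
  iy <- pmin(pmax(floor((pts[, 2] + extent) / (2 * extent) * g) + 1L, 1L), g)
  grid <- matrix(tabulate(ix + (iy - 1L) * g, nbins = g * g), nrow = g)
  if (normalize) grid <- grid / sum(grid)
  structure(list(grid = grid, extent = extent, normalized = normalize,
                 N = cloud$N, k = cloud$k),
            class = "attractor_image")
}

#' Rotate an attractor cloud about the origin
#'
#' Utility for symmetry checks and orientation adjustment.
#'
#' @param cloud An `attractor_cloud`.
#' @param angle Rotation angle in radians (counterclockwise).
#' @return The rotated `attractor_cloud`.
#' @export
rotate_cloud <- function(cloud, angle) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  cloud$points <- cloud$points %*% rot
  colnames(cloud$points) <- c("u", "v")
  cloud
}

#' Export an attractor cloud as a data.frame
#'
#' @param cloud An `attractor_cloud`.
#' @return data.frame with columns `u`, `v` (mV).
#' @export
cloud_table <- function(cloud) {
  data.frame(u = cloud$points[, 1], v = cloud$points[, 2])
}
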