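test_that("radial density places mass where the geometry says", {
  origin <- cloud_from_points(rep(0, 40), rep(0, 40))
  rd0 <- r_density(origin, n_bins = 50, r_cap = 2)
  expect_equal(rd0$values[1], 1)

  circ <- circle_cloud(rho = 1.234)
  rd <- r_density(circ, n_bins = 100, r_cap = 3)
  expect_equal(sum(rd$values), 1, tolerance = 1e-12)
  hit <- which(rd$values > 0)
  expect_length(hit, 1)
  expect_equal(hit, floor(1.234 / 3 * 100) + 1)

  # radii beyond the cap land in the last bin
  far <- cloud_from_points(c(0.1, 10), c(0, 0))
  rdf <- r_density(far, n_bins = 10, r_cap = 1)
  expect_equal(rdf$values[10], 0.5)
  expect_error(r_density(cloud_from_points(numeric(0), numeric(0))), "empty")
})

test_that("angular density is uniform on a circle and unit-sum", {
  set.seed(21)
  n <- 24000
  th <- runif(n, 0, 2 * pi)
  cl <- cloud_from_points(cos(th), sin(th))
  td <- theta_density(cl, n_bins = 120)
  expect_equal(sum(td$values), 1, tolerance = 1e-12)
  per_bin <- n / 120
  expect_lt(max(abs(td$values - 1 / 120)) / (1 / 120), 3 / sqrt(per_bin))

  single <- theta_density(cloud_from_points(1, 0), n_bins = 120)
  expect_equal(single$values[1], 1)
  # a point at the exact origin is assigned theta = 0
  at0 <- theta_density(cloud_from_points(0, 0), n_bins = 120)
  expect_equal(at0$values[1], 1)
})

test_that("the outline profile tracks maximum radius per direction", {
  circ <- circle_cloud(rho = 0.9)
  ol <- outline_r(circ, n_bins = 120)
  occupied <- ol$values[ol$values > 0]
  expect_true(all(abs(occupied - 0.9) < 1e-9))

  one <- outline_r(cloud_from_points(0.3, 0.4), n_bins = 60)
  expect_equal(sum(one$values > 0), 1)
  expect_equal(max(one$values), 0.5)

  # homogeneity: scaling the cloud doubles the outline, not the densities
  set.seed(3)
  u <- rnorm(500); v <- rnorm(500)
  a <- cloud_from_points(u, v); b <- cloud_from_points(2 * u, 2 * v)
  expect_equal(outline_r(b)$values, 2 * outline_r(a)$values)
  expect_equal(theta_density(b)$values, theta_density(a)$values)
  expect_equal(r_density(b, r_cap = 6)$values, r_density(a, r_cap = 3)$values)
})

test_that("profiles are invariant to point order", {
  set.seed(8)
  u <- rnorm(300); v <- rnorm(300)
  perm <- sample(300)
  a <- measure_profiles(cloud_from_points(u, v))
  b <- measure_profiles(cloud_from_points(u[perm], v[perm]))
  for (kind in names(a)) expect_equal(a[[kind]]$values, b[[kind]]$values)
})

test_that("profile maxima form the three basic metrics", {
  profs <- measure_profiles(circle_cloud(rho = 1.1), r_cap = 3)
  mm <- max_metrics(profs)
  expect_equal(unname(mm["max_outline_r"]), 1.1, tolerance = 1e-9)
  expect_equal(unname(mm["max_r_density"]), 1)
  expect_equal(unname(mm["max_theta_density"]),
               max(profs$theta_density$values))
  expect_error(max_metrics(profs[c("r_density", "outline_r")]), "missing")
})

test_that("female-like clouds have lower peak angular density than male-like", {
  pl <- projection_plane(3, 1)
  max_td <- function(class_label, seeds) {
    vapply(seeds, function(s) {
      p <- synth_params(template = make_preset(class_label),
                        class_label = class_label, seed = s)
      rec <- synthesize_record(p)
      cl <- lead_attractors(rec, "II", list(pl))[["N3k1"]]
      max(theta_density(cl)$values)
    }, numeric(1))
  }
  f <- max_td("F-like", 1:50)
  m <- max_td("M-like", 51:100)
  expect_lt(mean(f), mean(m))
})

test_that("cohort feature blocks have canonical keys and shapes", {
  ft <- small_cohort_features()
  expect_s3_class(ft, "spar_features")
  # 2 leads x 3 planes (N=3,5) x 3 kinds
  expect_length(ft$features, 2 * 3 * 3)
  expect_identical(ft$keys$key[1:3],
                   c("II|N3|k1|r_density", "II|N3|k1|theta_density",
                     "II|N3|k1|outline_r"))
  expect_equal(ncol(ft$features[["II|N3|k1|r_density"]]), 100)
  expect_equal(ncol(ft$features[["V3|N5|k2|outline_r"]]), 120)
  expect_equal(nrow(ft$features[[1]]), 16)
  expect_false(anyNA(unlist(ft$features)))
  # density rows are unit-sum
  expect_equal(rowSums(ft$features[["II|N3|k1|r_density"]]),
               rep(1, 16), tolerance = 1e-9)
  tab <- features_table(ft)
  expect_equal(ncol(tab), 1 + sum(vapply(ft$features, ncol, integer(1))))
})
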