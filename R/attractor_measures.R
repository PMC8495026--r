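# Polar quantification of an attractor cloud: the radial density profile
# (r density), the angular density profile (theta density) and the outline
# profile (maximum r per theta bin). Densities are unit-sum histograms; the
# outline is in signal units (mV), so absolute attractor size is preserved
# as a feature.

MEASURE_KINDS <- c("r_density", "theta_density", "outline_r")

new_measure_profile <- function(kind, bin_edges, values) {
  structure(list(kind = kind, bin_edges = bin_edges, values = values),
            class = "measure_profile")
}

#' @export
print.measure_profile <- function(x, ...) {
  cat(sprintf("<measure_profile %s> %d bins, max=%.4g\n", x$kind,
              length(x$values), max(x$values)))
  invisible(x)
}

cloud_polar <- function(cloud) {
  stopifnot(inherits(cloud, "attractor_cloud"))
  if (nrow(cloud$points) == 0) stop("empty attractor cloud")
  u <- cloud$points[, 1]; v <- cloud$points[, 2]
  r <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  th[th < 0] <- th[th < 0] + 2 * pi
  th[r == 0] <- 0  # points at the exact origin get theta = 0
  th[th >= 2 * pi] <- 0
  list(r = r, theta = th)
}

r_density_polar <- function(pol, n_bins, r_cap) {
  bin <- pmin(floor(pol$r / r_cap * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  new_measure_profile("r_density",
                      seq(0, r_cap, length.out = n_bins + 1),
                      counts / sum(counts))
}

theta_density_polar <- function(pol, n_bins) {
  bin <- pmin(floor(pol$theta / (2 * pi) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  new_measure_profile("theta_density",
                      seq(0, 2 * pi, length.out = n_bins + 1),
                      counts / sum(counts))
}

outline_r_polar <- function(pol, n_bins) {
  bin <- pmin(floor(pol$theta / (2 * pi) * n_bins) + 1L, n_bins)
  vals <- rep(0, n_bins)
  o <- order(pol$r)  # ascending: later (larger) assignments win
  vals[bin[o]] <- pol$r[o]
  new_measure_profile("outline_r",
                      seq(0, 2 * pi, length.out = n_bins + 1),
                      vals)
}

#' Radial density profile of an attractor
#'
#' Unit-sum histogram of the radial distance `r = sqrt(u^2 + v^2)` over
#' `n_bins` equal-width bins on `[0, r_cap]`; radii at or beyond `r_cap`
#' are counted in the last bin. A shared `r_cap` across a cohort keeps the
#' absolute-size information that distinguishes the groups.
#'
#' @param cloud An `attractor_cloud`.
#' @param n_bins Number of bins (default 100).
#' @param r_cap Radial domain cap in mV (default 3).
#' @return A `measure_profile` of kind `"r_density"`.
#' @export
r_density <- function(cloud, n_bins = 100, r_cap = 3) {
  stopifnot(r_cap > 0, n_bins >= 1)
  r_density_polar(cloud_polar(cloud), n_bins, r_cap)
}

#' Angular density profile of an attractor
#'
#' Unit-sum histogram of `theta = atan2(v, u)` mapped to `[0, 2 pi)` over
#' `n_bins` equal-width bins, counterclockwise from the positive u-axis.
#' Points at the exact origin are assigned `theta = 0`.
#'
#' @param cloud An `attractor_cloud`.
#' @param n_bins Number of bins (default 120, i.e. 3 degrees).
#' @return A `measure_profile` of kind `"theta_density"`.
#' @export
theta_density <- function(cloud, n_bins = 120) {
  stopifnot(n_bins >= 1)
  theta_density_polar(cloud_polar(cloud), n_bins)
}

#' Outline profile of an attractor
#'
#' Maximum radius per theta bin (mV); empty bins get 0. Scales linearly with
#' the cloud, so it carries the absolute attractor size.
#'
#' @param cloud An `attractor_cloud`.
#' @param n_bins Number of theta bins (default 120).
#' @return A `measure_profile` of kind `"outline_r"`.
#' @export
outline_r <- function(cloud, n_bins = 120) {
  stopifnot(n_bins >= 1)
  outline_r_polar(cloud_polar(cloud), n_bins)
}

#' All three measure profiles of a cloud
#'
#' @param cloud An `attractor_cloud`.
#' @param r_bins,theta_bins Bin counts for the radial and angular profiles.
#' @param r_cap Radial cap in mV shared across a cohort.
#' @return Named list with elements `r_density`, `theta_density`,
#'   `outline_r`.
#' @export
measure_profiles <- function(cloud, r_bins = 100, theta_bins = 120,
                             r_cap = 3) {
  pol <- cloud_polar(cloud)  # compute polar coordinates once
  list(r_density = r_density_polar(pol, r_bins, r_cap),
       theta_density = theta_density_polar(pol, theta_bins),
       outline_r = outline_r_polar(pol, theta_bins))
}

#' Maxima of the three measure profiles
#'
#' The three "basic metrics": the maximum of each measure profile.
#'
#' @param profiles Named list from [measure_profiles()] (all three kinds
#'   required).
#' @return Named numeric vector `max_r_density`, `max_theta_density`
#'   (unitless), `max_outline_r` (mV).
#' @export
max_metrics <- function(profiles) {
  missing <- setdiff(MEASURE_KINDS, names(profiles))
  if (length(missing))
    stop("missing measure profile kind(s): ", paste(missing, collapse = ", "))
  c(max_r_density = max(profiles$r_density$values),
    max_theta_density = max(profiles$theta_density$values),
    max_outline_r = max(profiles$outline_r$values))
}

#' Export a measure profile as a data.frame
#'
#' @param profile A `measure_profile`.
#' @return data.frame with columns `bin_center` and `value`.
#' @export
profile_table <- function(profile) {
  e <- profile$bin_edges
  data.frame(bin_center = (e[-1] + e[-length(e)]) / 2,
             value = profile$values)
}

#' Measure-profile feature block for a whole cohort
#'
#' Computes, for every record, the three measure profiles of every
#' (lead, plane) attractor, and returns one matrix per
#' `lead|N|k|kind` key (rows = records, columns = profile bins) together
#' with the cohort metadata. Key order is canonical: lead in standard
#' 12-lead order, then N ascending, then k ascending, then kind in the order
#' r density, theta density, outline r.
#'
#' @param cohort An `ecg_cohort`.
#' @param leads Leads to use (default: leads of the first record).
#' @param planes List of projection planes (default the standard 20).
#' @param r_bins,theta_bins,r_cap Profile binning configuration.
#' @param progress Print a dot per record (default `FALSE`).
#' @return A `spar_features` list with `features` (named list of matrices),
#'   `meta` (data.frame), `keys` (data.frame lead/N/k/kind), and the binning
#'   configuration.
#' @export
cohort_features <- function(cohort, leads = NULL,
                            planes = enumerate_planes(),
                            r_bins = 100, theta_bins = 120, r_cap = 3,
                            progress = FALSE) {
  stopifnot(inherits(cohort, "ecg_cohort"), length(cohort$records) > 0)
  if (is.null(leads)) leads <- cohort$records[[1]]$lead_names
  leads <- STANDARD_LEADS[STANDARD_LEADS %in% leads]
  meta <- cohort_metadata(cohort)
  keys <- expand.grid(kind = MEASURE_KINDS,
                      k = NA_integer_, N = NA_integer_, lead = leads,
                      stringsAsFactors = FALSE)[0, ]
  key_list <- list()
  for (lead in leads)
    for (pl in planes)
      for (kind in MEASURE_KINDS)
        key_list[[length(key_list) + 1]] <-
          data.frame(lead = lead, N = pl$N, k = pl$k, kind = kind,
                     stringsAsFactors = FALSE)
  keys <- do.call(rbind, key_list)
  keys$key <- sprintf("%s|N%d|k%d|%s", keys$lead, keys$N, keys$k, keys$kind)
  nbin <- ifelse(keys$kind == "r_density", r_bins, theta_bins)
  feats <- lapply(seq_len(nrow(keys)), function(i)
    matrix(NA_real_, nrow = length(cohort$records), ncol = nbin[i]))
  names(feats) <- keys$key
  for (ri in seq_along(cohort$records)) {
    rec <- cohort$records[[ri]]
    for (lead in leads) {
      clouds <- lead_attractors(rec, lead, planes)
      for (nm in names(clouds)) {
        prof <- measure_profiles(clouds[[nm]], r_bins, theta_bins, r_cap)
        for (kind in MEASURE_KINDS) {
          key <- sprintf("%s|%s|%s", lead,
                         sub("k", "|k", nm), kind)
          feats[[key]][ri, ] <- prof[[kind]]$values
        }
      }
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(features = feats, meta = meta, keys = keys,
                 leads = leads,
                 config = list(r_bins = r_bins, theta_bins = theta_bins,
                               r_cap = r_cap)),
            class = "spar_features")
}

#' @export
print.spar_features <- function(x, ...) {
  cat(sprintf("<spar_features> %d records x %d feature blocks (%d leads)\n",
              nrow(x$meta), length(x$features), length(x$leads)))
  invisible(x)
}

#' Flatten a feature block into one wide table
#'
#' @param features A `spar_features` object.
#' @return data.frame: record_id plus one column per (key, bin).
#' @export
features_table <- function(features) {
  mats <- lapply(names(features$features), function(key) {
    m <- features$features[[key]]
    colnames(m) <- sprintf("%s|b%03d", key, seq_len(ncol(m)))
    m
  })
  cbind(data.frame(record_id = features$meta$record_id,
                   stringsAsFactors = FALSE),
        as.data.frame(do.call(cbind, mats), check.names = FALSE))
}
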