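# Cohort-level profile visualization and statistics: per-bin median and
# centile bands by group, Euclidean distance between group medians, and the
# conventional heart-rate-corrected interval metrics used for comparison.

#' Assemble a profile ensemble from a cohort feature block
#'
#' @param features A `spar_features` object from [cohort_features()].
#' @param lead,N,k,kind The profile selector.
#' @return A `profile_ensemble`: list with `rows` (records x bins matrix),
#'   `groups` (sex per row), `record_id`, `key`.
#' @export
profile_ensemble <- function(features, lead, N, k, kind) {
  key <- sprintf("%s|N%d|k%d|%s", lead, N, k, kind)
  if (!key %in% names(features$features))
    stop("no feature block for key ", key)
  structure(list(rows = features$features[[key]],
                 groups = features$meta$sex,
                 record_id = features$meta$record_id, key = key),
            class = "profile_ensemble")
}

#' Per-bin median and centile bands for one group
#'
#' Medians and centiles are computed per bin independently (pointwise),
#' matching banded profile plots.
#'
#' @param ensemble A `profile_ensemble` (or a plain matrix with a `groups`
#'   attribute supplied via `groups`).
#' @param group Group label to summarize (e.g. `"female"`); `NULL` pools all
#'   rows.
#' @param centiles Numeric vector of centile pairs, default
#'   `c(25, 75, 0, 100)` meaning a 25-75 band and a 0-100 band.
#' @param groups Optional group label per row when `ensemble` is a matrix.
#' @return A `group_summary`: list with `median`, `bands` (named list of
#'   lower/upper matrices per pair), `group`, `n`.
#' @export
summarize_group <- function(ensemble, group = NULL,
                            centiles = c(25, 75, 0, 100), groups = NULL) {
  if (inherits(ensemble, "profile_ensemble")) {
    rows <- ensemble$rows; groups <- ensemble$groups
  } else {
    rows <- as.matrix(ensemble)
  }
  if (!is.null(group)) {
    if (is.null(groups)) stop("group labels required to select a group")
    rows <- rows[groups == group, , drop = FALSE]
  }
  if (nrow(rows) == 0) stop("empty group: ", group %||% "(all)")
  if (length(centiles) %% 2 != 0) stop("centiles must come in pairs")
  med <- apply(rows, 2, stats::median)
  bands <- list()
  for (i in seq(1, length(centiles), by = 2)) {
    lo <- centiles[i] / 100; hi <- centiles[i + 1] / 100
    bands[[sprintf("p%g_p%g", centiles[i], centiles[i + 1])]] <-
      list(lower = apply(rows, 2, stats::quantile, probs = lo),
           upper = apply(rows, 2, stats::quantile, probs = hi))
  }
  structure(list(median = med, bands = bands,
                 group = group %||% "all", n = nrow(rows)),
            class = "group_summary")
}

#' Euclidean distance between two group median profiles
#'
#' @param summary_a,summary_b `group_summary` objects with equal bin counts.
#' @return Scalar Euclidean norm of the difference of the median vectors.
#' @export
group_distance <- function(summary_a, summary_b) {
  stopifnot(inherits(summary_a, "group_summary"),
            inherits(summary_b, "group_summary"))
  if (length(summary_a$median) != length(summary_b$median))
    stop("median vectors have different lengths (",
         length(summary_a$median), " vs ", length(summary_b$median), ")")
  sqrt(sum((summary_a$median - summary_b$median)^2))
}

#' Permutation test of the female/male median-profile distance
#'
#' Compares the observed between-group distance with its distribution under
#' random relabeling of the group memberships.
#'
#' @param ensemble A `profile_ensemble`.
#' @param group_a,group_b The two group labels (default female/male).
#' @param n_perm Number of permutations (default 200).
#' @param seed Seed for the permutation draws.
#' @return List with `observed`, `permuted` (vector), and `p_value`.
#' @export
group_distance_permtest <- function(ensemble, group_a = "female",
                                    group_b = "male", n_perm = 200,
                                    seed = 1L) {
  obs <- group_distance(summarize_group(ensemble, group_a),
                        summarize_group(ensemble, group_b))
  rows <- ensemble$rows
  g <- ensemble$groups
  keep <- g %in% c(group_a, group_b)
  rows <- rows[keep, , drop = FALSE]; g <- g[keep]
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    gp <- sample(g)
    group_distance(
      summarize_group(rows, group_a, groups = gp),
      summarize_group(rows, group_b, groups = gp))
  }, numeric(1)))
  list(observed = obs, permuted = perm,
       p_value = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Heart-rate-corrected interval metrics
#'
#' Computes the Fridericia-corrected QT, `QTc = QT / RR^(1/3)`, and the
#' corrected J-point-to-T-peak interval, `JT_peak_c = JT_peak / RR^0.58`,
#' with RR in seconds and the intervals in milliseconds. `T_peak_T_end` is
#' passed through uncorrected.
#'
#' @param rr RR interval in seconds (> 0).
#' @param qt QT interval in ms (> 0).
#' @param qrs,pr,jt_peak,t_peak_t_end Optional further intervals in ms.
#' @return An `interval_metrics` list with the inputs plus `qtc_fridericia`
#'   and `jt_peak_c` (ms).
#' @export
corrected_intervals <- function(rr, qt, qrs = NA_real_, pr = NA_real_,
                                jt_peak = NA_real_,
                                t_peak_t_end = NA_real_) {
  vals <- c(rr = rr, qt = qt, qrs = qrs, pr = pr, jt_peak = jt_peak,
            t_peak_t_end = t_peak_t_end)
  bad <- !is.na(vals) & vals <= 0
  if (any(bad))
    stop("interval(s) must be positive: ", paste(names(vals)[bad],
                                                 collapse = ", "))
  structure(list(
    rr = rr, qt = qt, qrs = qrs, pr = pr, jt_peak = jt_peak,
    t_peak_t_end = t_peak_t_end,
    qtc_fridericia = qt / rr^(1 / 3),
    jt_peak_c = if (is.na(jt_peak)) NA_real_ else jt_peak / rr^0.58
  ), class = "interval_metrics")
}

#' Summary table for a group_summary
#'
#' @param summary A `group_summary`.
#' @param bin_centers Optional bin-center coordinates.
#' @return data.frame with the median and each band's lower/upper values.
#' @export
summary_table <- function(summary, bin_centers = NULL) {
  df <- data.frame(bin = seq_along(summary$median),
                   median = summary$median)
  if (!is.null(bin_centers)) df$bin_center <- bin_centers
  for (nm in names(summary$bands)) {
    df[[paste0(nm, "_lower")]] <- summary$bands[[nm]]$lower
    df[[paste0(nm, "_upper")]] <- summary$bands[[nm]]$upper
  }
  df
}

#' Banded profile plot by group
#'
#' Median line per group over shaded pooled centile bands, one panel per
#' selected lead.
#'
#' @param features A `spar_features` object.
#' @param N,k,kind Profile selector.
#' @param leads Leads to facet over (default all in the feature block).
#' @param centiles Centile pairs for the pooled bands.
#' @return A ggplot object.
#' @export
plot_profile_bands <- function(features, N = 3, k = 1,
                               kind = "theta_density", leads = NULL,
                               centiles = c(25, 75, 0, 100)) {
  if (is.null(leads)) leads <- features$leads
  panels <- list()
  for (lead in leads) {
    ens <- profile_ensemble(features, lead, N, k, kind)
    pooled <- summarize_group(ens, NULL, centiles)
    fem <- summarize_group(ens, "female", centiles)
    mal <- summarize_group(ens, "male", centiles)
    d <- group_distance(fem, mal)
    nb <- length(pooled$median)
    bandrows <- do.call(rbind, lapply(names(pooled$bands), function(nm)
      data.frame(lead = sprintf("%s (%.3f)", lead, d), bin = seq_len(nb),
                 band = nm, lower = pooled$bands[[nm]]$lower,
                 upper = pooled$bands[[nm]]$upper)))
    medrows <- rbind(
      data.frame(lead = sprintf("%s (%.3f)", lead, d), bin = seq_len(nb),
                 group = "female", value = fem$median),
      data.frame(lead = sprintf("%s (%.3f)", lead, d), bin = seq_len(nb),
                 group = "male", value = mal$median))
    panels[[lead]] <- list(bands = bandrows, medians = medrows)
  }
  bands <- do.call(rbind, lapply(panels, `[[`, "bands"))
  medians <- do.call(rbind, lapply(panels, `[[`, "medians"))
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(x = .data$bin, ymin = .data$lower, ymax = .data$upper,
                   group = .data$band),
      fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(
      data = medians,
      ggplot2::aes(x = .data$bin, y = .data$value, colour = .data$group,
                   linetype = .data$group)) +
    ggplot2::scale_colour_manual(values = c(female = "red", male = "blue")) +
    ggplot2::facet_wrap(~lead) +
    ggplot2::labs(x = "profile bin", y = kind) +
    ggplot2::theme_minimal()
}

#' Density-image plot of an attractor
#'
#' @param image An `attractor_image` from [rasterize_attractor()].
#' @return A ggplot object.
#' @export
plot_attractor <- function(image) {
  g <- nrow(image$grid)
  centers <- seq(-image$extent, image$extent, length.out = g + 1)
  centers <- (centers[-1] + centers[-(g + 1)]) / 2
  df <- expand.grid(u = centers, v = centers)
  df$density <- as.vector(image$grid)
  ggplot2::ggplot(df[df$density > 0, ],
                  ggplot2::aes(x = .data$u, y = .data$v,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (mV)", y = "v (mV)") +
    ggplot2::theme_minimal()
}
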