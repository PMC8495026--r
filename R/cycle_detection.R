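# QRS detection in the Pan-Tompkins style: band-pass, differentiate, square,
# moving-window integrate, adaptive dual-threshold with refractory period and
# search-back. Used only to estimate the average cardiac cycle length that
# sets the attractor delay spacing; no beat classification is attempted.

#' Detect R peaks with a Pan-Tompkins style detector
#'
#' Pipeline: zero-phase Butterworth band-pass 5-15 Hz, five-point-style
#' derivative, squaring, 150 ms moving-window integration, adaptive
#' signal/noise dual threshold with a 200 ms refractory period and a
#' missed-beat search-back at 1.66 times the running RR average. Each
#' detection is then refined to the local maximum of the raw signal within
#' +/- 80 ms.
#'
#' @param samples Numeric voltage vector (mV), at least 3 s long.
#' @param sampling_rate Hz, at least 100.
#' @return Integer vector of R-peak sample indices (1-based), strictly
#'   increasing, successive peaks >= 0.2 s apart.
#' @export
detect_qrs <- function(samples, sampling_rate) {
  fs <- sampling_rate
  if (fs < 100) stop("sampling_rate must be >= 100 Hz")
  if (length(samples) / fs < 3) stop("need at least 3 s of signal")
  x <- as.numeric(samples)
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x - mean(x))
  der <- c(0, diff(xf)) * fs
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 1))
  mwi[is.na(mwi)] <- 0

  refr <- round(0.2 * fs)
  cand <- local_maxima(mwi, min_sep = refr)
  if (length(cand) < 2) stop("insufficient beats: fewer than 2 QRS candidates")

  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  qrs <- integer(0)
  rr_avg <- NA_real_
  for (i in seq_along(cand)) {
    p <- cand[i]; v <- mwi[p]
    thr <- npki + 0.25 * (spki - npki)
    accepted <- FALSE
    if (v > thr && (length(qrs) == 0 || p - qrs[length(qrs)] > refr)) {
      qrs <- c(qrs, p)
      spki <- 0.125 * v + 0.875 * spki
      accepted <- TRUE
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    # search-back for a missed beat
    if (!accepted && length(qrs) >= 2) {
      rr_avg <- mean(diff(utils::tail(qrs, 8)))
      if (p - qrs[length(qrs)] > 1.66 * rr_avg) {
        gap <- cand[cand > qrs[length(qrs)] + refr & cand < p]
        if (length(gap)) {
          best <- gap[which.max(mwi[gap])]
          if (mwi[best] > 0.5 * thr) {
            qrs <- sort(c(qrs, best))
            spki <- 0.25 * mwi[best] + 0.75 * spki
          }
        }
      }
    }
  }
  if (length(qrs) < 2) stop("insufficient beats: fewer than 2 QRS detections")
  # refine to the local maximum of the raw signal within +/- 80 ms
  half <- as.integer(round(0.08 * fs))
  peaks <- vapply(qrs, function(p) {
    lo <- max(1L, as.integer(p) - half)
    hi <- min(length(x), as.integer(p) + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory contract after refinement
  keep <- c(TRUE, diff(peaks) >= refr)
  peaks[keep]
}

local_maxima <- function(y, min_sep) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  # greedy suppression: keep the larger of any pair closer than min_sep
  ord <- idx[order(-y[idx], idx)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Mean cardiac cycle length from detected peaks
#'
#' @param peaks Integer sample indices of successive R peaks (>= 2).
#' @param sampling_rate Hz.
#' @return Arithmetic mean of successive peak differences, in seconds.
#' @export
mean_cycle_length <- function(peaks, sampling_rate) {
  if (length(peaks) < 2) stop("need at least 2 peaks")
  mean(diff(peaks)) / sampling_rate
}

#' Delay spacing for an N-point attractor
#'
#' The N points placed on the signal are spaced 1/N of the average cardiac
#' cycle apart.
#'
#' @param mean_cycle Average cardiac cycle length in seconds.
#' @param N Odd number of points, >= 3.
#' @return Delay spacing tau in seconds.
#' @export
delay_spacing <- function(mean_cycle, N) {
  check_n_points(N)
  stopifnot(mean_cycle > 0)
  mean_cycle / N
}

check_n_points <- function(N) {
  if (length(N) != 1 || N < 3 || N %% 2 == 0)
    stop("N must be an odd integer >= 3, got ", N)
  invisible(TRUE)
}

#' Estimate the cardiac cycle for one lead of a record
#'
#' The cycle length is estimated per lead from that lead's own samples; if
#' detection fails on a lead, the estimate falls back to lead II (when
#' available).
#'
#' @param record An `ecg_record`.
#' @param lead Lead label.
#' @return A `cycle_estimate`: list with `r_peak_indices`, `n_beats`,
#'   `rr_intervals` (s), `mean_cycle_length` (s), and `source_lead`.
#' @export
estimate_cycle <- function(record, lead) {
  try_lead <- function(l) {
    peaks <- detect_qrs(record_lead(record, l), record$sampling_rate)
    rr <- diff(peaks) / record$sampling_rate
    structure(list(r_peak_indices = peaks, n_beats = length(peaks),
                   rr_intervals = rr,
                   mean_cycle_length = mean(rr), source_lead = l),
              class = "cycle_estimate")
  }
  est <- tryCatch(try_lead(lead), error = function(e) e)
  if (inherits(est, "error")) {
    if (lead != "II" && "II" %in% record$lead_names) {
      est2 <- tryCatch(try_lead("II"), error = function(e) e)
      if (!inherits(est2, "error")) return(est2)
    }
    stop("cycle estimation failed for record ", record$record_id,
         " lead ", lead, ": ", conditionMessage(est))
  }
  est
}

#' Export detected peaks as a data.frame
#'
#' @param peaks Integer sample indices.
#' @param sampling_rate Hz.
#' @return data.frame with columns `sample_index` and `time_s`.
#' @export
peaks_table <- function(peaks, sampling_rate) {
  data.frame(sample_index = as.integer(peaks),
             time_s = (as.integer(peaks) - 1) / sampling_rate)
}
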