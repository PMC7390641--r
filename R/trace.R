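# Transient detection on fluorescence traces and the four response metrics:
# onset/offset (-> duration), FWHM, inter-peak interval, F_max/F_base.

#' Uniformly sampled fluorescence trace
#'
#' @param times Sample times in s, strictly increasing and uniform to within
#'   1e-9 s.
#' @param values Fluorescence values (a.u.), same length as `times`.
#' @param frame_period Frame period in s; defaults to the median time step.
#' @param validate_length Require at least 10 samples (default). Internal
#'   callers constructing stub traces may relax this.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(times, values, frame_period = NULL,
                               validate_length = TRUE) {
  stopifnot(length(times) == length(values), is.numeric(times),
            is.numeric(values))
  if (validate_length && length(times) < 10) {
    stop("a fluorescence trace needs at least 10 samples", call. = FALSE)
  }
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 1e-9) {
      stop("times must be uniformly spaced (to within 1e-9 s)",
           call. = FALSE)
    }
    if (is.null(frame_period)) frame_period <- stats::median(dt)
  } else if (is.null(frame_period)) {
    frame_period <- 0.05
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 frame_period = frame_period),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat("Fluorescence trace:", length(x$values), "samples at",
      x$frame_period, "s/frame (", round(max(x$times), 2), "s )\n")
  invisible(x)
}

#' Read a trace from CSV
#'
#' Expects columns `time_s` and `fluorescence_au`.
#'
#' @param path CSV file path.
#' @return A [fluorescence_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "fluorescence_au") %in% names(df))) {
    stop("trace CSV needs columns time_s and fluorescence_au", call. = FALSE)
  }
  fluorescence_trace(df$time_s, df$fluorescence_au)
}

#' Write a trace to CSV
#'
#' @param trace A [fluorescence_trace()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times,
                              fluorescence_au = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- internal signal-processing primitives ---------------------------------

# Blockwise rolling lower-percentile baseline, linearly interpolated back to
# every sample. Robust provisional baseline for the first pass of the
# two-pass scheme.
rolling_percentile_baseline <- function(values, frame_period, window_s = 4,
                                        prob = 0.2) {
  n <- length(values)
  block <- max(5L, min(n, as.integer(round(window_s / frame_period))))
  starts <- seq(1L, n, by = block)
  centers <- pmin(starts + (block - 1) / 2, n)
  q <- vapply(starts, function(s) {
    stats::quantile(values[s:min(s + block - 1L, n)], prob, names = FALSE)
  }, numeric(1))
  if (length(q) == 1) return(rep(q, n))
  stats::approx(centers, q, xout = seq_len(n), rule = 2)$y
}

# Indices of strict local maxima (first sample of any plateau that
# subsequently drops).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1L
    keep[ci] <- j == n || v[j + 1] < v[i]
  }
  cand[keep]
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two key saddles (the minima separating it from the nearest
# higher terrain on each side, or from the trace edge).
peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]
  j <- i - 1L
  while (j >= 1 && v[j] <= v[i]) {
    if (v[j] < left_min) left_min <- v[j]
    j <- j - 1L
  }
  right_min <- v[i]
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) {
    if (v[j] < right_min) right_min <- v[j]
    j <- j + 1L
  }
  v[i] - max(left_min, right_min)
}

# Last downward bracket of `thr` left of imax (>= lo_bound): returns the
# interpolated crossing time, or NA if v stays above thr on the whole span.
cross_left <- function(v, t, imax, thr, lo_bound = 1L) {
  j <- imax - 1L
  while (j >= lo_bound && v[j] > thr) j <- j - 1L
  if (j < lo_bound || v[j] > thr) return(NA_real_)
  if (v[j] == thr || v[j + 1] == v[j]) return(t[j])
  t[j] + (thr - v[j]) / (v[j + 1] - v[j]) * (t[j + 1] - t[j])
}

# First downward crossing of `thr` right of imax (<= hi_bound).
cross_right <- function(v, t, imax, thr, hi_bound = length(v)) {
  j <- imax + 1L
  while (j <= hi_bound && v[j] > thr) j <- j + 1L
  if (j > hi_bound || v[j] > thr) return(NA_real_)
  if (v[j] == thr || v[j - 1] == v[j]) return(t[j])
  t[j - 1] + (v[j - 1] - thr) / (v[j - 1] - v[j]) * (t[j] - t[j - 1])
}

# Onset/offset for each peak maximum: last/first crossing of its threshold
# before/after the maximum, bounded by the neighbouring maxima; if the signal
# never returns to threshold between two peaks (overlap), the inter-maximum
# valley is used as the shared boundary.
peak_bounds <- function(v, t, imaxes, thrs) {
  m <- length(imaxes)
  onset <- offset <- numeric(m)
  for (p in seq_len(m)) {
    i <- imaxes[p]
    lo <- if (p > 1) imaxes[p - 1] else 1L
    hi <- if (p < m) imaxes[p + 1] else length(v)
    on <- cross_left(v, t, i, thrs[p], lo)
    if (is.na(on)) {
      on <- if (p > 1) t[lo + which.min(v[lo:i]) - 1L] else t[1]
    }
    off <- cross_right(v, t, i, thrs[p], hi)
    if (is.na(off)) {
      off <- if (p < m) t[i + which.min(v[i:hi]) - 1L] else t[length(t)]
    }
    onset[p] <- on
    offset[p] <- off
  }
  list(onset = onset, offset = offset)
}

# ---- exported trace-analysis operations ------------------------------------

#' Estimate the baseline fluorescence between peaks
#'
#' With a peak table: median of all samples outside every
#' `[t_onset, t_offset]` window. Without one: the full two-pass scheme
#' (provisional rolling-percentile baseline, peak detection, then the median
#' of the inter-peak samples).
#'
#' @param trace A [fluorescence_trace()].
#' @param peaks Optional peak table (data frame with `t_onset`, `t_offset`).
#' @return Baseline fluorescence (a.u.).
#' @export
estimate_baseline <- function(trace, peaks = NULL) {
  if (is.null(peaks)) {
    return(attr(detect_peaks(trace), "f_base"))
  }
  out <- outside_peaks(trace, peaks)
  if (!any(out)) {
    stop("no inter-peak samples available for baseline estimation",
         call. = FALSE)
  }
  stats::median(trace$values[out])
}

outside_peaks <- function(trace, peaks) {
  out <- rep(TRUE, length(trace$times))
  if (!is.null(peaks) && nrow(peaks)) {
    for (p in seq_len(nrow(peaks))) {
      out[trace$times >= peaks$t_onset[p] &
            trace$times <= peaks$t_offset[p]] <- FALSE
    }
  }
  out
}

#' Detect fluorescence transients
#'
#' Two-pass detection. Pass 1 subtracts a provisional rolling-percentile
#' baseline to find candidate local maxima with topographic prominence at
#' least `min_prominence` (default `5 * sigma_noise`), separated by at least
#' `min_separation`. Pass 2 re-estimates the baseline as the median of the
#' inter-peak samples, the noise scale as `1.4826 * MAD` of those samples,
#' and places each peak's onset (last upward crossing before the maximum)
#' and offset (first downward crossing after it) at the threshold
#' `f_base + max(k_onset * sigma_noise, onset_floor_frac * amplitude)`,
#' linearly interpolated between frames. The fractional-amplitude floor keeps
#' the threshold meaningful on noiseless traces.
#'
#' @param trace A [fluorescence_trace()].
#' @param min_prominence Minimum topographic prominence (a.u.); default
#'   `5 * sigma_noise` estimated from the provisional pass.
#' @param min_separation Minimum time between retained maxima in s; among
#'   conflicting maxima the highest is kept.
#' @param min_height_sd Minimum height of a maximum above the baseline, in
#'   noise-SD units (default 5). Prominence alone admits peak-to-trough
#'   noise excursions of up to ~7 SD; requiring the maximum itself to clear
#'   `f_base + min_height_sd * sigma_noise` suppresses them. `NULL`
#'   disables.
#' @param k_onset Multiplier on the noise SD for the onset/offset threshold.
#' @param onset_floor_frac Minimum onset/offset threshold as a fraction of
#'   each peak's amplitude above baseline.
#' @param tail_guard When re-estimating the baseline, samples up to
#'   `tail_guard * (t_offset - t_max)` beyond each provisional offset are
#'   also excluded, so that sub-threshold indicator-decay tails do not bias
#'   the inter-peak median upward.
#' @return A data frame (class `peak_table`) with one row per peak:
#'   `t_onset`, `t_max`, `t_offset`, `f_max`, `f_base`, `duration`, `fwhm`,
#'   `prominence`, `is_artifact`, `merged_from`, sorted by `t_onset`.
#'   Attributes `f_base` and `sigma_noise` carry the final baseline and
#'   noise-scale estimates.
#' @export
detect_peaks <- function(trace, min_prominence = NULL, min_separation = 1,
                         k_onset = 2, onset_floor_frac = 0.005,
                         tail_guard = 3, min_height_sd = 5) {
  v <- trace$values
  t <- trace$times
  empty <- empty_peak_table(stats::median(v), 0)

  # pass 1: provisional baseline and candidate maxima
  b0 <- rolling_percentile_baseline(v, trace$frame_period)
  sigma0 <- stats::mad(v - b0)
  cand <- local_maxima(v)
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  thr_prom <- if (is.null(min_prominence)) 5 * sigma0 else min_prominence
  keep <- prom >= thr_prom & prom > 0
  if (!is.null(min_height_sd)) {
    keep <- keep & v[cand] >= b0[cand] + min_height_sd * sigma0
  }
  cand <- cand[keep]
  prom <- prom[keep]
  if (!length(cand)) return(empty)
  # enforce separation, keeping the higher maximum
  ord <- order(v[cand], decreasing = TRUE)
  sel <- logical(length(cand))
  for (ci in ord) {
    if (!any(sel & abs(t[cand] - t[cand[ci]]) < min_separation)) {
      sel[ci] <- TRUE
    }
  }
  cand <- cand[sel]
  prom <- prom[sel]
  o <- order(cand)
  cand <- cand[o]
  prom <- prom[o]

  # provisional bounds -> final baseline and noise from inter-peak samples
  base0 <- stats::median(b0)
  thr0 <- pmax(base0 + k_onset * sigma0,
               base0 + onset_floor_frac * (v[cand] - base0))
  b1 <- peak_bounds(v, t, cand, thr0)
  prov <- data.frame(
    t_onset = b1$onset,
    t_offset = b1$offset + tail_guard * pmax(b1$offset - t[cand], 0)
  )
  out <- outside_peaks(trace, prov)
  if (!any(out)) {
    f_base <- base0
    sigma <- sigma0
  } else {
    f_base <- stats::median(v[out])
    sigma <- stats::mad(v[out])
  }

  # final pass with the settled threshold
  amp <- v[cand] - f_base
  ok <- amp > 0
  if (!is.null(min_height_sd)) {
    ok <- ok & v[cand] >= f_base + min_height_sd * sigma
  }
  cand <- cand[ok]
  prom <- prom[ok]
  amp <- amp[ok]
  if (!length(cand)) return(empty_peak_table(f_base, sigma))
  thrs <- f_base + pmax(k_onset * sigma, onset_floor_frac * amp)
  b2 <- peak_bounds(v, t, cand, thrs)
  peaks <- data.frame(
    t_onset = b2$onset, t_max = t[cand], t_offset = b2$offset,
    f_max = v[cand], f_base = f_base,
    duration = b2$offset - b2$onset, fwhm = NA_real_,
    prominence = prom, is_artifact = FALSE, merged_from = 1L
  )
  valid <- peaks$t_onset < peaks$t_max & peaks$t_max < peaks$t_offset &
    peaks$f_max > peaks$f_base
  peaks <- peaks[valid, , drop = FALSE]
  peaks <- peaks[order(peaks$t_onset), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks$fwhm <- vapply(seq_len(nrow(peaks)), function(p) {
    tryCatch(fwhm(peaks[p, ], trace), error = function(e) NA_real_)
  }, numeric(1))
  attr(peaks, "f_base") <- f_base
  attr(peaks, "sigma_noise") <- sigma
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

empty_peak_table <- function(f_base, sigma) {
  peaks <- data.frame(t_onset = numeric(0), t_max = numeric(0),
                      t_offset = numeric(0), f_max = numeric(0),
                      f_base = numeric(0), duration = numeric(0),
                      fwhm = numeric(0), prominence = numeric(0),
                      is_artifact = logical(0), merged_from = integer(0))
  attr(peaks, "f_base") <- f_base
  attr(peaks, "sigma_noise") <- sigma
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

#' Full width at half maximum of a peak
#'
#' Width between the two crossings of `f_base + (f_max - f_base) / 2`
#' nearest the maximum, linearly interpolated between frames. The half-max
#' level is measured above the baseline, not above zero.
#'
#' @param peak One row of a peak table.
#' @param trace The [fluorescence_trace()] the peak was detected on.
#' @return Width in seconds.
#' @export
fwhm <- function(peak, trace) {
  half <- peak$f_base + (peak$f_max - peak$f_base) / 2
  imax <- which.min(abs(trace$times - peak$t_max))
  lo <- which.min(abs(trace$times - peak$t_onset))
  hi <- which.min(abs(trace$times - peak$t_offset))
  left <- cross_left(trace$values, trace$times, imax, half, lo)
  right <- cross_right(trace$values, trace$times, imax, half, hi)
  if (is.na(left) || is.na(right)) {
    stop("half-maximum crossing not bracketed inside [t_onset, t_offset]",
         call. = FALSE)
  }
  right - left
}

#' Merge double-topped peaks
#'
#' Adjacent maxima closer than `merge_window` whose inter-maximum valley
#' stays above half of the lower maximum's amplitude (over baseline) are
#' merged into one peak spanning both; `merged_from` accumulates. The
#' operation is idempotent.
#'
#' @param peaks A peak table from [detect_peaks()].
#' @param trace The underlying [fluorescence_trace()].
#' @param merge_window Maximum inter-maximum gap in s to consider merging.
#' @return The merged peak table.
#' @export
merge_double_tops <- function(peaks, trace, merge_window = 1) {
  if (nrow(peaks) < 2) return(peaks)
  atts <- attributes(peaks)[c("f_base", "sigma_noise")]
  repeat {
    merged_any <- FALSE
    p <- 1L
    while (p < nrow(peaks)) {
      a <- peaks[p, ]
      b <- peaks[p + 1, ]
      gap <- b$t_max - a$t_max
      if (gap < merge_window) {
        i1 <- which.min(abs(trace$times - a$t_max))
        i2 <- which.min(abs(trace$times - b$t_max))
        valley <- min(trace$values[i1:i2])
        lower_amp <- min(a$f_max, b$f_max) - a$f_base
        if (valley - a$f_base > lower_amp / 2) {
          top <- if (a$f_max >= b$f_max) a else b
          merged <- a
          merged$t_onset <- a$t_onset
          merged$t_offset <- b$t_offset
          merged$t_max <- top$t_max
          merged$f_max <- top$f_max
          merged$prominence <- max(a$prominence, b$prominence)
          merged$duration <- merged$t_offset - merged$t_onset
          merged$merged_from <- a$merged_from + b$merged_from
          merged$is_artifact <- a$is_artifact && b$is_artifact
          merged$fwhm <- tryCatch(fwhm(merged, trace),
                                  error = function(e) NA_real_)
          peaks <- rbind(peaks[seq_len(p - 1), , drop = FALSE], merged,
                         peaks[-seq_len(p + 1), , drop = FALSE])
          rownames(peaks) <- NULL
          merged_any <- TRUE
          next
        }
      }
      p <- p + 1L
    }
    if (!merged_any) break
  }
  attr(peaks, "f_base") <- atts$f_base
  attr(peaks, "sigma_noise") <- atts$sigma_noise
  class(peaks) <- c("peak_table", "data.frame")
  peaks
}

#' Flag artifact peaks
#'
#' Default rules, each individually switchable: (a) duration shorter than
#' `min_duration_frames` frame periods (single-frame spikes); (b) amplitude
#' above `amplitude_outlier_mult` times the median peak amplitude — a robust
#' envelope on the population of detected transients (applied when at least
#' 3 peaks are present); (c) onset before the stimulus motion start.
#'
#' @param peaks A peak table.
#' @param trace The underlying [fluorescence_trace()].
#' @param min_duration_frames Minimum credible duration in frames, or `NULL`
#'   to disable.
#' @param amplitude_outlier_mult Amplitude outlier multiplier, or `NULL`.
#' @param t_move_start Stimulus motion start time in s, or `NULL` to skip
#'   the pre-stimulus rule.
#' @return The peak table with `is_artifact` set.
#' @export
flag_artifacts <- function(peaks, trace, min_duration_frames = 2,
                           amplitude_outlier_mult = 5, t_move_start = NULL) {
  if (!nrow(peaks)) return(peaks)
  flag <- peaks$is_artifact
  if (!is.null(min_duration_frames)) {
    flag <- flag | peaks$duration < min_duration_frames * trace$frame_period
  }
  if (!is.null(amplitude_outlier_mult) && nrow(peaks) >= 3) {
    amp <- peaks$f_max - peaks$f_base
    flag <- flag | amp > amplitude_outlier_mult * stats::median(amp)
  }
  if (!is.null(t_move_start)) {
    flag <- flag | peaks$t_onset < t_move_start
  }
  peaks$is_artifact <- flag
  peaks
}

#' Keep the first n non-artifact peaks
#'
#' Artifact-flagged peaks are excluded, then the first `n` peaks by onset
#' time are retained (all of them if fewer).
#'
#' @param peaks A peak table.
#' @param n Number of peaks to keep (default 5).
#' @return The filtered peak table.
#' @export
select_first_n <- function(peaks, n = 5L) {
  keep <- peaks[!peaks$is_artifact, , drop = FALSE]
  keep <- keep[order(keep$t_onset), , drop = FALSE]
  out <- utils::head(keep, n)
  rownames(out) <- NULL
  out
}

#' Peak durations
#' @param peaks A peak table.
#' @return `t_offset - t_onset` per peak, in s.
#' @export
duration <- function(peaks) {
  peaks$t_offset - peaks$t_onset
}

#' Inter-peak intervals
#'
#' Time from the offset of each peak to the onset of the next:
#' `t_onset[i + 1] - t_offset[i]`. Peaks must be sorted and non-overlapping
#' (guaranteed after merging).
#'
#' @param peaks A peak table.
#' @return Numeric vector of length `nrow(peaks) - 1` (empty for a single
#'   peak).
#' @export
inter_peak_intervals <- function(peaks) {
  m <- nrow(peaks)
  if (m < 2) return(numeric(0))
  if (is.unsorted(peaks$t_onset)) {
    stop("peaks must be sorted by onset", call. = FALSE)
  }
  iv <- peaks$t_onset[-1] - peaks$t_offset[-m]
  if (any(iv < -1e-9)) {
    stop("overlapping peaks: merge double tops before computing intervals",
         call. = FALSE)
  }
  pmax(iv, 0)
}

#' Maximum-to-baseline fluorescence ratio
#' @param peaks A peak table.
#' @return `f_max / f_base` per peak (dimensionless).
#' @export
fmax_fbase <- function(peaks) {
  peaks$f_max / peaks$f_base
}

#' One-call trace analysis
#'
#' Runs [detect_peaks()] and returns the peak table together with the final
#' baseline and noise-scale estimates.
#'
#' @param trace A [fluorescence_trace()].
#' @param ... Passed to [detect_peaks()].
#' @return A list with `peaks`, `f_base`, `sigma_noise`.
#' @export
analyze_trace <- function(trace, ...) {
  peaks <- detect_peaks(trace, ...)
  list(peaks = peaks, f_base = attr(peaks, "f_base"),
       sigma_noise = attr(peaks, "sigma_noise"))
}
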