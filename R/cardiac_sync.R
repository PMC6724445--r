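#' Construct an ECG trace with XA frame timestamps
#'
#' @param samples numeric vector of ECG samples (arbitrary units)
#' @param fs sampling rate in Hz (> 0)
#' @param frame_times XA frame timestamps in seconds, strictly increasing,
#'   all inside the trace duration; may be empty
#' @return object of class `ecg_trace`
#' @export
ecg_trace <- function(samples, fs, frame_times = numeric()) {
  if (!is.numeric(fs) || fs <= 0) abort("fs must be > 0")
  samples <- as.numeric(samples)
  duration <- length(samples) / fs
  if (length(frame_times) > 0L) {
    if (is.unsorted(frame_times, strictly = TRUE)) {
      abort("frame_times must be strictly increasing")
    }
    if (min(frame_times) < 0 || max(frame_times) > duration) {
      abort("frame_times must lie within the trace duration")
    }
  }
  structure(list(samples = samples, fs = fs, frame_times = as.numeric(frame_times),
                 duration = duration),
            class = "ecg_trace")
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(sprintf("<ecg_trace> %.3g s at %g Hz, %d frames\n",
              x$duration, x$fs, length(x$frame_times)))
  invisible(x)
}

#' Detect R peaks in an ECG trace
#'
#' Pan-Tompkins-style detection: zero-phase 5-15 Hz Butterworth band-pass,
#' squaring, then local maxima of the energy signal above an adaptive
#' threshold with an enforced refractory spacing of at least `min_rr`
#' seconds (candidates are accepted greedily by decreasing energy).
#'
#' @param trace an `ecg_trace` of at least 2 s
#' @param min_rr minimum R-R spacing in seconds (default 0.3 s, i.e. a
#'   200 bpm ceiling; also suppresses T-wave bumps)
#' @return sorted numeric vector of peak times in seconds (empty, with a
#'   warning, for a flat trace)
#' @export
detect_r_peaks <- function(trace, min_rr = 0.3) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (min_rr <= 0) abort("min_rr must be > 0")
  if (trace$duration < 2) abort("trace must be at least 2 s long")
  x <- trace$samples - mean(trace$samples)
  if (max(abs(x)) < .Machine$double.eps^0.5) {
    warn("flat ECG signal; no R peaks")
    return(numeric(0))
  }
  nyq <- trace$fs / 2
  hi <- min(15, 0.9 * nyq)
  bf <- signal::butter(2, c(5, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, x)
  e <- y^2
  n <- length(e)
  loc <- which(e[2:(n - 1)] >= e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n]) + 1L
  thr <- 0.1 * stats::quantile(e[loc], 0.99, names = FALSE)
  loc <- loc[e[loc] > thr]
  if (length(loc) == 0L) {
    warn("no R peaks above threshold")
    return(numeric(0))
  }
  loc <- loc[order(e[loc], decreasing = TRUE)]
  min_gap <- min_rr * trace$fs
  keep <- integer(0)
  for (i in loc) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  sort((keep - 1L) / trace$fs)
}

#' Cardiac phase of a time point within its R-R interval
#'
#' Phase is the fractional position of `frame_time` between the preceding
#' and following R peaks: 0 at an R peak, approaching 1 just before the
#' next.
#'
#' @param frame_time time in seconds (vectorized)
#' @param r_peaks sorted R-peak times
#' @return phase fraction(s) in `[0, 1)`
#' @export
frame_phase <- function(frame_time, r_peaks) {
  if (length(r_peaks) < 2L) abort("frame outside R-R coverage")
  vapply(frame_time, function(t) {
    if (t < r_peaks[1] || t > r_peaks[length(r_peaks)]) {
      abort("frame outside R-R coverage")
    }
    i <- findInterval(t, r_peaks, rightmost.closed = FALSE)
    if (i == length(r_peaks)) return(0)  # exactly at the last peak
    (t - r_peaks[i]) / (r_peaks[i + 1] - r_peaks[i])
  }, numeric(1))
}

circular_phase_dist <- function(a, b) {
  d <- abs(a - b) %% 1
  pmin(d, 1 - d)
}

#' Select XA frames matching a CTA acquisition phase
#'
#' Computes the cardiac phase of every XA frame from the detected R peaks
#' and returns the frames whose circular phase distance to `cta_phase` is at
#' most `tol`, sorted by closeness. If no frame falls within `tol`, the
#' single closest frame is returned so the result is never empty.
#'
#' @param trace an `ecg_trace` with frame timestamps
#' @param cta_phase CTA reconstruction-window phase, fraction of R-R in
#'   `[0, 1)`
#' @param tol phase tolerance in `(0, 0.5]`; default 0.05, about one frame
#'   at 15 fps and 75 bpm
#' @param r_peaks optional precomputed peak times; detected otherwise
#' @return tibble with columns `frame` (index), `time`, `phase`,
#'   `phase_dist`, sorted by `phase_dist`
#' @export
select_candidate_frames <- function(trace, cta_phase, tol = 0.05, r_peaks = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (cta_phase < 0 || cta_phase >= 1) abort("cta_phase must be in [0, 1)")
  if (tol <= 0 || tol > 0.5) abort("tol must be in (0, 0.5]")
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(trace)
  ft <- trace$frame_times
  ok <- which(ft >= r_peaks[1] & ft <= r_peaks[length(r_peaks)])
  if (length(r_peaks) < 2L || length(ok) == 0L) {
    abort("no frame with computable phase")
  }
  ph <- frame_phase(ft[ok], r_peaks)
  d <- circular_phase_dist(ph, cta_phase)
  res <- tibble(frame = ok, time = ft[ok], phase = ph, phase_dist = d)
  hit <- res[res$phase_dist <= tol, ]
  if (nrow(hit) == 0L) hit <- res[which.min(res$phase_dist), ]
  hit[order(hit$phase_dist, hit$frame), ]
}

#' Pick the best frame among candidates by registration error
#'
#' @param candidates integer frame indices (non-empty)
#' @param errors one registration error (final AADD) per candidate
#' @return the candidate frame index with minimal error; ties go to the
#'   earliest frame
#' @export
select_best_frame <- function(candidates, errors) {
  if (length(candidates) == 0L) abort("no candidate frames")
  stopifnot(length(candidates) == length(errors))
  best <- which(errors == min(errors))
  candidates[best[which.min(candidates[best])]]
}
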