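# Butterworth filtering and single-lead beat delineation.
#
# Filters are designed as cascaded second-order sections (biquads) from the
# analog Butterworth prototype via the bilinear transform. At ECG-typical
# cutoffs (0.5 Hz at 1 kHz sampling) the expanded transfer-function
# polynomial is numerically unusable in double precision, while the biquad
# cascade is exact to rounding; this is the standard remedy.

# Analog Butterworth prototype poles (left half-plane, unit cutoff)
butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Design digital Butterworth as second-order sections.
# Returns a list of sections, each list(b = c(b0,b1,b2), a = c(1,a1,a2)).
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  assert_that(cutoff_hz > 0 && cutoff_hz < fs / 2,
              "cutoff (%g Hz) must lie in (0, fs/2 = %g Hz)", cutoff_hz, fs / 2)
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)     # prewarped analog cutoff
  p <- butter_proto_poles(order)
  s_poles <- if (type == "low") wc * p else wc / p
  zp <- (2 * fs + s_poles) / (2 * fs - s_poles)   # bilinear transform
  # pair complex-conjugate poles; odd order leaves one real pole
  idx <- order(Im(zp))
  zp <- zp[idx]
  used <- rep(FALSE, length(zp))
  sections <- list()
  zero_at <- if (type == "low") -1 else 1        # digital zeros
  for (i in seq_along(zp)) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {                # real pole: first-order section
      a <- c(1, -Re(zp[i]), 0)
      b <- if (type == "low") c(1, 1, 0) else c(1, -1, 0)
    } else {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-9)[1]
      used[j] <- TRUE
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    }
    used[i] <- TRUE
    # normalize section gain at DC (low-pass) or Nyquist (high-pass)
    zref <- if (type == "low") 1 else -1
    g <- sum(b * zref^(0:2)) / sum(a * zref^(0:2))
    sections[[length(sections) + 1]] <- list(b = b / g, a = a)
  }
  sections
}

# Single-pass cascade filter
sosfilt <- function(sos, x) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

# Zero-phase (forward-backward) filtering with odd-reflection padding of
# length 3 x filter order at each edge.
filtfilt_sos <- function(sos, x, order) {
  n <- length(x)
  pad <- min(3L * order, n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- sosfilt(sos, ext)
  y <- rev(sosfilt(sos, rev(y)))
  y[(pad + 1):(pad + n)]
}

apply_zero_phase <- function(rec, order, cutoff_hz, type) {
  assert_that(all(is.finite(rec$samples)), "recording contains non-finite samples")
  sos <- butter_sos(order, cutoff_hz, rec$fs, type)
  out <- rec$samples
  for (j in seq_len(ncol(out))) out[, j] <- filtfilt_sos(sos, out[, j], order)
  ecg_recording(out, rec$fs, rec$leads, rec$t0)
}

#' Remove baseline wander
#'
#' Zero-phase high-pass filter: a 6th-order Butterworth with 0.5 Hz cutoff
#' applied forward and backward, per lead. The effective magnitude response
#' is the squared single-pass response; phase is identically zero, so wave
#' morphology and fiducial timing are preserved.
#'
#' @param rec an [ecg_recording()].
#' @param cutoff_hz high-pass cutoff in Hz (default 0.5).
#' @param order filter order of each pass (default 6).
#' @return The filtered `ecg_recording` (same leads, same length).
#' @export
remove_baseline <- function(rec, cutoff_hz = 0.5, order = 6) {
  assert_that(rec$fs > 2 * cutoff_hz, "fs too low for %g Hz high-pass", cutoff_hz)
  apply_zero_phase(rec, order, cutoff_hz, "high")
}

#' Remove high-frequency noise
#'
#' Zero-phase low-pass Butterworth filter. The record-level default is
#' 40 Hz / 3rd order; the T-wave stream extracted from the periodic component
#' is filtered again at 20 Hz / 6th order before warping.
#'
#' @param rec an [ecg_recording()].
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param order filter order of each pass.
#' @return The filtered `ecg_recording`.
#' @export
remove_highfreq <- function(rec, cutoff_hz = 40, order = 3) {
  apply_zero_phase(rec, order, cutoff_hz, "low")
}

#' Detect beats and delineate T waves on one lead
#'
#' QRS detection uses a band-passed (5-25 Hz), squared and moving-window
#' integrated envelope with an adaptive threshold and a 250 ms refractory
#' period, followed by R-peak refinement on the band-passed signal. T waves
#' are delineated per beat in a window after the QRS: the T peak is the
#' dominant smoothed extremum, and onset/end are located by the tangent
#' method -- the tangent at the steepest up/down slope is intersected with the
#' isoelectric (zero) line, giving sub-sample resolution. Beats whose T wave
#' is too small or violates onset < peak < end ordering are flagged missing
#' rather than fabricated.
#'
#' @param rec a filtered [ecg_recording()] (baseline removed).
#' @param lead lead name to analyse (default: first lead).
#' @param t_search_ms window after the R peak searched for the T wave,
#'   `c(start, end)` in ms (end also capped at 70% of the current RR).
#' @param min_t_rel minimum T-peak amplitude relative to the median R
#'   amplitude below which the T wave is flagged missing.
#' @return A `beat_annotations` data frame with one row per detected beat:
#'   `qrs` (R sample index), `t_on`, `t_peak`, `t_end` (fractional sample
#'   indices, `NA` when missing) and `rr_ms` (preceding RR interval).
#' @export
detect_and_delineate <- function(rec, lead = rec$leads[1],
                                 t_search_ms = c(90, 600), min_t_rel = 0.05) {
  assert_that(lead %in% rec$leads, "lead '%s' not present", lead)
  fs <- rec$fs
  x <- rec$samples[, lead]
  if (max(abs(x)) < 1e-9 || sd(x) < 1e-9) {
    warning("flat signal: no beats detected")
    return(empty_annotations())
  }

  # --- QRS detection (Pan-Tompkins style) ---
  bp <- filtfilt_sos(butter_sos(2, 5, fs, "high"), x, 2)
  bp <- filtfilt_sos(butter_sos(2, 25, fs, "low"), bp, 2)
  d <- c(0, diff(bp)) * fs
  env <- d^2
  w <- max(1L, round(0.12 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  thr <- 0.2 * quantile(env, 0.995)
  refr <- round(0.25 * fs)
  above <- env > thr
  peaks <- integer(0)
  i <- 1L
  n <- length(env)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      seg <- i:j
      peaks <- c(peaks, seg[which.max(env[seg])])
      i <- j + refr
    }
    i <- i + 1L
  }
  if (length(peaks) < 2) {
    warning("fewer than 2 beats detected")
    return(empty_annotations())
  }
  # refine R: extremum of |bp| within +-60 ms of envelope peak
  half <- round(0.06 * fs)
  half <- as.integer(half)
  qrs <- vapply(as.integer(peaks), function(p) {
    a <- max(1L, p - half); b <- min(n, p + half)
    a + which.max(abs(bp[a:b])) - 1L
  }, integer(1))
  qrs <- sort(unique(qrs))
  qrs <- qrs[c(TRUE, diff(qrs) > refr)]

  # --- T-wave delineation ---
  y <- filtfilt_sos(butter_sos(3, 25, fs, "low"), x, 3)
  dy <- c(0, diff(y)) * fs                      # uV per s
  r_amp <- median(abs(bp[qrs]))
  nb <- length(qrs)
  t_on <- t_peak <- t_end <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    rr_next <- if (k < nb) (qrs[k + 1] - qrs[k]) / fs * 1000 else Inf
    a <- qrs[k] + round(t_search_ms[1] / 1000 * fs)
    b <- qrs[k] + round(min(t_search_ms[2], 0.7 * rr_next) / 1000 * fs)
    if (b - a < 0.04 * fs || b > n) next
    # isoelectric level over this beat's RR interval: the signal spends most
    # of the interval on the baseline, so the median estimates it robustly
    # (the zero-phase high-pass shifts the baseline away from zero)
    beat_end <- if (k < nb) qrs[k + 1] else min(n, qrs[k] + round(fs))
    base <- median(y[qrs[k]:beat_end])
    seg <- a:b
    p <- seg[which.max(abs(y[seg] - base))]
    if (p <= a || p >= b) next                  # extremum on boundary: unreliable
    s <- sign(y[p] - base)
    if (abs(y[p] - base) < min_t_rel * r_amp) next
    up <- a:p
    mu <- up[which.max(s * dy[up])]
    dn <- p:b
    md <- dn[which.min(s * dy[dn])]
    if (abs(dy[mu]) < 1e-9 || abs(dy[md]) < 1e-9) next
    on <- mu - (y[mu] - base) / dy[mu] * fs     # fractional sample index
    en <- md - (y[md] - base) / dy[md] * fs
    if (!(on < p && p < en && en < (if (k < nb) qrs[k + 1] else n + 1))) next
    if (on <= qrs[k]) next
    t_on[k] <- on; t_peak[k] <- p; t_end[k] <- en
  }
  ann <- data.frame(qrs = qrs, t_on = t_on, t_peak = t_peak, t_end = t_end,
                    rr_ms = c(NA, diff(qrs)) / fs * 1000)
  class(ann) <- c("beat_annotations", "data.frame")
  attr(ann, "fs") <- fs
  attr(ann, "lead") <- lead
  ann
}

empty_annotations <- function() {
  ann <- data.frame(qrs = integer(0), t_on = numeric(0), t_peak = numeric(0),
                    t_end = numeric(0), rr_ms = numeric(0))
  class(ann) <- c("beat_annotations", "data.frame")
  ann
}

#' @export
print.beat_annotations <- function(x, ...) {
  cat(sprintf("<beat_annotations> %d beats, %d with delineated T waves\n",
              nrow(x), sum(!is.na(x$t_peak))))
  invisible(x)
}

# Internal invariant check used by tests and the pipeline
validate_annotations <- function(ann) {
  ok <- !is.na(ann$t_peak)
  assert_that(all(diff(ann$qrs) > 0), "qrs times not strictly increasing")
  assert_that(all(ann$t_on[ok] < ann$t_peak[ok] & ann$t_peak[ok] < ann$t_end[ok]),
              "t-wave fiducial ordering violated")
  nxt <- c(ann$qrs[-1], Inf)
  assert_that(all(ann$t_end[ok] < nxt[ok]), "t_end crosses next QRS")
  invisible(TRUE)
}
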