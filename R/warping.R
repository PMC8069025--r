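# Time-warping T-wave morphology markers.
#
# Waves are compared in the square-root-slope-function (SRSF) framework:
# both waves are mapped to normalized time [0, 1], q = sign(f') sqrt(|f'|)
# is computed, and the optimal monotone warping minimizing
# || q_ref - sqrt(g') (q_test o g) ||^2 is found by dynamic programming over
# piecewise-linear lattice paths. The warping is boundary-anchored (T onset
# to T onset, T end to T end), so duration differences appear as the
# deviation of the de-normalized warping from the identity. The marker dwu
# is the mean absolute deviation |gamma(t) - t| in ms over the reference
# support; dw attaches the sign of the mean deviation. The default sign
# convention is narrowing-positive: a test wave narrower than the reference
# (the hyperkalemic direction -- T waves narrow as potassium rises above
# the dialysis-end reference) gives dw > 0, so the marker grows with the
# potassium excess and the monotone-increasing sensing models apply
# directly. The widening-positive convention is available as an option.

# Admissible DP slopes: coprime (di, dj) steps, diagonal listed first so
# cost ties resolve to the identity path.
warp_steps <- function() {
  rbind(c(1, 1), c(1, 2), c(2, 1), c(1, 3), c(3, 1),
        c(2, 3), c(3, 2), c(1, 4), c(4, 1), c(3, 4), c(4, 3))
}

# SRSF of samples on a uniform grid over [0, 1], L2-normalized so the
# alignment is invariant to amplitude scaling.
srsf_norm <- function(f, n) {
  df <- pracma::gradient(f, 1 / (n - 1))
  q <- sign(df) * sqrt(abs(df))
  nrm <- sqrt(sum(q^2) / (n - 1))
  if (nrm > 0) q <- q / nrm
  q
}

#' Optimal time warping between two mean warped T waves
#'
#' @param ref,test waves as lists with `t` (ms, starting at 0) and `f`
#'   (amplitude); typically [compute_mwtw()] outputs.
#' @param grid_ms warping grid step on the reference support (default
#'   0.5 ms); both waves are resampled to the resulting common length on
#'   normalized time.
#' @param n_grid override the number of grid samples directly (used by
#'   small exact-search checks).
#' @param band Sakoe-Chiba band half-width as a fraction of the grid
#'   (admissible paths keep |i - j| below it); 1 disables the constraint.
#' @param sign_convention `"narrowing"` (default: a narrower test wave
#'   gives dw > 0, the hyperkalemic direction) or `"widening"`.
#' @return A `warping_result`: `t` (reference grid, ms), `gamma`
#'   (warped times, ms, strictly increasing, mapping the reference support
#'   boundaries onto the test support boundaries), `dwu` (mean |gamma - t|,
#'   ms), `dw` (signed), the DP `cost` and path node indices.
#' @export
warp_pair <- function(ref, test, grid_ms = 0.5, n_grid = NULL, band = 0.25,
                      sign_convention = c("narrowing", "widening")) {
  sign_convention <- match.arg(sign_convention)
  for (w in list(ref, test)) {
    assert_that(all(is.finite(w$t)) && all(is.finite(w$f)),
                "wave contains non-finite values")
    assert_that(length(w$t) >= 4, "wave too short to warp")
    rng <- diff(range(w$f))
    assert_that(rng > 1e-9 && rng > 1e-6 * max(abs(w$f), 1e-300),
                "unwarpable wave: near-flat amplitude")
  }
  T1 <- max(ref$t) - min(ref$t)
  T2 <- max(test$t) - min(test$t)
  assert_that(T1 > 0 && T2 > 0, "degenerate wave support")
  n <- if (is.null(n_grid)) max(round(T1 / grid_ms) + 1, 30) else as.integer(n_grid)
  u <- seq(0, 1, length.out = n)
  f1 <- approx(ref$t - min(ref$t), ref$f, u * T1, rule = 2)$y
  f2 <- approx(test$t - min(test$t), test$f, u * T2, rule = 2)$y
  q1 <- srsf_norm(f1, n)
  q2 <- srsf_norm(f2, n)
  res <- dp_warp_cpp(q1, q2, warp_steps(), band = band)
  # piecewise-linear warping through the DP nodes, on normalized time
  gam_n <- approx(u[res$i], u[res$j], xout = u)$y
  t_ms <- u * T1
  gamma <- T2 * gam_n
  dev <- gamma - t_ms
  dwu <- mean(abs(dev))
  s <- sign(sum(dev))
  if (sign_convention == "narrowing") s <- -s
  structure(list(t = t_ms, gamma = gamma, dwu = dwu,
                 dw = if (s == 0) 0 else s * dwu,
                 cost = res$cost, path_i = res$i, path_j = res$j,
                 n_grid = n),
            class = "warping_result")
}

# Exhaustive monotone-path search over the same step set and cost function
# as the DP; exponential, only for tiny grids. Used as an oracle.
exhaustive_warp_cost <- function(q1, q2, steps = warp_steps()) {
  n <- length(q1)
  dt <- 1 / (n - 1)
  interp_q <- function(q, pos) {
    pos <- pmin(pmax(pos, 0), n - 1)
    lo <- floor(pos); w <- pos - lo
    q[lo + 1] * (1 - w) + q[pmin(lo + 2, n)] * w
  }
  seg_cost <- function(i0, j0, i1, j1) {
    m <- (j1 - j0) / (i1 - i0)
    k <- (i0 + 1):i1
    g <- j0 + m * (k - i0)
    sum((q1[k + 1] - sqrt(m) * interp_q(q2, g))^2) * dt
  }
  best <- Inf
  best_path <- NULL
  recurse <- function(i, j, acc, path) {
    if (acc >= best) return()
    if (i == n - 1 && j == n - 1) {
      if (acc < best) { best <<- acc; best_path <<- path }
      return()
    }
    for (s in seq_len(nrow(steps))) {
      ni <- i + steps[s, 1]; nj <- j + steps[s, 2]
      if (ni > n - 1 || nj > n - 1) next
      recurse(ni, nj, acc + seg_cost(i, j, ni, nj),
              rbind(path, c(ni, nj)))
    }
  }
  recurse(0, 0, 0, matrix(c(0, 0), 1))
  list(cost = best, path = best_path + 1)
}

#' Mean warped T wave of a window
#'
#' Iterative warped average: the template is initialized from the wave of
#' median duration, time-scaled to the mean duration of the window; at each
#' iteration every wave is warped onto the template with [warp_pair()], the
#' aligned amplitudes are averaged, and iteration stops when the template
#' changes by less than `tol` (relative sup norm) or after `max_iter`
#' rounds (with a warning).
#'
#' @param win a `twave_window` from [extract_twave_windows()], or a plain
#'   list of waves (each `list(t, f)`).
#' @param grid_ms warping grid, ms.
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap.
#' @param band passed to [warp_pair()].
#' @return An `mwtw`: `t` (uniform ms grid from 0), `f`, `n_waves`, plus
#'   window provenance (`center_time_h`, `rr_median_ms`) when available.
#' @export
compute_mwtw <- function(win, grid_ms = 0.5, tol = 1e-3, max_iter = 10,
                         band = 0.25) {
  waves <- if (!is.null(win$waves)) win$waves else win
  assert_that(length(waves) >= 1, "no waves in window")
  durs <- vapply(waves, function(w) max(w$t) - min(w$t), numeric(1))
  mean_dur <- mean(durs)
  # deterministic, order-invariant initialization from the median duration
  med <- median(durs)
  key <- cbind(abs(durs - med), durs,
               vapply(waves, function(w) sum(w$f^2), numeric(1)),
               vapply(waves, function(w) sum(w$f), numeric(1)))
  o <- do.call(order, as.data.frame(key))
  init <- waves[[o[1]]]

  n_t <- max(round(mean_dur / grid_ms) + 1, 30)
  t_grid <- seq(0, mean_dur, length.out = n_t)
  u <- t_grid / mean_dur
  f_tpl <- approx(init$t - min(init$t), init$f, u * (max(init$t) - min(init$t)),
                  rule = 2)$y
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    tpl <- list(t = t_grid, f = f_tpl)
    aligned <- vapply(waves, function(w) {
      res <- warp_pair(tpl, w, grid_ms = grid_ms, n_grid = n_t, band = band)
      approx(w$t - min(w$t), w$f, pmin(pmax(res$gamma, 0), max(w$t) - min(w$t)),
             rule = 2)$y
    }, numeric(n_t))
    f_new <- rowMeans(aligned)
    delta <- max(abs(f_new - f_tpl)) / max(max(abs(f_tpl)), 1e-12)
    f_tpl <- f_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && length(waves) > 1)
    warning("MWTW iteration did not converge; returning last iterate")
  structure(list(t = t_grid, f = f_tpl, n_waves = length(waves),
                 center_time_h = win$center_time_h,
                 rr_median_ms = win$rr_median_ms,
                 converged = converged),
            class = "mwtw")
}

#' Extract 2-minute T-wave windows from the periodic component
#'
#' Windows are centered on a fixed minute grid of each hour (default the
#' 5th and 35th minutes). Within each window, delineated T waves from piC1
#' are low-pass filtered at 20 Hz (6th-order zero-phase Butterworth),
#' screened by a beat-rejection policy (duration deviating more than
#' `dur_dev` from the window median, or correlation with the window average
#' below `corr_min`), and stored with their time supports re-anchored at
#' T onset = 0. Windows with fewer than `min_beats` surviving waves are
#' flagged invalid rather than dropped.
#'
#' @param pc the periodic component recording ([apply_pica()] output); the
#'   first lead is analysed.
#' @param ann annotations of that lead ([detect_and_delineate()] on `pc`).
#' @param protocol the [session_protocol()] (for the duration).
#' @param grid_min minutes of each hour at which windows are centered.
#' @param half_width_s half window width in seconds (60 = 2-min windows).
#' @param min_beats minimum retained waves for a valid window.
#' @param corr_min,dur_dev beat-rejection thresholds.
#' @param edge_s guard band excluded at both record ends (filter edge
#'   transients).
#' @param max_waves cap on the number of waves kept per window (those
#'   closest to the window center); `Inf` keeps every wave, the reference
#'   behaviour.
#' @return A list of `twave_window` objects: `center_time_h`, `waves`,
#'   `rr_median_ms`, `n_used`, `n_rejected`, `valid`.
#' @export
extract_twave_windows <- function(pc, ann, protocol,
                                  grid_min = c(5, 35), half_width_s = 60,
                                  min_beats = 20, corr_min = 0.95,
                                  dur_dev = 0.25, edge_s = 10,
                                  max_waves = Inf) {
  fs <- pc$fs
  dur_s <- rec_duration_s(pc)
  y <- filtfilt_sos(butter_sos(6, 20, fs, "low"), pc$samples[, 1], 6)
  centers <- as.vector(outer(grid_min * 60, (0:ceiling(dur_s / 3600)) * 3600, "+"))
  centers <- sort(centers[centers - half_width_s >= edge_s &
                          centers + half_width_s <= dur_s - edge_s])
  ok <- !is.na(ann$t_peak)
  t_on_s <- ann$t_on / fs
  t_end_s <- ann$t_end / fs
  lapply(centers, function(ct) {
    inw <- which(ok & t_on_s >= ct - half_width_s & t_end_s <= ct + half_width_s)
    win <- list(center_time_h = ct / 3600, waves = list(),
                rr_median_ms = NA_real_, n_used = 0L,
                n_rejected = 0L, valid = FALSE)
    class(win) <- "twave_window"
    if (length(inw) == 0) return(win)
    waves <- lapply(inw, function(i) {
      idx <- seq(ann$t_on[i], ann$t_end[i], by = 1)  # fractional sample indices
      f <- approx(seq_along(y), y, idx, rule = 2)$y
      list(t = (idx - idx[1]) / fs * 1000, f = f)
    })
    durs <- vapply(waves, function(w) max(w$t), numeric(1))
    keep <- abs(durs - median(durs)) <= dur_dev * median(durs)
    if (sum(keep) >= 2) {
      norm100 <- vapply(waves[keep], function(w)
        approx(w$t / max(w$t), w$f, seq(0, 1, length.out = 100), rule = 2)$y,
        numeric(100))
      avg <- rowMeans(norm100)
      cc <- apply(norm100, 2, function(v)
        suppressWarnings(cor(v, avg)))
      cc[is.na(cc)] <- 0
      keep[keep] <- cc >= corr_min
    }
    if (is.finite(max_waves) && sum(keep) > max_waves) {
      kidx <- which(keep)
      ctr <- abs((ann$t_peak[inw[kidx]] / fs) - ct)
      keep[kidx[order(ctr)][-seq_len(max_waves)]] <- FALSE
    }
    win$waves <- waves[keep]
    win$n_used <- sum(keep)
    win$n_rejected <- length(waves) - win$n_used
    win$rr_median_ms <- median(ann$rr_ms[inw[keep]], na.rm = TRUE)
    win$valid <- win$n_used >= min_beats
    win
  })
}

#' Warping marker series against the dialysis-end reference
#'
#' Computes the signed warping marker dw of every valid window's mean
#' warped T wave against the fixed reference MWTW -- the valid window
#' nearest the dialysis end (ties resolve to the earlier window). The
#' marker at the reference window is exactly 0.
#'
#' @param mwtws list of [compute_mwtw()] results (entries may be `NULL`
#'   for invalid windows).
#' @param times_h window center times in hours.
#' @param rr_ms per-window median RR, ms.
#' @param reference_h the dialysis-end time h4, hours.
#' @param grid_ms warping grid.
#' @param band,sign_convention passed to [warp_pair()].
#' @return A `marker_series` data frame: `time_h`, `dw_ms`, `dwc_ms`
#'   (equal to `dw_ms` until [hr_correct()] runs), `rr_ms`, `valid`; the
#'   reference window index and time are attached as attributes.
#' @export
marker_series <- function(mwtws, times_h, rr_ms, reference_h,
                          grid_ms = 0.5, band = 0.25,
                          sign_convention = "narrowing") {
  valid <- !vapply(mwtws, is.null, logical(1))
  assert_that(any(valid), "no valid windows: patient unusable")
  cand <- which(valid)
  dist <- abs(times_h[cand] - reference_h)
  ref_idx <- cand[order(dist, times_h[cand])][1]
  ref <- mwtws[[ref_idx]]
  dw <- rep(NA_real_, length(mwtws))
  for (i in seq_along(mwtws)) {
    if (!valid[i]) next
    dw[i] <- if (i == ref_idx) 0 else
      warp_pair(ref, mwtws[[i]], grid_ms, band = band,
                sign_convention = sign_convention)$dw
  }
  out <- data.frame(time_h = times_h, dw_ms = dw, dwc_ms = dw,
                    rr_ms = rr_ms, valid = valid)
  class(out) <- c("marker_series", "data.frame")
  attr(out, "reference_index") <- ref_idx
  attr(out, "reference_h") <- times_h[ref_idx]
  out
}

#' Heart-rate correction of the warping marker
#'
#' Removes the component of dw attributable to heart-rate change via a
#' Bazett-like linear compensation in sqrt(RR): the coefficient is fitted
#' by least squares on a late post-dialysis stability segment (default the
#' final `stability_h` hours of the recording, where potassium-driven
#' marker dynamics are low), then
#' `dwc(t) = dw(t) - c_hat * (sqrt(RR(t)) - sqrt(RR_ref))`.
#'
#' @param series a [marker_series()].
#' @param stability_h length of the trailing stability segment, hours.
#' @return The series with `dwc_ms` filled; the fitted coefficient is in
#'   `attr(, "c_hat")`. If the stability segment has no RR variation or no
#'   valid points, `c_hat` falls back to 0 with a warning.
#' @export
hr_correct <- function(series, stability_h = 4) {
  ref_idx <- attr(series, "reference_index")
  assert_that(!is.null(ref_idx), "series lacks a reference window")
  rr_ref <- series$rr_ms[ref_idx]
  assert_that(is.finite(rr_ref), "reference window has no RR")
  x <- sqrt(series$rr_ms) - sqrt(rr_ref)
  t_max <- max(series$time_h[series$valid])
  in_seg <- series$valid & series$time_h >= t_max - stability_h &
    is.finite(x) & is.finite(series$dw_ms)
  sxx <- sum(x[in_seg]^2)
  if (!any(in_seg) || sxx < 1e-12) {
    if (!any(in_seg)) warning("stability segment missing: c_hat = 0")
    c_hat <- 0
  } else {
    c_hat <- sum(series$dw_ms[in_seg] * x[in_seg]) / sxx
  }
  series$dwc_ms <- if (c_hat == 0) series$dw_ms else series$dw_ms - c_hat * x
  series$dwc_ms[ref_idx] <- 0
  attr(series, "c_hat") <- c_hat
  attr(series, "rr_ref_ms") <- rr_ref
  series
}

#' Pair marker windows to blood-sample hours
#'
#' For each blood-sample hour the valid window nearest in time is used
#' (ties resolve to the earlier window).
#'
#' @param series a [marker_series()] (heart-rate corrected or not).
#' @param sample_hours the six blood-sample times, hours.
#' @param hour_labels labels for the output rows.
#' @return A data frame: `hour_label`, `time_h` (sample hour),
#'   `window_time_h`, `dw_ms`, `dwc_ms`, `rr_ms`.
#' @export
markers_at_hours <- function(series, sample_hours,
                             hour_labels = paste0("h", seq_along(sample_hours) - 1)) {
  cand <- which(series$valid)
  assert_that(length(cand) > 0, "no valid windows")
  rows <- lapply(seq_along(sample_hours), function(k) {
    dist <- abs(series$time_h[cand] - sample_hours[k])
    i <- cand[order(dist, series$time_h[cand])][1]
    data.frame(hour_label = hour_labels[k], time_h = sample_hours[k],
               window_time_h = series$time_h[i],
               dw_ms = series$dw_ms[i], dwc_ms = series$dwc_ms[i],
               rr_ms = series$rr_ms[i])
  })
  do.call(rbind, rows)
}
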