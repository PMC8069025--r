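# Periodic component analysis (piCA).
#
# A spatial transformation w maximizing one-beat periodicity of the chosen
# segment minimizes the Rayleigh quotient
#   eps(w) = E||w'x(t') - w'x(t)||^2 / E||w'x(t)||^2,
# where t runs over the analysis segment of beat i and t' is the
# time-aligned sample of beat i+1. With A the covariance of beat-to-beat
# differences and B the total covariance, stationary points solve the
# generalized eigenproblem A w = lambda B w; components are ordered by
# ascending lambda so the most periodic one comes first (piC1).

#' Fit the periodic-component transformation
#'
#' Beat-to-beat sample pairs are built by anchoring each beat's analysis
#' segment at its fiducials (T-wave onset to end for `piCT`; 60 ms before
#' the QRS to T end for `piCB`) and linearly resampling it to a fixed
#' length, so one-beat periodicity stays defined while RR drifts.
#'
#' @param rec an [ecg_recording()] with the 8 independent leads.
#' @param ann [detect_and_delineate()] annotations for `rec`.
#' @param mode `"piCT"` (T-wave periodicity, default) or `"piCB"` (QRST).
#' @param n_resample samples per segment after time normalization
#'   (default 400 for piCT, 600 for piCB).
#' @param min_beats minimum number of delineated beats required.
#' @return A `pica_transform`: `psi` (8 x 8, rows = component weights,
#'   most periodic first, unit variance under the total covariance),
#'   `eigenvalues` (ascending periodicity scores), `mode`, `leads`,
#'   `segment_def`.
#' @export
fit_pica <- function(rec, ann, mode = c("piCT", "piCB"),
                     n_resample = NULL, min_beats = 100) {
  mode <- match.arg(mode)
  assert_that(length(rec$leads) == 8, "piCA needs 8 independent leads")
  if (is.null(n_resample)) n_resample <- if (mode == "piCT") 400L else 600L
  fs <- rec$fs
  ok <- which(!is.na(ann$t_peak))
  assert_that(length(ok) >= min_beats,
              "only %d delineated beats, need >= %d", length(ok), min_beats)

  seg_bounds <- function(i) {
    if (mode == "piCT") c(ann$t_on[i], ann$t_end[i])
    else c(ann$qrs[i] - 0.06 * fs, ann$t_end[i])
  }
  X <- rec$samples
  n <- nrow(X)
  resample_seg <- function(i) {
    b <- seg_bounds(i)
    idx <- seq(max(b[1], 1), min(b[2], n), length.out = n_resample)
    lo <- floor(idx); hi <- pmin(lo + 1, n); w <- idx - lo
    X[lo, , drop = FALSE] * (1 - w) + X[hi, , drop = FALSE] * w
  }

  # accumulate covariances over consecutive delineated-beat pairs
  A <- B <- matrix(0, 8, 8)
  nA <- nB <- 0L
  prev_idx <- NA_integer_
  prev_seg <- NULL
  for (i in ok) {
    seg <- resample_seg(i)
    B <- B + crossprod(seg); nB <- nB + n_resample
    if (!is.na(prev_idx) && i == prev_idx + 1L) {
      D <- seg - prev_seg
      A <- A + crossprod(D); nA <- nA + n_resample
    }
    prev_idx <- i; prev_seg <- seg
  }
  assert_that(nA > 0, "no consecutive delineated beat pairs")
  A <- A / nA
  B <- B / nB

  # generalized symmetric eigenproblem via the eigenbasis of B; directions
  # of (numerically) zero total variance are treated as linearly dependent
  eb <- eigen(B, symmetric = TRUE)
  tol <- 1e-10 * max(eb$values)
  keep <- eb$values > tol
  assert_that(any(keep), "leads linearly dependent: total covariance is null")
  r <- sum(keep)
  Wh <- eb$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(eb$values[keep]), r, r)      # B-whitening, 8 x r
  M <- crossprod(Wh, A %*% Wh)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ordr <- order(es$values)                     # ascending: most periodic first
  W <- Wh %*% es$vectors[, ordr, drop = FALSE] # 8 x r, w' B w = I
  lambda <- pmax(es$values[ordr], 0)

  if (r < 8) {
    # null-variance directions appended last, flagged by NA eigenvalues
    Wnull <- eb$vectors[, !keep, drop = FALSE]
    W <- cbind(W, Wnull)
    lambda <- c(lambda, rep(NA_real_, 8 - r))
    warning(sprintf("leads linearly dependent: rank(B) = %d < 8", r))
  }

  psi <- t(W)                                   # rows = component weights
  # sign convention: median T-peak amplitude of each component positive
  tp <- round(ann$t_peak[ok])
  comp_tp <- X[tp, , drop = FALSE] %*% W
  flip <- apply(comp_tp, 2, function(v) if (median(v) < 0) -1 else 1)
  psi <- psi * flip
  dimnames(psi) <- list(paste0("piC", 1:8), rec$leads)

  structure(list(psi = psi, eigenvalues = lambda, mode = mode,
                 leads = rec$leads, n_resample = n_resample,
                 n_pairs = nA / n_resample,
                 segment_def = if (mode == "piCT") "t_on..t_end"
                               else "qrs-60ms..t_end"),
            class = "pica_transform")
}

#' @export
print.pica_transform <- function(x, ...) {
  cat(sprintf("<pica_transform> mode %s, eigenvalues: %s\n", x$mode,
              paste(signif(x$eigenvalues, 3), collapse = " ")))
  invisible(x)
}

#' Apply a periodic-component transformation
#'
#' @param rec an [ecg_recording()] with the same 8 leads, same order, the
#'   transform was fitted on.
#' @param tr a `pica_transform`.
#' @return An [ecg_recording()] of the 8 periodic components piC1..piC8
#'   (class also `periodic_component`), most periodic first. piC1 is
#'   `$samples[, 1]`.
#' @export
apply_pica <- function(rec, tr) {
  assert_that(identical(rec$leads, tr$leads),
              "lead set/order mismatch with fitted transform")
  pc <- rec$samples %*% t(tr$psi)
  out <- ecg_recording(pc, rec$fs, rownames(tr$psi), rec$t0)
  class(out) <- c("periodic_component", "ecg_recording")
  attr(out, "transform") <- tr
  out
}

# Rayleigh periodicity quotient of projection w on a fitted pair (A, B);
# used by tests as the direct definition of the score.
periodicity_quotient <- function(rec, ann, w, mode = "piCT",
                                 n_resample = 400L) {
  fs <- rec$fs
  ok <- which(!is.na(ann$t_peak))
  y <- rec$samples %*% w
  seg_bounds <- function(i) {
    if (mode == "piCT") c(ann$t_on[i], ann$t_end[i])
    else c(ann$qrs[i] - 0.06 * fs, ann$t_end[i])
  }
  n <- length(y)
  resample_seg <- function(i) {
    b <- seg_bounds(i)
    idx <- seq(max(b[1], 1), min(b[2], n), length.out = n_resample)
    lo <- floor(idx); hi <- pmin(lo + 1, n); wgt <- idx - lo
    y[lo] * (1 - wgt) + y[hi] * wgt
  }
  num <- den <- 0
  nn <- nd <- 0L
  prev_idx <- NA_integer_; prev_seg <- NULL
  for (i in ok) {
    seg <- resample_seg(i)
    den <- den + sum(seg^2); nd <- nd + n_resample
    if (!is.na(prev_idx) && i == prev_idx + 1L) {
      num <- num + sum((seg - prev_seg)^2); nn <- nn + n_resample
    }
    prev_idx <- i; prev_seg <- seg
  }
  (num / nn) / (den / nd)
}

#' Serialize a periodic-component transform to JSON
#'
#' @param tr a `pica_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pica_json <- function(tr, path) {
  jsonlite::write_json(list(mode = tr$mode, leads = tr$leads,
                            eigenvalues = tr$eigenvalues,
                            psi_row_major = as.vector(t(tr$psi)),
                            n_resample = tr$n_resample,
                            segment_def = tr$segment_def),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
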