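#' Construct a multi-lead ECG recording
#'
#' Container for a uniformly sampled multi-lead ECG. Amplitudes are in
#' microvolts, one column per lead.
#'
#' @param samples numeric matrix, samples x leads, in microvolts.
#' @param fs sampling rate in Hz.
#' @param leads character vector of lead names (defaults to column names).
#' @param t0 recording start time in seconds (clock offset; 0 by default).
#' @return An object of class `ecg_recording` with elements `samples`
#'   (matrix), `leads`, `fs` and `t0`.
#' @export
ecg_recording <- function(samples, fs, leads = colnames(samples), t0 = 0) {
  samples <- as.matrix(samples)
  if (is.null(leads)) leads <- paste0("ch", seq_len(ncol(samples)))
  assert_that(length(leads) == ncol(samples),
              "number of lead names (%d) != number of columns (%d)",
              length(leads), ncol(samples))
  assert_that(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs must be > 0")
  colnames(samples) <- leads
  structure(list(samples = samples, leads = leads, fs = fs, t0 = t0),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %d leads (%s), %d samples @ %g Hz (%.2f h)\n",
              length(x$leads), paste(x$leads, collapse = ","),
              nrow(x$samples), x$fs, nrow(x$samples) / x$fs / 3600))
  invisible(x)
}

# Number of samples / duration helpers
n_samples <- function(rec) nrow(rec$samples)
rec_duration_s <- function(rec) nrow(rec$samples) / rec$fs

#' Select the eight independent standard leads
#'
#' From a standard 12-lead set, keeps I, II and V1-V6; the limb leads III,
#' aVR, aVL, aVF are linear combinations of I and II and carry no independent
#' information for spatial transformations.
#'
#' @param rec an `ecg_recording`.
#' @return An `ecg_recording` restricted to the 8 independent leads, in
#'   canonical order. If the recording already holds exactly these leads it is
#'   returned reordered; leads other than the standard 12 cause an error.
#' @export
independent_leads <- function(rec) {
  want <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
  have <- intersect(want, rec$leads)
  assert_that(length(have) == 8,
              "need the 8 independent standard leads, found: %s",
              paste(rec$leads, collapse = ","))
  ecg_recording(rec$samples[, want, drop = FALSE], rec$fs, want, rec$t0)
}
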