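# Reading and writing ECG and laboratory files.
#
# WFDB support covers the subset this pipeline produces and consumes:
# single-segment records, all signals in one .dat file, format 16 (16-bit
# little-endian two's complement, interleaved). EDF support covers
# fixed-rate 16-bit signals. Both writers use the same digitization step
# (3.75 uV per ADC unit, the Holter amplitude resolution), so the two
# encodings of a record reconstruct identical amplitudes.

ADC_UV_PER_LSB <- 3.75

#' Write an ECG recording as a WFDB record
#'
#' Produces `<record>.hea` and `<record>.dat` (format 16, interleaved).
#' Amplitudes are digitized at 3.75 uV per ADC unit.
#'
#' @param rec an [ecg_recording()].
#' @param record record name (no extension).
#' @param dir output directory.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(rec, record, dir = ".") {
  n <- n_samples(rec)
  ns <- length(rec$leads)
  gain_per_mv <- 1000 / ADC_UV_PER_LSB    # ADC units per millivolt
  dig <- round(rec$samples / ADC_UV_PER_LSB)
  dig <- pmin(pmax(dig, -32768), 32767)
  storage.mode(dig) <- "integer"
  hea <- file.path(dir, paste0(record, ".hea"))
  dat <- paste0(record, ".dat")
  lines <- c(sprintf("%s %d %.9g %d", record, ns, rec$fs, n),
             sprintf("%s 16 %.17g(0)/mV 16 0 0 0 0 %s",
                     dat, gain_per_mv, rec$leads))
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  invisible(hea)
}

#' Read a WFDB record
#'
#' @param path path to the `.hea` file (or the record name without
#'   extension).
#' @return An [ecg_recording()] in microvolts.
#' @export
read_wfdb <- function(path) {
  if (!grepl("\\.hea$", path)) path <- paste0(path, ".hea")
  assert_that(file.exists(path), "no such header: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  assert_that(length(hd) >= 4, "malformed WFDB header line: %s", lines[1])
  ns <- as.integer(hd[2]); fs <- as.numeric(hd[3]); n <- as.integer(hd[4])
  sig <- lapply(lines[2:(1 + ns)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmts <- vapply(sig, `[[`, "", 2)
  assert_that(all(fmts == "16"), "only WFDB format 16 is supported")
  datf <- unique(vapply(sig, `[[`, "", 1))
  assert_that(length(datf) == 1, "multi-file WFDB records are not supported")
  gains <- vapply(sig, function(s) {
    g <- sub("\\(.*$", "", sub("/.*$", "", s[3]))
    as.numeric(g)
  }, numeric(1))
  base <- vapply(sig, function(s) {
    b <- regmatches(s[3], regexpr("\\(([-0-9]+)\\)", s[3]))
    if (length(b)) as.numeric(gsub("[()]", "", b)) else 0
  }, numeric(1))
  leads <- vapply(sig, function(s) if (length(s) >= 9) s[9] else "", "")
  if (any(leads == "")) leads <- paste0("ch", seq_len(ns))
  con <- file(file.path(dirname(path), datf), "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n * ns, size = 2, endian = "little",
                 signed = TRUE)
  X <- matrix(raw, ncol = ns, byrow = TRUE)
  for (j in seq_len(ns)) X[, j] <- (X[, j] - base[j]) / gains[j] * 1000  # -> uV
  ecg_recording(X, fs, leads)
}

# --- EDF (16-bit, fixed record duration) ---

edf_pad <- function(x, w) formatC(substr(as.character(x), 1, w), width = w, flag = "-")

#' Write an ECG recording as EDF
#'
#' 16-bit EDF with one-second data records and a physical scaling of
#' 3.75 uV per digital unit (identical to the WFDB writer, so the two
#' encodings reconstruct the same amplitudes).
#'
#' @param rec an [ecg_recording()].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  assert_that(abs(fs - round(fs)) < 1e-9, "EDF writer needs an integer fs")
  fs <- as.integer(round(fs))
  ns <- length(rec$leads)
  n <- n_samples(rec)
  nrec <- floor(n / fs)
  assert_that(nrec >= 1, "recording shorter than one EDF data record")
  # digital and physical ranges are chosen so both print exactly inside the
  # fixed-width EDF header fields and the scale is exactly 3.75 uV/LSB
  dig <- round(rec$samples / ADC_UV_PER_LSB)
  dig <- pmin(pmax(dig, -32000), 32000)
  storage.mode(dig) <- "integer"
  phys_min <- -32000 * ADC_UV_PER_LSB
  phys_max <- 32000 * ADC_UV_PER_LSB
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("EDF", 44)
  wr(nrec, 8); wr("1", 8); wr(ns, 4)
  for (l in rec$leads) wr(l, 16)
  for (i in seq_len(ns)) wr("synthetic ECG", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%d", as.integer(phys_min)), 8)
  for (i in seq_len(ns)) wr(sprintf("%d", as.integer(phys_max)), 8)
  for (i in seq_len(ns)) wr("-32000", 8)
  for (i in seq_len(ns)) wr("32000", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(dig[idx, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path path to a 16-bit EDF file with equal sampling rates across
#'   signals.
#' @return An [ecg_recording()] in the file's physical units (uV assumed).
#' @export
read_edf <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hbytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  assert_that(is.finite(ns) && ns > 0, "malformed EDF header")
  leads <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  assert_that(length(unique(spr)) == 1, "mixed sampling rates not supported")
  fs <- spr[1] / recdur
  X <- matrix(0, nrec * spr[1], ns)
  for (r in seq_len(nrec)) {
    blk <- readBin(con, "integer", n = spr[1] * ns, size = 2,
                   endian = "little", signed = TRUE)
    X[((r - 1) * spr[1] + 1):(r * spr[1]), ] <- matrix(blk, ncol = ns)
  }
  for (j in seq_len(ns)) {
    scale <- (pmax_[j] - pmin_[j]) / (dmax[j] - dmin[j])
    X[, j] <- pmin_[j] + (X[, j] - dmin[j]) * scale
    if (grepl("^mV$", units[j])) X[, j] <- X[, j] * 1000
  }
  ecg_recording(X, fs, leads)
}

#' Read an ECG file
#'
#' Dispatches on format; if the record holds a standard 12-lead set, the 8
#' independent leads (I, II, V1-V6) are selected and derived leads dropped.
#'
#' @param path file path (`.hea` or record name for WFDB, `.edf` for EDF).
#' @param format `"wfdb"` or `"edf"` (guessed from the extension by
#'   default).
#' @return An [ecg_recording()].
#' @export
read_ecg <- function(path, format = c("auto", "wfdb", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "wfdb"
  rec <- if (format == "edf") read_edf(path) else read_wfdb(path)
  std12 <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  if (all(std12 %in% rec$leads) || all(rec$leads %in% std12))
    rec <- independent_leads(rec)
  rec
}

#' Read a laboratory potassium table
#'
#' @param path CSV with columns `patient_id`, `hour_label`, `time_h`,
#'   `k_mmol` (the [write_lab_csv()] layout).
#' @return A data frame with those columns, one row per sample, ordered by
#'   patient then time.
#' @export
read_lab_csv <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "hour_label", "time_h", "k_mmol")
  assert_that(all(need %in% names(df)),
              "lab CSV must have columns: %s", paste(need, collapse = ", "))
  df$time_h <- as.numeric(df$time_h)
  df$k_mmol <- as.numeric(df$k_mmol)
  assert_that(all(is.finite(df$k_mmol)), "non-numeric potassium values")
  df[order(df$patient_id, df$time_h), need]
}
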