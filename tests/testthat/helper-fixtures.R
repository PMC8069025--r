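# Shared fixtures. Sessions are expensive to synthesize, so they are cached
# on disk (tempdir) and reused across test files within the session.

cache_fixture <- function(key, expr) {
  path <- file.path(tempdir(), paste0("kwarp-fixture-", key, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  val <- force(expr)
  saveRDS(val, path)
  val
}

# Short protocol for delineation-accuracy checks: 12 min at 500 Hz
short_protocol <- function(fs = 500) {
  session_protocol(duration_h = 0.2,
                   sample_hours = c(0, 0.03, 0.06, 0.09, 0.12, 0.18),
                   hd_end_h = 0.12, fs = fs)
}

# Clean (noise-free) short session, filtered, with lead-II annotations
clean_short_session <- function() {
  cache_fixture("clean-short", {
    proto <- short_protocol()
    s <- generate_session(proto, NULL,
                          morphology_coupling(wander_uv = 0, noise_uv = 0),
                          seed = 3)
    rec <- remove_highfreq(remove_baseline(s$rec))
    ann <- detect_and_delineate(rec, "II")
    list(proto = proto, s = s, rec = rec, ann = ann)
  })
}

# Noisy short session (default wander + broadband noise)
noisy_short_session <- function() {
  cache_fixture("noisy-short", {
    proto <- short_protocol()
    s <- generate_session(proto, NULL, morphology_coupling(), seed = 4)
    rec <- remove_highfreq(remove_baseline(s$rec))
    ann <- detect_and_delineate(rec, "II")
    list(proto = proto, s = s, rec = rec, ann = ann)
  })
}

# Compact end-to-end protocol: ~1.1 h, windows every 10 min, blood-sample
# hours placed exactly at six window centers so marker/potassium pairing is
# exact; dialysis "end" at 45 min
e2e_protocol <- function(fs = 200) {
  session_protocol(duration_h = 1.2,
                   sample_hours = c(5, 15, 25, 35, 45, 65) / 60,
                   hd_end_h = 45 / 60, fs = fs)
}

e2e_config <- function(...) {
  pipeline_config(window = list(grid_min = seq(5, 55, by = 10),
                                min_beats = 8, max_waves = 15),
                  hr_correction = list(stability_h = 0.3),
                  ...)
}

# Full pipeline run on a clean compact session (shared by several files)
e2e_run <- function() {
  cache_fixture("e2e-run", {
    proto <- e2e_protocol()
    s <- generate_session(proto, NULL,
                          morphology_coupling(wander_uv = 0, noise_uv = 0),
                          seed = 11)
    res <- suppressWarnings(
      run_patient(s$rec, s$gt$k_at_samples, proto, e2e_config()))
    list(proto = proto, s = s, res = res)
  })
}

# Raised-cosine lobe wave on [0, dur] ms
cosine_wave <- function(dur, n = 241, amp = 400) {
  t <- seq(0, dur, length.out = n)
  list(t = t, f = amp / 2 * (1 - cos(2 * pi * t / dur)))
}

# Match detected beats to ground-truth beats by R time; returns index map
match_beats <- function(ann, fid, fs, tol_s = 0.05) {
  rt <- ann$qrs / fs
  vapply(fid$r, function(x) {
    i <- which.min(abs(rt - x))
    if (abs(rt[i] - x) < tol_s) i else NA_integer_
  }, integer(1))
}
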