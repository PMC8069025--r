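# Constructed 8-lead mixtures with exact one-beat periodicity: a periodic
# source repeated at a fixed integer-sample period, mixed through a fixed
# vector, plus optional white noise. Annotations are built analytically so
# the periodicity pairing is exact.
periodic_mixture <- function(n_beats = 150, period = 400, fs = 500,
                             noise = 0, seed = 1) {
  withr::with_seed(seed, {
    beat <- numeric(period)
    tw <- 101:260                           # "T wave" segment of each beat
    beat[tw] <- 300 * sin(pi * seq_along(tw) / length(tw))^2
    beat[21:40] <- 800 * sin(pi * seq_len(20) / 20)    # "QRS"
    src <- rep(beat, n_beats)
    m <- c(0.5, 1, -0.4, 0.8, 1.2, 0.9, 0.7, 0.45)
    X <- outer(src, m)
    if (noise > 0) X <- X + matrix(rnorm(length(X), sd = noise), nrow(X))
    colnames(X) <- c("I", "II", paste0("V", 1:6))
    rec <- ecg_recording(X, fs)
    qrs <- (seq_len(n_beats) - 1) * period + 30
    ann <- data.frame(qrs = as.integer(qrs),
                      t_on = qrs + 71, t_peak = qrs + 150, t_end = qrs + 230,
                      rr_ms = c(NA, rep(period / fs * 1000, n_beats - 1)))
    class(ann) <- c("beat_annotations", "data.frame")
    list(rec = rec, ann = ann, src = src, mixing = m)
  })
}

test_that("a perfectly periodic source yields a zero leading eigenvalue", {
  mx <- periodic_mixture(noise = 0)
  tr <- suppressWarnings(fit_pica(mx$rec, mx$ann))    # rank-1 total covariance
  expect_lt(tr$eigenvalues[1], 1e-8)
})

test_that("the leading eigenvalue vanishes as noise vanishes", {
  lam <- vapply(c(20, 5, 1, 0.01), function(nv) {
    mx <- periodic_mixture(noise = nv, seed = 2)
    fit_pica(mx$rec, mx$ann)$eigenvalues[1]
  }, numeric(1))
  expect_true(all(diff(lam) < 0))
  expect_lt(lam[4], 1e-4)
})

test_that("piC1 recovers the periodic source under noise", {
  mx <- periodic_mixture(noise = 20, seed = 3)
  tr <- fit_pica(mx$rec, mx$ann)
  pc <- apply_pica(mx$rec, tr)
  expect_gt(abs(cor(pc$samples[, 1], mx$src)), 0.95)
  expect_true(all(diff(tr$eigenvalues) >= -1e-12))    # ascending order
})

test_that("permuting lead order leaves piC1 unchanged up to sign", {
  mx <- periodic_mixture(noise = 10, seed = 4)
  tr1 <- fit_pica(mx$rec, mx$ann)
  pc1 <- apply_pica(mx$rec, tr1)$samples[, 1]
  perm <- c(3, 1, 5, 2, 8, 4, 6, 7)
  rec_p <- ecg_recording(mx$rec$samples[, perm], mx$rec$fs,
                         mx$rec$leads[perm])
  tr2 <- fit_pica(rec_p, mx$ann)
  pc2 <- apply_pica(rec_p, tr2)$samples[, 1]
  err <- min(max(abs(pc2 - pc1)), max(abs(pc2 + pc1)))
  expect_lt(err / max(abs(pc1)), 1e-6)
})

test_that("applying an identity transform returns the first lead; scaling is linear", {
  mx <- periodic_mixture(noise = 5, seed = 5)
  tr <- fit_pica(mx$rec, mx$ann)
  id <- tr
  id$psi <- diag(8)
  dimnames(id$psi) <- dimnames(tr$psi)
  expect_equal(apply_pica(mx$rec, id)$samples[, 1],
               unname(mx$rec$samples[, 1]))
  rec2 <- ecg_recording(mx$rec$samples * 2, mx$rec$fs, mx$rec$leads)
  expect_equal(apply_pica(rec2, tr)$samples[, 1],
               2 * apply_pica(mx$rec, tr)$samples[, 1])
})

test_that("the fitted component attains its own periodicity quotient", {
  mx <- periodic_mixture(noise = 15, seed = 6)
  tr <- fit_pica(mx$rec, mx$ann)
  eps <- kwarp:::periodicity_quotient(mx$rec, mx$ann, tr$psi[1, ])
  expect_equal(eps, tr$eigenvalues[1], tolerance = 1e-6)
})

test_that("piC1 minimizes the periodicity quotient over random projections", {
  mx <- periodic_mixture(n_beats = 60, noise = 15, seed = 7)
  tr <- fit_pica(mx$rec, mx$ann, min_beats = 50)
  lam1 <- tr$eigenvalues[1]
  withr::with_seed(42, {
    for (k in 1:1000) {
      w <- rnorm(8)
      w <- w / sqrt(sum(w^2))
      eps <- kwarp:::periodicity_quotient(mx$rec, mx$ann, w)
      expect_gte(eps, lam1 * (1 - 1e-9))
    }
  })
})

test_that("refitting identical input reproduces piC1 including its sign", {
  mx <- periodic_mixture(noise = 10, seed = 8)
  tr1 <- fit_pica(mx$rec, mx$ann)
  tr2 <- fit_pica(mx$rec, mx$ann)
  expect_identical(tr1$psi, tr2$psi)
  # sign convention: median T-peak amplitude of piC1 is positive
  pc <- apply_pica(mx$rec, tr1)
  tp <- round(mx$ann$t_peak)
  expect_gt(median(pc$samples[tp, 1]), 0)
})

test_that("lead mismatch and insufficient beats abort", {
  mx <- periodic_mixture(noise = 5, seed = 9)
  tr <- fit_pica(mx$rec, mx$ann)
  rec_bad <- ecg_recording(mx$rec$samples[, c(2, 1, 3:8)], mx$rec$fs,
                           mx$rec$leads[c(2, 1, 3:8)])
  expect_error(apply_pica(rec_bad, tr), "mismatch")
  expect_error(fit_pica(mx$rec, mx$ann[1:20, ], min_beats = 100),
               "delineated beats")
})

test_that("transform serializes to JSON with eigenvalues and mode", {
  mx <- periodic_mixture(noise = 5, seed = 10)
  tr <- fit_pica(mx$rec, mx$ann)
  path <- tempfile(fileext = ".json")
  write_pica_json(tr, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$mode, "piCT")
  expect_equal(j$eigenvalues, tr$eigenvalues, tolerance = 1e-12)
  expect_equal(matrix(j$psi_row_major, 8, 8, byrow = TRUE),
               unname(tr$psi), tolerance = 1e-12)
})
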