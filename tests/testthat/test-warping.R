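test_that("warping a wave onto itself is the identity", {
  ref <- cosine_wave(180)
  r <- warp_pair(ref, ref)
  expect_equal(r$dwu, 0)
  expect_equal(r$dw, 0)
  expect_equal(r$gamma, r$t)
})

test_that("pure time scaling matches the closed-form warping", {
  ref <- cosine_wave(180)
  tst <- cosine_wave(180 * 1.1)
  r <- warp_pair(ref, tst)
  # gamma(t) = 1.1 t, so mean |gamma - t| = 0.05 * T_ref
  expect_equal(r$dwu, 0.05 * 180, tolerance = 0.05)
  expect_equal(r$gamma, 1.1 * r$t, tolerance = 1e-6)
  # narrowing-positive convention: a WIDER test wave gives dw < 0
  expect_lt(r$dw, 0)
  # widening-positive convention restores the opposite sign
  r2 <- warp_pair(ref, tst, sign_convention = "widening")
  expect_gt(r2$dw, 0)
  expect_equal(r2$dwu, r$dwu)
  # and a narrower test wave is positive under the default
  expect_gt(warp_pair(ref, cosine_wave(180 * 0.9))$dw, 0)
})

test_that("a known smooth warping is recovered within 2 ms RMS", {
  n <- 361
  T1 <- 180
  u <- seq(0, 1, length.out = n)
  ref <- cosine_wave(T1, n)
  gam_n <- u + 0.06 * sin(pi * u)           # monotone, end-anchored
  gi <- approx(gam_n, u, xout = u)$y        # inverse warping
  tst <- list(t = u * T1, f = approx(u * T1, ref$f, gi * T1)$y)
  r <- warp_pair(ref, tst, n_grid = n, band = 1)
  expect_lt(sqrt(mean((r$gamma - gam_n * T1)^2)), 2)
})

test_that("dynamic programming equals exhaustive monotone-path search", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      f1 <- cumsum(rnorm(12))
      f2 <- cumsum(rnorm(12))
    })
    q1 <- kwarp:::srsf_norm(f1, 12)
    q2 <- kwarp:::srsf_norm(f2, 12)
    dp <- kwarp:::dp_warp_cpp(q1, q2, kwarp:::warp_steps(), band = 1)
    ex <- kwarp:::exhaustive_warp_cost(q1, q2)
    expect_equal(dp$cost, ex$cost, tolerance = 1e-12)
  }
})

test_that("warping functions are strictly monotone on random smooth pairs", {
  withr::with_seed(11, {
    for (k in 1:20) {
      d1 <- runif(1, 120, 240); d2 <- runif(1, 120, 240)
      a1 <- runif(1, 200, 600); a2 <- runif(1, 200, 600)
      skew <- runif(1, 0.8, 1.25)
      w1 <- cosine_wave(d1, amp = a1)
      t2 <- seq(0, d2, length.out = 241)
      w2 <- list(t = t2, f = a2 / 2 * (1 - cos(2 * pi * (t2 / d2)^skew)))
      r <- warp_pair(w1, w2)
      expect_true(all(diff(r$gamma) > 0))
      expect_equal(abs(r$dw), r$dwu)
      expect_equal(r$gamma[1], 0)
      expect_equal(r$gamma[length(r$gamma)], d2, tolerance = 1e-9)
    }
  })
})

test_that("the unsigned marker is near-symmetric in its arguments", {
  withr::with_seed(12, {
    for (k in 1:8) {
      w1 <- cosine_wave(runif(1, 150, 210), amp = 400)
      w2 <- cosine_wave(runif(1, 150, 210), amp = 350)
      d12 <- warp_pair(w1, w2)$dwu
      d21 <- warp_pair(w2, w1)$dwu
      if (d12 > 0.5)                        # relative check needs signal
        expect_lt(abs(d12 - d21) / max(d12, d21), 0.10)
    }
  })
})

test_that("flat waves are rejected as unwarpable", {
  flat <- list(t = seq(0, 100, length.out = 60), f = rep(3, 60))
  ref <- cosine_wave(100, 60)
  expect_error(warp_pair(ref, flat), "unwarpable")
  expect_error(warp_pair(flat, ref), "unwarpable")
})

test_that("the mean warped T wave of identical waves is that wave", {
  w <- cosine_wave(180, 241)
  m <- compute_mwtw(list(w, w, w, w))
  expect_equal(max(m$t), 180)
  wi <- approx(w$t, w$f, m$t)$y
  expect_lt(max(abs(m$f - wi)), 1e-9)
  expect_true(m$converged)
})

test_that("the mean of two time-scalings has the central duration", {
  w09 <- cosine_wave(180 * 0.9)
  w11 <- cosine_wave(180 * 1.1)
  m <- compute_mwtw(list(w09, w11))
  expect_equal(max(m$t), 180, tolerance = 0.02)
  # shape matches the unit-scale wave after support alignment
  ref <- cosine_wave(180)
  expect_equal(m$f, approx(ref$t, ref$f, m$t)$y, tolerance = 0.02 * 400)
})

test_that("the mean warped T wave is invariant to wave order", {
  withr::with_seed(13, {
    waves <- lapply(runif(7, 150, 210), cosine_wave)
  })
  m1 <- compute_mwtw(waves)
  m2 <- compute_mwtw(rev(waves))
  expect_equal(m1$f, m2$f)
  expect_equal(m1$t, m2$t)
})

test_that("marker series anchor at the reference and tolerate gaps", {
  mwtws <- list(compute_mwtw(list(cosine_wave(200))), NULL,
                compute_mwtw(list(cosine_wave(180))), NULL,
                compute_mwtw(list(cosine_wave(190))))
  times <- c(0.1, 0.35, 0.6, 0.85, 1.1)
  s <- marker_series(mwtws, times, rr_ms = rep(900, 5), reference_h = 0.6)
  expect_equal(attr(s, "reference_h"), 0.6)
  expect_equal(s$dw_ms[3], 0)
  expect_true(is.na(s$dw_ms[2]) && is.na(s$dw_ms[4]))
  # reference is 180 ms; the 200 and 190 ms waves are wider, so the
  # narrowing-positive marker is negative, more so for the wider wave
  expect_lt(s$dw_ms[1], s$dw_ms[5])
  expect_lt(s$dw_ms[5], 0)
})

test_that("all-invalid windows except the reference still work", {
  mwtws <- list(NULL, compute_mwtw(list(cosine_wave(180))), NULL)
  s <- marker_series(mwtws, c(0.1, 0.5, 0.9), rep(850, 3), reference_h = 0.5)
  expect_equal(s$dw_ms[2], 0)
  expect_true(all(is.na(s$dw_ms[c(1, 3)])))
  expect_error(marker_series(list(NULL, NULL), c(0, 1), c(1, 1), 0.5),
               "unusable")
})

test_that("heart-rate correction is exact under constant RR and shrinks RR-driven markers", {
  # constant RR: the correction term vanishes identically
  mwtws <- lapply(c(200, 190, 180, 185), function(d) compute_mwtw(list(cosine_wave(d))))
  s <- marker_series(mwtws, c(0.1, 0.4, 0.7, 1.0), rep(880, 4), reference_h = 0.7)
  sc <- hr_correct(s, stability_h = 2)
  expect_equal(sc$dwc_ms, sc$dw_ms)
  expect_equal(attr(sc, "c_hat"), 0)

  # a marker series that is entirely RR-driven collapses after correction
  withr::with_seed(21, {
    rr <- seq(820, 980, length.out = 12) * (1 + 0.004 * rnorm(12))
  })
  ref_i <- 6
  x <- sqrt(rr) - sqrt(rr[ref_i])
  dw <- 1.8 * x
  df <- data.frame(time_h = seq(0.1, 4.5, length.out = 12), dw_ms = dw,
                   dwc_ms = dw, rr_ms = rr, valid = TRUE)
  class(df) <- c("marker_series", "data.frame")
  attr(df, "reference_index") <- ref_i
  out <- hr_correct(df, stability_h = 2)
  keep <- seq_len(12)[-ref_i]
  expect_lt(mean(abs(out$dwc_ms[keep])), 0.3 * mean(abs(out$dw_ms[keep])))
})

test_that("missing stability segment falls back to no correction", {
  # the trailing window holds only a point without RR: no usable segment
  mwtws <- lapply(c(180, 200), function(d) compute_mwtw(list(cosine_wave(d))))
  s <- marker_series(mwtws, c(0.1, 0.5), c(900, NA), reference_h = 0.1)
  expect_warning(sc <- hr_correct(s, stability_h = 0.1), "c_hat = 0")
  expect_equal(sc$dwc_ms, sc$dw_ms)
})
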