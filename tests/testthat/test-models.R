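# Brute-force SSE minimizer over a non-negative coefficient grid; the
# independent oracle for the constrained fits.
grid_nnls <- function(X, y, upper, step = 1e-3) {
  g1 <- seq(0, upper[1], by = step)
  if (ncol(X) == 1) {
    sse <- vapply(g1, function(a) sum((y - X[, 1] * a)^2), numeric(1))
    return(g1[which.min(sse)])
  }
  g2 <- seq(0, upper[2], by = step)
  best <- c(NA, NA); best_sse <- Inf
  for (a in g1) {
    r <- y - X[, 1] * a
    sse <- vapply(g2, function(b) sum((r - X[, 2] * b)^2), numeric(1))
    i <- which.min(sse)
    if (sse[i] < best_sse) { best_sse <- sse[i]; best <- c(a, g2[i]) }
  }
  best
}

# Mid-rank Spearman computed from first principles on tiny vectors
spearman_brute <- function(x, y) {
  rk <- function(v) vapply(v, function(a) mean(which(sort(v) == a)), numeric(1))
  cor(rk(x), rk(y))
}

test_that("potassium variation is the elementwise difference from the reference", {
  ks <- delta_k(c(5.6, 5.0, 4.4, 4.0, 3.6, 5.2))
  expect_equal(ks$delta_k, c(2.0, 1.4, 0.8, 0.4, 0.0, 1.6))
  expect_equal(ks$delta_k[ks$hours == "h4"], 0)
  expect_equal(delta_k(rep(4.4, 6))$delta_k, rep(0, 6))
  expect_error(delta_k(c(5, 4, 3), hours = c("h0", "h1", "h2")), "reference")
})

test_that("exact linear data is fitted exactly", {
  d <- c(0, 2, 4, 6, 8, 10)
  m <- fit_kmodel(d, 2 * d, "linear")
  expect_equal(unname(m$coef), 2, tolerance = 1e-10)
  expect_equal(m$sse, 0, tolerance = 1e-12)
})

test_that("a negative relation pins the constrained coefficient at zero", {
  d <- c(0, 2, 4, 6, 8, 10)
  dk <- -d
  m <- fit_kmodel(d, dk, "linear", constrained = TRUE)
  expect_equal(unname(m$coef), 0)
  # oracle: scan alpha >= 0
  a_star <- grid_nnls(cbind(d), dk, upper = 2)
  expect_equal(unname(m$coef), a_star, tolerance = 1e-3)
  # unconstrained recovers the true negative slope
  mu <- fit_kmodel(d, dk, "linear", constrained = FALSE)
  expect_equal(unname(mu$coef), -1, tolerance = 1e-10)
})

test_that("noise-free cubic data in the interior is recovered to 1e-6", {
  d <- c(0, 5, 10, 15, 20, 25)
  dk <- 0.5 * d + 0.1 * d^2 + 0.02 * d^3
  m <- fit_kmodel(d, dk, "cubic", constrained = TRUE)
  expect_equal(unname(m$coef), c(0.5, 0.1, 0.02), tolerance = 1e-6)
})

test_that("constrained solutions match grid search on 2-coefficient problems", {
  withr::with_seed(31, {
    for (k in 1:5) {
      d <- sort(runif(6, 0, 10)); d[1] <- 0
      dk <- runif(1, -0.1, 0.25) * d + runif(1, -0.005, 0.02) * d^2 +
        rnorm(6, sd = 0.15)
      X <- cbind(d, d^2)
      m <- fit_kmodel(d, dk, "quadratic", constrained = TRUE)
      g <- grid_nnls(X, dk, upper = c(0.5, 0.05), step = 1e-3)
      expect_lt(max(abs(unname(m$coef) - g)), 2e-3)
    }
  })
})

test_that("estimates follow the intercept-free polynomial", {
  m <- structure(list(coef = c(alpha = 0.5), order = "linear",
                      constrained = TRUE), class = "kmodel")
  expect_equal(estimate_delta_k(m, 3), 1.5)
  expect_equal(estimate_delta_k(m, 0), 0)
  mc <- fit_kmodel(c(0, 5, 10, 15, 20, 25),
                   0.5 * c(0, 5, 10, 15, 20, 25), "cubic")
  expect_equal(estimate_delta_k(mc, 0), 0)
})

test_that("every constrained fit is monotone non-decreasing for positive markers", {
  withr::with_seed(32, {
    for (k in 1:20) {
      d <- c(0, sort(runif(5, 0.5, 14)))
      dk <- cumsum(c(0, runif(5, -0.3, 0.6)))   # not necessarily monotone data
      for (o in c("linear", "quadratic", "cubic")) {
        m <- fit_kmodel(d, dk, o, constrained = TRUE)
        grid <- seq(0.001, 20, length.out = 400)
        p <- length(m$coef)
        deriv <- rowSums(vapply(seq_len(p), function(j)
          j * m$coef[j] * grid^(j - 1), numeric(400)))
        expect_true(all(deriv >= -1e-12))
      }
    }
  })
})

test_that("constrained training SSE is non-increasing in model order", {
  withr::with_seed(33, {
    for (k in 1:10) {
      d <- c(0, sort(runif(5, 0.5, 12)))
      dk <- 0.1 * d + rnorm(6, sd = 0.3)
      sse <- vapply(c("linear", "quadratic", "cubic"), function(o)
        fit_kmodel(d, dk, o, constrained = TRUE)$sse, numeric(1))
      expect_true(all(diff(sse) <= 1e-10))
    }
  })
})

test_that("degenerate designs and short data abort", {
  expect_error(fit_kmodel(rep(0, 6), rnorm(6), "linear"), "degenerate")
  expect_error(fit_kmodel(c(0, 1), c(0, 1), "quadratic"), "training points")
  expect_error(fit_kmodel(c(0, 1, NA, 2), c(0, 1, 2, 3), "linear"),
               "non-finite")
})

test_that("per-patient bookkeeping: all-samples fits and LOO refits", {
  ks <- delta_k(c(5.6, 5.0, 4.4, 4.0, 3.6, 5.2))
  d <- c(12, 7, 4, 2, 0, 10)
  fits <- fit_all_hours(d, ks)
  expect_named(fits, c("linear", "quadratic", "cubic"))
  expect_equal(fits$quadratic$training_hours, paste0("h", 0:5))
  expect_true(fits$quadratic$sse <= fits$linear$sse + 1e-10)
  expect_true(fits$cubic$sse <= fits$quadratic$sse + 1e-10)

  est_o <- loo_cv(d, ks)
  expect_named(est_o, c("linear", "quadratic", "cubic"))
  # five held-out predictions plus an exact zero at the reference
  expect_equal(est_o$linear[5], 0)
  expect_equal(sum(is.finite(est_o$linear)), 6)
  # each held-out value equals direct evaluation of the refit model
  refit <- fit_kmodel(d[-1], ks$delta_k[-1], "quadratic")
  expect_equal(est_o$quadratic[1], estimate_delta_k(refit, d[1]))
})

test_that("markers missing an hour are dropped with a warning", {
  ks <- delta_k(c(5.6, 5.0, 4.4, 4.0, 3.6, 5.2))
  d <- c(12, NA, 4, 2, 0, 10)
  expect_warning(fits <- fit_all_hours(d, ks), "h1")
  expect_equal(fits$linear$training_hours, paste0("h", c(0, 2:5)))
})

test_that("extrapolated leave-one-out errors exceed all-samples errors", {
  # h0 marker far outside the training range: the cubic extrapolates badly
  d <- c(30, 5, 3.5, 2, 0, 6)
  ks <- delta_k(c(6.3, 4.3, 4.0, 3.8, 3.6, 4.5))
  fits <- fit_all_hours(d, ks)
  est_a <- estimate_delta_k(fits$cubic, d)
  est_o <- loo_cv(d, ks)$cubic
  e_a <- abs(est_a[1] - ks$delta_k[1])
  e_o <- abs(est_o[1] - ks$delta_k[1])
  expect_gt(e_o, e_a)
})

test_that("evaluation reproduces exact fits and rank-invariant correlations", {
  ks <- delta_k(c(5.6, 5.0, 4.4, 4.0, 3.6, 5.2))
  ev <- evaluate_estimates(ks$delta_k, ks)
  expect_equal(ev$spearman, 1)
  expect_equal(ev$pearson, 1)
  expect_equal(unname(ev$errors), rep(0, 5))
  expect_named(ev$errors, paste0("h", c(0:3, 5)))
  # monotone but curved: rank correlation stays 1, Pearson drops
  ev3 <- evaluate_estimates(ks$delta_k^3, ks)
  expect_equal(ev3$spearman, 1)
  expect_lt(ev3$pearson, 1)
})

test_that("tied estimates match a brute-force mid-rank Spearman", {
  ks <- delta_k(c(5.6, 5.0, 4.4, 4.0, 3.6, 5.2))
  est <- c(1.2, 1.2, 0.6, 0.3, 0, 1.2)       # triple tie
  ev <- evaluate_estimates(est, ks)
  expect_equal(ev$spearman, spearman_brute(ks$delta_k, est), tolerance = 1e-12)
})

test_that("cohort aggregation uses median and linear-interpolation IQR", {
  coh <- simulate_marker_cohort(n_patients = 12, seed = 5)
  evals <- lapply(coh, function(p) {
    ks <- delta_k(p$delta_k + 4, hours = p$hours)   # shift: delta unchanged
    fits <- fit_all_hours(p$d, ks)
    est_a <- lapply(fits, estimate_delta_k, d = p$d)
    est_o <- loo_cv(p$d, ks)
    list(dw = list(a = lapply(est_a, evaluate_estimates, ks = ks),
                   o = lapply(est_o, evaluate_estimates, ks = ks)))
  })
  tab <- aggregate_evaluation(evals)
  expect_equal(nrow(tab), 6)                 # 1 marker x 3 orders x 2 rules
  expect_true(all(c("rho_median", "r_iqr", "err_median_h0", "err_iqr_h5")
                  %in% names(tab)))
  # spot-check one cell against a direct computation
  rho_lin_a <- vapply(evals, function(e) e$dw$a$linear$spearman, numeric(1))
  expect_equal(tab$rho_median[tab$order == "linear" & tab$rule == "a"],
               median(rho_lin_a))
  errs <- unlist(lapply(evals, function(e) e$dw$a$linear$errors))
  expect_equal(tab$err_iqr[tab$order == "linear" & tab$rule == "a"],
               unname(diff(quantile(errs, c(0.25, 0.75)))))
})
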