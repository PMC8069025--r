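# Per-patient monotone polynomial sensing models.
#
# The relation between a warping marker d (ms) and the potassium variation
# delta_k = K(hi) - K(h4) (mmol/L) is modelled per patient by intercept-free
# linear, quadratic and cubic polynomials. Monotonicity of the estimate in d
# (the physiologically expected direction: larger warping deviation from the
# dialysis-end reference, larger potassium excess) is enforced by
# constraining all coefficients to be non-negative, which makes the
# derivative non-negative for d > 0. Constrained fits solve a non-negative
# least squares problem on the Vandermonde design (Lawson-Hanson active
# set, deterministic).

MODEL_ORDERS <- c(linear = 1L, quadratic = 2L, cubic = 3L)

#' Potassium variation relative to the dialysis-end reference
#'
#' @param k_mmol six potassium values at hours h0..h5, mmol/L.
#' @param hours hour labels (default h0..h5).
#' @param reference the reference hour (default `"h4"`, dialysis end).
#' @return A `potassium_series`: `hours`, `k_mmol`, `delta_k`
#'   (elementwise `k - k[reference]`; exactly 0 at the reference),
#'   `reference`.
#' @export
delta_k <- function(k_mmol, hours = paste0("h", 0:5), reference = "h4") {
  assert_that(length(k_mmol) == length(hours), "k/hours length mismatch")
  assert_that(all(is.finite(k_mmol)), "missing potassium values")
  ri <- match(reference, hours)
  assert_that(!is.na(ri), "reference hour '%s' missing", reference)
  structure(list(hours = hours, k_mmol = k_mmol,
                 delta_k = k_mmol - k_mmol[ri], reference = reference),
            class = "potassium_series")
}

vandermonde <- function(d, p) {
  X <- outer(d, seq_len(p), `^`)
  colnames(X) <- c("alpha", "beta", "gamma")[seq_len(p)]
  X
}

#' Fit one intercept-free polynomial sensing model
#'
#' Minimizes `sum((delta_k - X c)^2)` where `X` has columns `d, d^2, ...`
#' up to the model order and there is no intercept (the marker and the
#' potassium variation both vanish at the reference by construction). When
#' `constrained` (the default), all coefficients are restricted to be
#' non-negative, guaranteeing a monotone non-decreasing estimate for
#' d > 0.
#'
#' @param d marker values at the training hours, ms.
#' @param dk potassium variations at the same hours, mmol/L.
#' @param order `"linear"`, `"quadratic"` or `"cubic"`.
#' @param constrained enforce non-negative coefficients.
#' @return A `kmodel`: `coef` (named, length = polynomial order),
#'   `order`, `constrained`, `sse` (training sum of squared errors).
#' @export
fit_kmodel <- function(d, dk, order = c("linear", "quadratic", "cubic"),
                       constrained = TRUE) {
  order <- match.arg(order)
  p <- MODEL_ORDERS[[order]]
  assert_that(length(d) == length(dk), "d/dk length mismatch")
  assert_that(all(is.finite(d)) && all(is.finite(dk)), "non-finite training data")
  assert_that(length(d) >= p + 1, "need at least %d training points", p + 1)
  assert_that(any(d != 0), "degenerate design: all marker values are zero")
  X <- vandermonde(d, p)
  if (constrained) {
    fit <- pracma::lsqnonneg(X, dk)
    cf <- fit$x
  } else {
    cf <- qr.coef(qr(X), dk)
    cf[is.na(cf)] <- 0
  }
  names(cf) <- colnames(X)
  resid <- dk - as.vector(X %*% cf)
  structure(list(coef = cf, order = order, constrained = constrained,
                 sse = sum(resid^2)),
            class = "kmodel")
}

#' @export
print.kmodel <- function(x, ...) {
  cat(sprintf("<kmodel> %s%s: %s (SSE %.4g)\n", x$order,
              if (x$constrained) " (constrained)" else "",
              paste(sprintf("%s=%.4g", names(x$coef), x$coef), collapse = ", "),
              x$sse))
  invisible(x)
}

#' Estimate potassium variation from marker values
#'
#' Evaluates the fitted intercept-free polynomial; `d = 0` (the reference)
#' always maps to 0.
#'
#' @param model a [fit_kmodel()] result.
#' @param d marker values, ms.
#' @return Estimated potassium variations, mmol/L.
#' @export
estimate_delta_k <- function(model, d) {
  p <- length(model$coef)
  as.vector(vandermonde(d, p) %*% model$coef)
}

#' Fit all-samples models for one patient
#'
#' The "all" estimation rule: each model order is trained on every hour
#' with both a marker and a potassium value (hours missing a marker are
#' dropped with a warning; at least 4 points are required).
#'
#' @param d marker values at the six hours, ms (may contain `NA`).
#' @param ks a [delta_k()] series.
#' @param orders model orders to fit.
#' @param constrained enforce non-negative coefficients.
#' @return Named list of `kmodel`s, one per order, with the training hours
#'   attached.
#' @export
fit_all_hours <- function(d, ks, orders = names(MODEL_ORDERS),
                          constrained = TRUE) {
  ok <- is.finite(d)
  if (!all(ok)) warning(sprintf("dropping hours without markers: %s",
                                paste(ks$hours[!ok], collapse = ",")))
  assert_that(sum(ok) >= 4, "fewer than 4 usable hour points")
  lapply(stats::setNames(orders, orders), function(o) {
    m <- fit_kmodel(d[ok], ks$delta_k[ok], o, constrained)
    m$training_hours <- ks$hours[ok]
    m
  })
}

#' Leave-one-out estimates for one patient
#'
#' The "leave-one-out" estimation rule: for each non-reference hour the
#' model is refitted with that hour excluded (the reference h4 stays in
#' every training set -- it anchors the model and is excluded only from
#' error evaluation) and the held-out hour is predicted from the refit.
#'
#' @inheritParams fit_all_hours
#' @return A list per order of numeric vectors of length 6: the held-out
#'   prediction at each non-reference hour, 0 at the reference, `NA` where
#'   the marker is missing.
#' @export
loo_cv <- function(d, ks, orders = names(MODEL_ORDERS), constrained = TRUE) {
  ri <- match(ks$reference, ks$hours)
  ok <- is.finite(d)
  assert_that(ok[ri], "reference hour lacks a marker")
  lapply(stats::setNames(orders, orders), function(o) {
    est <- rep(NA_real_, length(d))
    est[ri] <- 0
    for (i in seq_along(d)) {
      if (i == ri || !ok[i]) next
      tr <- ok & seq_along(d) != i
      m <- fit_kmodel(d[tr], ks$delta_k[tr], o, constrained)
      est[i] <- estimate_delta_k(m, d[i])
    }
    est
  })
}

#' Evaluate estimates against measured potassium variations
#'
#' Per patient and model: Spearman and Pearson correlations between the
#' measured and estimated series (over all six hours by default, the
#' reference included), and the estimation errors
#' `e(hi) = delta_k_hat(hi) - delta_k(hi)` at the five non-reference hours
#' (the reference is excluded: both quantities are identically zero there
#' and would bias the error distribution).
#'
#' @param est estimated potassium variations at the six hours.
#' @param ks the measured [delta_k()] series.
#' @param include_reference_in_corr include the reference point in the
#'   correlation (default `TRUE`).
#' @return A list: `spearman`, `pearson`, `errors` (named by the
#'   non-reference hours).
#' @export
evaluate_estimates <- function(est, ks, include_reference_in_corr = TRUE) {
  ri <- match(ks$reference, ks$hours)
  use <- is.finite(est) & is.finite(ks$delta_k)
  cu <- use
  if (!include_reference_in_corr) cu[ri] <- FALSE
  rho <- r <- NA_real_
  if (sum(cu) >= 3) {
    rho <- suppressWarnings(cor(ks$delta_k[cu], est[cu], method = "spearman"))
    r <- suppressWarnings(cor(ks$delta_k[cu], est[cu], method = "pearson"))
  }
  err_idx <- setdiff(which(use), ri)
  errors <- est[err_idx] - ks$delta_k[err_idx]
  names(errors) <- ks$hours[err_idx]
  list(spearman = rho, pearson = r, errors = errors)
}

# IQR as the 75th - 25th percentile with linear interpolation
iqr_lin <- function(x) diff(quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7,
                                     names = FALSE))

#' Aggregate per-patient evaluations across a cohort
#'
#' Builds the evaluation table: for each marker, model order and
#' estimation rule, the median and interquartile range of the per-patient
#' correlations, and of the estimation errors pooled over all patients and
#' non-reference hours (ALL) and segregated at the first and last hours.
#'
#' @param evals nested list: `evals[[patient]][[marker]][[rule]][[order]]`
#'   as produced by [run_pipeline()] / [evaluate_estimates()].
#' @param hours_segregated hours reported separately (default h0, h5).
#' @return A data frame with one row per (marker, order, rule) and columns
#'   `rho_median`, `rho_iqr`, `r_median`, `r_iqr`, `err_median`, `err_iqr`,
#'   plus `err_median_<h>`/`err_iqr_<h>` for each segregated hour.
#' @export
aggregate_evaluation <- function(evals, hours_segregated = c("h0", "h5")) {
  markers <- names(evals[[1]])
  rules <- names(evals[[1]][[1]])
  orders <- names(evals[[1]][[1]][[1]])
  rows <- list()
  for (d in markers) for (f in orders) for (m in rules) {
    per <- lapply(evals, function(e) e[[d]][[m]][[f]])
    rho <- vapply(per, `[[`, numeric(1), "spearman")
    r <- vapply(per, `[[`, numeric(1), "pearson")
    errs <- unlist(lapply(per, `[[`, "errors"))
    row <- data.frame(marker = d, order = f, rule = m,
                      rho_median = median(rho, na.rm = TRUE),
                      rho_iqr = iqr_lin(rho),
                      r_median = median(r, na.rm = TRUE),
                      r_iqr = iqr_lin(r),
                      err_median = median(abs(errs), na.rm = TRUE),
                      err_iqr = iqr_lin(errs))
    for (h in hours_segregated) {
      eh <- unlist(lapply(per, function(x) x$errors[names(x$errors) == h]))
      row[[paste0("err_median_", h)]] <- median(abs(eh), na.rm = TRUE)
      row[[paste0("err_iqr_", h)]] <- iqr_lin(eh)
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
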