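# End-to-end pipeline: preprocess -> periodic components -> delineate piC1
# -> windows -> mean warped T waves -> markers -> heart-rate correction ->
# per-patient model fits (all-samples and leave-one-out) -> evaluation.

#' Pipeline configuration
#'
#' All tunables of every stage, with defaults matching the reference
#' processing chain: 0.5 Hz / 6th-order zero-phase high-pass, 40 Hz /
#' 3rd-order low-pass, T-wave periodicity mode for the lead transformation,
#' 2-min windows at the 5th and 35th minute of each hour, 0.5 ms warping
#' grid, Bazett-like heart-rate correction fitted on the trailing 4 h, and
#' fully constrained linear/quadratic/cubic models under both estimation
#' rules.
#'
#' @param ... overrides for any default, as nested lists (e.g.
#'   `window = list(min_beats = 5)` replaces only that entry).
#' @return A `pipeline_config` (nested named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    filter = list(hp_hz = 0.5, hp_order = 6, lp_hz = 40, lp_order = 3,
                  twave_lp_hz = 20, twave_lp_order = 6),
    delineate = list(t_search_ms = c(90, 600), min_t_rel = 0.05),
    pica = list(mode = "piCT", n_resample = NULL, min_beats = 100),
    window = list(grid_min = c(5, 35), half_width_s = 60, min_beats = 20,
                  corr_min = 0.95, dur_dev = 0.25, edge_s = 10,
                  max_waves = Inf),
    warp = list(grid_ms = 0.5, tol = 1e-3, max_iter = 10, band = 0.25,
                sign_convention = "narrowing"),
    hr_correction = list(enabled = TRUE, stability_h = 4),
    models = list(orders = c("linear", "quadratic", "cubic"),
                  rules = c("a", "o"), constrained = TRUE,
                  include_reference_in_corr = TRUE),
    seed = 1L)
  ov <- list(...)
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(upd[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, ov)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(pipeline_config())
  bad <- setdiff(names(y), known)
  assert_that(length(bad) == 0, "unknown config keys: %s",
              paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Process one patient: ECG and lab values to markers, models and errors
#'
#' @param rec the raw [ecg_recording()] (8 independent leads, microvolts).
#' @param k_mmol the six potassium values at `sample_hours`, mmol/L.
#' @param protocol the [session_protocol()].
#' @param config a [pipeline_config()].
#' @return A list: `markers` (full [marker_series()]), `at_hours` (markers
#'   paired to the blood hours), `ks` ([delta_k()] series), `models`
#'   (per marker, all-samples fits), `estimates`
#'   (`[[marker]][[rule]][[order]]`, length-6 vectors), `eval`
#'   (matching [evaluate_estimates()] results), `transform`.
#' @export
run_patient <- function(rec, k_mmol, protocol, config = pipeline_config()) {
  fc <- config$filter
  rec8 <- if (all(c("I", "II", "V1") %in% rec$leads)) independent_leads(rec) else rec
  rec8 <- remove_baseline(rec8, fc$hp_hz, fc$hp_order)
  rec8 <- remove_highfreq(rec8, fc$lp_hz, fc$lp_order)
  ann <- detect_and_delineate(rec8, "II",
                              t_search_ms = config$delineate$t_search_ms,
                              min_t_rel = config$delineate$min_t_rel)
  tr <- fit_pica(rec8, ann, mode = config$pica$mode,
                 n_resample = config$pica$n_resample,
                 min_beats = config$pica$min_beats)
  pc <- apply_pica(rec8, tr)
  ann_pc <- detect_and_delineate(pc, "piC1",
                                 t_search_ms = config$delineate$t_search_ms,
                                 min_t_rel = config$delineate$min_t_rel)
  wins <- do.call(extract_twave_windows,
                  c(list(pc = pc, ann = ann_pc, protocol = protocol),
                    config$window))
  mwtws <- lapply(wins, function(w)
    if (w$valid) compute_mwtw(w, grid_ms = config$warp$grid_ms,
                              tol = config$warp$tol,
                              max_iter = config$warp$max_iter,
                              band = config$warp$band) else NULL)
  series <- marker_series(mwtws,
                          vapply(wins, `[[`, numeric(1), "center_time_h"),
                          vapply(wins, `[[`, numeric(1), "rr_median_ms"),
                          reference_h = protocol$hd_end_h,
                          grid_ms = config$warp$grid_ms,
                          band = config$warp$band,
                          sign_convention = config$warp$sign_convention)
  if (config$hr_correction$enabled)
    series <- hr_correct(series, config$hr_correction$stability_h)
  at_hours <- markers_at_hours(series, protocol$sample_hours,
                               protocol$hour_labels)
  ks <- delta_k(k_mmol, protocol$hour_labels, "h4")

  mc <- config$models
  markers <- list(dw = at_hours$dw_ms, dwc = at_hours$dwc_ms)
  models <- estimates <- evals <- list()
  for (d in names(markers)) {
    dv <- markers[[d]]
    fits <- fit_all_hours(dv, ks, mc$orders, mc$constrained)
    est_a <- lapply(fits, estimate_delta_k, d = dv)
    est_o <- loo_cv(dv, ks, mc$orders, mc$constrained)
    models[[d]] <- fits
    estimates[[d]] <- list(a = est_a, o = est_o)
    evals[[d]] <- lapply(estimates[[d]], function(by_rule)
      lapply(by_rule, evaluate_estimates, ks = ks,
             include_reference_in_corr = mc$include_reference_in_corr))
  }
  list(markers = series, at_hours = at_hours, ks = ks, models = models,
       estimates = estimates, eval = evals, transform = tr)
}

#' Run the full pipeline over a cohort
#'
#' Each patient is processed independently; a failing patient is logged
#' and skipped, the others continue.
#'
#' @param patients a named list; each element is either
#'   `list(rec = , k_mmol = )` or `list(ecg_path = , format = )` plus
#'   `k_mmol`.
#' @param protocol the [session_protocol()] shared by the cohort.
#' @param config a [pipeline_config()].
#' @return A `run_report`: `patients` (per-patient [run_patient()]
#'   results), `failed` (named error messages), `table` (the
#'   [aggregate_evaluation()] data frame), `config`.
#' @export
run_pipeline <- function(patients, protocol, config = pipeline_config()) {
  assert_that(length(patients) > 0, "empty cohort")
  if (is.null(names(patients)))
    names(patients) <- sprintf("P%03d", seq_along(patients))
  results <- list()
  failed <- character(0)
  for (id in names(patients)) {
    p <- patients[[id]]
    res <- tryCatch({
      rec <- if (!is.null(p$rec)) p$rec else read_ecg(p$ecg_path)
      run_patient(rec, p$k_mmol, protocol, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("patient %s failed: %s", id, conditionMessage(res)))
      failed[id] <- conditionMessage(res)
    } else results[[id]] <- res
  }
  assert_that(length(results) > 0, "all patients failed")
  tab <- aggregate_evaluation(lapply(results, `[[`, "eval"))
  structure(list(patients = results, failed = failed, table = tab,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d patients (%d failed)\n",
              length(x$patients), length(x$failed)))
  print(x$table, digits = 3)
  invisible(x)
}

#' Write a run report to a directory
#'
#' Emits `aggregate.csv` (the evaluation table), one
#' `markers_<patient>.csv` per patient, `models.json` (all fitted
#' coefficients) and `config.json` (the fully resolved configuration, for
#' provenance).
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.10g", v))
  write.csv(tab, file.path(dir, "aggregate.csv"), row.names = FALSE,
            quote = FALSE)
  for (id in names(report$patients)) {
    s <- report$patients[[id]]$markers
    out <- data.frame(time_h = sprintf("%.6f", s$time_h),
                      dw_ms = sprintf("%.6f", s$dw_ms),
                      dwc_ms = sprintf("%.6f", s$dwc_ms),
                      rr_ms = sprintf("%.6f", s$rr_ms),
                      valid = s$valid)
    write.csv(out, file.path(dir, paste0("markers_", id, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  models <- lapply(report$patients, function(p)
    lapply(p$models, function(by_order)
      lapply(by_order, function(m)
        list(order = m$order, constrained = m$constrained,
             coef = as.list(m$coef), training_hours = m$training_hours))))
  jsonlite::write_json(models, file.path(dir, "models.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(unclass(report$config), file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}
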