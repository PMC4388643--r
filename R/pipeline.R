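# End-to-end pipelines tying the stages together, and dual-format report
# output (human-readable text + machine-readable key/value). Each report
# embeds the configuration and seed that produced it, so every result is
# reproducible from its own report.

#' Run the full calorimetric kinetics pipeline
#'
#' Executes baseline fit -> correction -> Tian deconvolution -> apparent
#' enthalpy (from the single-injection experiment) -> rates -> residual
#' substrate -> rate curve -> Michaelis-Menten fit -> catalytic constants.
#' Either supply measured thermograms + schedules, or set `simulate = TRUE`
#' to generate both experiments from `sim` ground truth.
#'
#' @param single list with `thermogram` and `schedule` for the
#'   single-injection (enthalpy) experiment; ignored when `simulate = TRUE`.
#' @param multi list with `thermogram` and `schedule` for the
#'   multiple-injection (rate) experiment; ignored when `simulate = TRUE`.
#' @param cell a [cell_config()].
#' @param tau instrument response time constant in s (deconvolution and
#'   settling windows); default 6.
#' @param settle post-injection exclusion window in s; default
#'   `max(5 * tau, 20)`.
#' @param tian_window points of the deconvolution smoothing filter
#'   (default 7); the rate curve excludes half this span before each
#'   injection, where the smoothed derivative is unreliable.
#' @param baseline `"constant"` or `"linear"`.
#' @param simulate if TRUE, generate both experiments with the packaged
#'   default lignosulfonic-acid ground truth.
#' @param sim_args list of overrides passed to [make_default_lsa_params()]
#'   when simulating (e.g. `noise_sd`, `seed`).
#' @param MW optional enzyme molecular weight (g/mol) for specific activity.
#' @return an object of class `itc_report`: list with `delta_h`,
#'   `rate_curve`, `fit` (with catalytic constants), `lineweaver_burk`,
#'   `baseline_single`, `baseline_multi`, `config`, and `ground_truth`
#'   (when simulated).
#' @export
run_itc_pipeline <- function(single = NULL, multi = NULL,
                             cell = cell_config(volume = 200, E0 = 1.39),
                             tau = 6, settle = NULL, tian_window = 7,
                             baseline = "constant",
                             simulate = FALSE, sim_args = list(), MW = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  gt <- NULL
  if (simulate) {
    ps <- stage("simulate", do.call(make_default_lsa_params,
                                    c(list(protocol = "single_lsa"), sim_args)))
    pm <- stage("simulate", do.call(make_default_lsa_params,
                                    c(list(protocol = "multi_lsa"), sim_args)))
    ps$instrument_tau <- pm$instrument_tau <- tau
    sims <- stage("simulate", simulate_itc(ps))
    simm <- stage("simulate", simulate_itc(pm))
    single <- list(thermogram = sims$thermogram, schedule = ps$schedule)
    multi <- list(thermogram = simm$thermogram, schedule = pm$schedule)
    cell <- pm$cell
    gt <- list(kcat = pm$kcat, Km = pm$Km, Vmax = pm$kcat * pm$E0,
               delta_h = pm$delta_h, E0 = pm$E0, seed = pm$seed,
               noise_sd = pm$noise_sd)
  }
  if (is.null(single) || is.null(multi))
    stop("[input] supply 'single' and 'multi' experiments, or simulate = TRUE",
         call. = FALSE)
  for (nm in c("single", "multi")) {
    x <- get(nm)
    if (is.null(x$thermogram) || is.null(x$schedule))
      stop(sprintf("[input] '%s' must carry a thermogram and a schedule", nm),
           call. = FALSE)
  }
  bl_s <- stage("baseline", fit_baseline(single$thermogram, single$schedule,
                                         kind = baseline))
  tg_s <- stage("baseline", baseline_correct(single$thermogram, bl_s))
  dh <- stage("deltaH", estimate_delta_h_app(tg_s, single$schedule, cell))

  bl_m <- stage("baseline", fit_baseline(multi$thermogram, multi$schedule,
                                         kind = baseline))
  tg_m <- stage("baseline", baseline_correct(multi$thermogram, bl_m))
  tg_m <- stage("deconvolve", deconvolve_tian(tg_m, tau = tau,
                                              window = tian_window))
  rates <- stage("rates", power_to_rate(tg_m, dh, cell))
  straj <- stage("substrate", substrate_trajectory(tg_m, dh, multi$schedule, cell))
  guard <- if (tau > 0) (tian_window %/% 2L) * multi$thermogram$sample_interval else 0
  rc <- stage("rate_curve", build_rate_curve(rates, straj, multi$schedule,
                                             settle = settle, tau = tau,
                                             guard = guard, cell = cell))
  fit <- stage("fit", fit_michaelis_menten(rc))
  fit <- stage("fit", derive_catalytic_constants(fit, E0 = cell$E0, MW = MW))
  kept <- rc[rc$retained, ]
  lb <- stage("fit", suppressWarnings(
    lineweaver_burk(kept$S_uM, kept$rate_E0_uM_per_s)))
  structure(list(delta_h = dh, rate_curve = rc, fit = fit,
                 lineweaver_burk = lb, baseline_single = bl_s,
                 baseline_multi = bl_m,
                 config = list(cell = cell, tau = tau,
                               settle = settle %||% max(5 * tau, 20),
                               tian_window = tian_window, guard = guard,
                               baseline = baseline, MW = MW,
                               simulate = simulate, sim_args = sim_args),
                 ground_truth = gt),
            class = "itc_report")
}

#' @export
print.itc_report <- function(x, ...) {
  cat("== Calorimetric enzyme kinetics report ==\n")
  print(x$delta_h)
  print(x$rate_curve)
  print(x$fit)
  if (!is.null(x$ground_truth))
    cat(sprintf("Ground truth (simulated): Vmax %.4g uM/s, Km %.4g uM, dH %.5g cal/mol\n",
                x$ground_truth$Vmax, x$ground_truth$Km, x$ground_truth$delta_h))
  invisible(x)
}

#' Run the spectrophotometric initial-rate pipeline
#'
#' Extracts initial rates from a set of absorbance traces, fits the
#' Michaelis-Menten model, and derives catalytic constants: the complete
#' chromogenic-assay workflow behind a kinetic-parameter table row.
#'
#' @param traces list of [absorbance_trace()] objects.
#' @param E0 enzyme concentration in uM (> 0).
#' @param MW optional molecular weight in g/mol.
#' @param assay an [assay_config()] (metadata for the report; the traces
#'   carry their own).
#' @param ... passed to [initial_rate()].
#' @return an object of class `spectro_report`: list with `points`, `fit`,
#'   `lineweaver_burk`, `config`. The report metadata records the activity
#'   unit definition: one unit is the amount of enzyme that oxidizes 1 umol
#'   of substrate per minute.
#' @export
run_spectro_pipeline <- function(traces, E0, MW = NULL, assay = NULL, ...) {
  if (!length(traces)) stop("[input] no absorbance traces supplied", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  pts <- stage("initial_rate", assemble_mm_dataset(traces, ...))
  fit <- stage("fit", fit_michaelis_menten(pts$S_uM, pts$rate_uM_per_s))
  fit <- stage("fit", derive_catalytic_constants(fit, E0 = E0, MW = MW))
  pos <- pts$S_uM > 0 & pts$rate_uM_per_s > 0
  lb <- if (sum(pos) >= 2L)
    stage("fit", suppressWarnings(
      lineweaver_burk(pts$S_uM[pos], pts$rate_uM_per_s[pos])))
  else NULL
  if (is.null(assay)) assay <- traces[[1L]]$assay
  structure(list(points = pts, fit = fit, lineweaver_burk = lb,
                 config = list(E0 = E0, MW = MW, assay = assay),
                 unit_definition = paste("One unit of enzyme activity is the",
                                         "amount of enzyme that oxidizes 1 umol",
                                         "of substrate per minute")),
            class = "spectro_report")
}

#' @export
print.spectro_report <- function(x, ...) {
  cat("== Spectrophotometric initial-rate kinetics report ==\n")
  cat(sprintf("%d (S, rate) points, S %.4g-%.4g uM\n", nrow(x$points),
              min(x$points$S_uM), max(x$points$S_uM)))
  print(x$fit)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Writes a human-readable `report.txt`, a machine-readable key/value
#' `report.kv` (full precision, plus reporting-convention rounded
#' efficiency), and plot-ready delimited tables (rate curve or rate points).
#' No timestamps are written, so identical configurations yield
#' byte-identical bundles.
#'
#' @param report an `itc_report` or `spectro_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- report$fit
  kv <- c(
    sprintf("Vmax_uM_per_s=%.17g", fit$Vmax),
    sprintf("Km_uM=%.17g", fit$Km),
    sprintf("Vmax_se=%.17g", fit$se[["Vmax"]]),
    sprintf("Km_se=%.17g", fit$se[["Km"]]),
    sprintf("kcat_per_s=%.17g", fit$kcat),
    sprintf("efficiency_per_s_per_uM=%.17g", fit$efficiency),
    sprintf("efficiency_reported=%.17g", round_efficiency(fit$efficiency)),
    sprintf("specific_activity_U_per_mg=%.17g", fit$specific_activity),
    sprintf("rss=%.17g", fit$rss),
    sprintf("converged=%s", fit$converged),
    sprintf("reliable=%s", fit$reliable),
    sprintf("n_points=%d", fit$n))
  if (inherits(report, "itc_report")) {
    kv <- c(kv,
            sprintf("delta_h_app_cal_per_mol=%.17g", report$delta_h$delta_h_app),
            sprintf("tau_s=%g", report$config$tau),
            sprintf("settle_s=%g", report$config$settle),
            sprintf("baseline_kind=%s", report$config$baseline))
    if (!is.null(report$ground_truth))
      kv <- c(kv, sprintf("seed=%d", report$ground_truth$seed),
              sprintf("gt_Km_uM=%.17g", report$ground_truth$Km),
              sprintf("gt_Vmax_uM_per_s=%.17g", report$ground_truth$Vmax),
              sprintf("gt_delta_h_cal_per_mol=%.17g", report$ground_truth$delta_h))
    write_rate_curve(report$rate_curve, file.path(dir, "rate_curve.csv"))
  } else {
    utils::write.csv(report$points, file.path(dir, "rate_points.csv"),
                     row.names = FALSE, quote = FALSE)
    kv <- c(kv, sprintf("unit_definition=%s", report$unit_definition))
  }
  writeLines(kv, file.path(dir, "report.kv"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
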