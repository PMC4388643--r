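# Signal conditioning for thermograms: baseline estimation and subtraction,
# instrument-response (Tian) deconvolution, and peak/heat integration.

#' Fit a baseline model to a thermogram
#'
#' Fits a constant or linear baseline to segments of the thermogram that
#' carry no reaction heat: the pre-first-injection equilibration segment and,
#' for the linear model, a terminal return-to-baseline segment. The residual
#' noise SD is estimated robustly (scaled median absolute deviation), so
#' occasional excursions do not inflate it.
#'
#' @param tg a [thermogram()].
#' @param schedule an [injection_schedule()]; used to locate the
#'   pre-injection segment. May be NULL when `windows` is given.
#' @param kind `"constant"` or `"linear"`.
#' @param windows optional explicit list of `c(start, end)` windows in s to
#'   fit on, overriding the automatic policy.
#' @param terminal_window length in s of the terminal segment used for the
#'   linear model (default 60).
#' @return an object of class `baseline_model`: list with `kind`,
#'   `coefficients` (intercept ucal/s, and slope ucal/s per s for linear),
#'   `windows`, `noise_sd`.
#' @export
fit_baseline <- function(tg, schedule = NULL, kind = c("constant", "linear"),
                         windows = NULL, terminal_window = 60) {
  stopifnot(inherits(tg, "thermogram"))
  kind <- match.arg(kind)
  if (is.null(windows)) {
    if (is.null(schedule))
      stop("supply either 'schedule' or explicit fit 'windows'", call. = FALSE)
    t1 <- min(schedule$time_s)
    if (t1 - min(tg$time) < 30)
      stop(paste0("fewer than 30 s of pre-injection data; ",
                  "pass explicit fit windows instead"), call. = FALSE)
    # stop one sample short of the injection so the (lagged) onset never
    # leaks into the baseline estimate
    windows <- list(c(min(tg$time), t1 - tg$sample_interval))
    if (kind == "linear")
      windows <- c(windows, list(c(max(tg$time) - terminal_window, max(tg$time))))
  }
  idx <- sort(unique(unlist(lapply(windows, function(w) {
    if (w[1L] < min(tg$time) - 1e-9 || w[2L] > max(tg$time) + 1e-9)
      stop("baseline fit window outside the thermogram time span", call. = FALSE)
    which(tg$time >= w[1L] & tg$time <= w[2L])
  }))))
  if (length(idx) < 2L) stop("baseline fit windows contain < 2 samples", call. = FALSE)
  tt <- tg$time[idx]; pp <- tg$power[idx]
  if (kind == "constant") {
    coef <- c(intercept = mean(pp))
    resid <- pp - coef[[1L]]
  } else {
    fit <- stats::lm.fit(cbind(1, tt), pp)
    coef <- c(intercept = fit$coefficients[[1L]], slope = fit$coefficients[[2L]])
    resid <- fit$residuals
  }
  noise_sd <- stats::mad(resid, center = 0)
  structure(list(kind = kind, coefficients = coef, windows = windows,
                 noise_sd = noise_sd),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline (%s): %s; noise SD %.4g ucal/s\n", x$kind,
              paste(sprintf("%s=%.6g", names(x$coefficients), x$coefficients),
                    collapse = ", "), x$noise_sd))
  invisible(x)
}

#' @keywords internal
predict_baseline <- function(baseline, time) {
  b <- baseline$coefficients
  if (baseline$kind == "constant") rep(b[["intercept"]], length(time))
  else b[["intercept"]] + b[["slope"]] * time
}

#' Subtract a baseline from a thermogram
#'
#' @param tg a [thermogram()].
#' @param baseline a [fit_baseline()] model fitted on the same time span.
#' @return the corrected [thermogram()], with the step appended to its
#'   processing log and the baseline noise SD attached as attribute
#'   `noise_sd`.
#' @export
baseline_correct <- function(tg, baseline) {
  stopifnot(inherits(tg, "thermogram"), inherits(baseline, "baseline_model"))
  out <- tg
  out$power <- tg$power - predict_baseline(baseline, tg$time)
  out <- log_step(out, sprintf("baseline corrected (%s)", baseline$kind))
  attr(out, "noise_sd") <- baseline$noise_sd
  out
}

#' Tian instrument-response deconvolution
#'
#' Removes the first-order response lag of a compensation calorimeter with
#' the Tian equation, `P_true(t) = P_meas(t) + tau * dP_meas/dt`. The
#' derivative is estimated by local-quadratic (Savitzky-Golay) smoothing
#' over `window` points, which tames sampling noise without flattening
#' minute-scale features. `tau = 0` is an exact passthrough.
#'
#' @param tg a uniformly sampled [thermogram()].
#' @param tau instrument time constant in s (>= 0).
#' @param window odd number of points of the local-quadratic filter
#'   (default 7).
#' @return the deconvolved [thermogram()].
#' @export
deconvolve_tian <- function(tg, tau, window = 7) {
  stopifnot(inherits(tg, "thermogram"))
  check_scalar(tau, "tau", nonneg = TRUE)
  if (tau == 0) return(tg)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("'window' must be odd", call. = FALSE)
  if (window > length(tg$time))
    stop(sprintf("smoothing window (%d points) exceeds series length (%d)",
                 window, length(tg$time)), call. = FALSE)
  dt <- tg$sample_interval
  dP <- signal::sgolayfilt(tg$power, p = 2, n = window, m = 1, ts = dt)
  out <- tg
  out$power <- tg$power + tau * dP
  noise <- attr(tg, "noise_sd")
  out <- log_step(out, sprintf("Tian deconvolution (tau=%g s, window=%d)", tau, window))
  attr(out, "noise_sd") <- noise
  out
}

#' Integrate heat over a thermogram window
#'
#' Trapezoidal integral of the (baseline-corrected) differential power over
#' a time window, returned in cal. With `window = "auto"` the window starts
#' at `from` and closes at the first run of `persist` consecutive samples
#' whose power stays within `threshold_mult * noise_sd` of zero (or at the
#' end of `until`, if supplied, e.g. the next injection).
#'
#' @param tg a corrected [thermogram()].
#' @param window `c(start, end)` in s, or `"auto"`.
#' @param noise_sd baseline noise SD in ucal/s (for the auto window);
#'   defaults to the value attached by [baseline_correct()], else 0.
#' @param from start of the auto window in s (required for `"auto"`).
#' @param until hard upper bound for the auto window in s (optional).
#' @param threshold_mult,persist return-to-baseline detection: the window
#'   closes after `persist` consecutive samples within
#'   `threshold_mult * noise_sd` (defaults 3 and 5).
#' @return the integrated heat in cal (negative = exothermic), with the
#'   window used attached as attribute `window`.
#' @export
integrate_heat <- function(tg, window = NULL, noise_sd = NULL, from = NULL,
                           until = NULL, threshold_mult = 3, persist = 5L) {
  stopifnot(inherits(tg, "thermogram"))
  if (is.null(noise_sd)) noise_sd <- attr(tg, "noise_sd") %||% 0
  if (is.null(window)) window <- c(min(tg$time), max(tg$time))
  if (identical(window, "auto")) {
    if (is.null(from)) stop("auto window requires 'from' (injection time)", call. = FALSE)
    hi <- if (is.null(until)) max(tg$time) else until
    idx <- which(tg$time >= from & tg$time <= hi)
    thr <- max(threshold_mult * noise_sd, 1e-9)
    quiet <- abs(tg$power[idx]) <= thr
    run <- 0L; close_at <- NA_integer_
    for (i in seq_along(quiet)) {
      run <- if (quiet[i]) run + 1L else 0L
      if (run >= persist) { close_at <- i; break }
    }
    if (is.na(close_at)) {
      if (is.null(until))
        stop(paste0("auto integration window never closed (power does not ",
                    "return to baseline); supply an explicit window"), call. = FALSE)
      close_at <- length(idx)
    }
    window <- c(from, tg$time[idx[close_at]])
  }
  sel <- which(tg$time >= window[1L] - 1e-9 & tg$time <= window[2L] + 1e-9)
  if (length(sel) < 2L) stop("integration window contains < 2 samples", call. = FALSE)
  heat <- power_trapz_cal(tg$time[sel], tg$power[sel])
  attr(heat, "window") <- window
  heat
}
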