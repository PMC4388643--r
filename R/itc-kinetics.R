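# The calorimetric kinetics inference: the apparent molar enthalpy from a
# single-injection (complete-conversion) experiment, pointwise reaction
# rates from differential power, and the residual substrate concentration
# from cumulative heat, assembled into a rate curve for Michaelis-Menten
# fitting.
#
# Sign convention (enforced, never silently absoluted): exothermic reactions
# give negative power AND negative delta_h_app, so rates come out positive.

#' Estimate the apparent molar enthalpy from a single-injection experiment
#'
#' The apparent enthalpy is the heat released or consumed per mole of
#' substrate completely converted to product,
#' `delta_H_app = integral(dQ/dt) / ([S]_total * V)`. Each injection's heat
#' is integrated from its injection time up to the next injection (or the
#' end of the trace), after validating that the power has returned to
#' baseline before the window closes, i.e. that the bolus was fully
#' converted. Per-injection enthalpies are reported alongside the pooled
#' estimate (total heat over total converted moles).
#'
#' @param tg a baseline-corrected [thermogram()].
#' @param schedule the [injection_schedule()] of the experiment.
#' @param cell a [cell_config()].
#' @param noise_sd baseline noise SD in ucal/s; defaults to the value
#'   attached by [baseline_correct()], else 0. Return-to-baseline is judged
#'   against `max(3 * noise_sd, 1% of the peak |power|)`.
#' @param bolus_displacement accounting convention for the moles of an
#'   injected bolus retained in the overflow cell: `"none"` (all of
#'   `c_syr * v` stays; consistent with [apply_injection()], the default),
#'   `"half"` (`c_syr * v * (1 - v/2V)`: on average half the bolus is
#'   exposed to displacement), or `"full"` (`c_syr * v * (1 - v/V)`). For
#'   iTC-200 bolus sizes the three differ by at most 2.5%.
#' @return an object of class `enthalpy_estimate`: list with `delta_h_app`
#'   (cal/mol), `total_heat` (cal), `converted_moles` (mol),
#'   `per_injection` (data.frame), `integration_windows`,
#'   `bolus_displacement`.
#' @export
estimate_delta_h_app <- function(tg, schedule, cell, noise_sd = NULL,
                                 bolus_displacement = c("none", "half", "full")) {
  stopifnot(inherits(tg, "thermogram"), inherits(schedule, "injection_schedule"))
  bolus_displacement <- match.arg(bolus_displacement)
  if (is.null(noise_sd)) noise_sd <- attr(tg, "noise_sd") %||% 0
  V <- cell$volume
  n <- nrow(schedule)
  ends <- c(schedule$time_s[-1L], max(tg$time))
  peak <- max(abs(tg$power))
  return_tol <- max(3 * noise_sd, 0.01 * peak)
  heats <- moles <- numeric(n)
  windows <- vector("list", n)
  for (k in seq_len(n)) {
    w <- c(schedule$time_s[k], ends[k])
    # judge return-to-baseline on the last samples of the window, excluding
    # the next-injection instant itself (whose sample already carries the
    # lagged onset of the following bolus)
    hi <- if (k < n) w[2L] - tg$sample_interval / 2 else w[2L] + 1e-9
    tail_idx <- which(tg$time <= hi)
    tail_idx <- tail_idx[tg$time[tail_idx] > w[2L] - 3.5 * tg$sample_interval]
    if (any(abs(tg$power[tail_idx]) > return_tol))
      stop(sprintf(paste0("incomplete conversion: power has not returned to ",
                          "baseline before the end of injection %d's window ",
                          "(%g-%g s); the single-injection enthalpy method ",
                          "requires each bolus to be fully converted"),
                   k, w[1L], w[2L]), call. = FALSE)
    heats[k] <- integrate_heat(tg, window = w, noise_sd = noise_sd)
    v <- schedule$volume_uL[k]
    frac <- switch(bolus_displacement, none = 1, half = 1 - v / (2 * V),
                   full = 1 - v / V)
    moles[k] <- moles_from_conc(schedule$syringe_conc_uM[k] * frac, v)
    windows[[k]] <- w
  }
  if (sum(moles) <= 0) stop("converted moles are zero; check the schedule", call. = FALSE)
  total_heat <- sum(heats)
  per_dh <- heats / moles
  se <- if (n >= 2L) stats::sd(per_dh) / sqrt(n) else NA_real_
  structure(list(delta_h_app = total_heat / sum(moles), se = se,
                 total_heat = total_heat, converted_moles = sum(moles),
                 per_injection = data.frame(injection = seq_len(n),
                                            heat_cal = heats, moles = moles,
                                            delta_h = heats / moles),
                 integration_windows = windows,
                 bolus_displacement = bolus_displacement),
            class = "enthalpy_estimate")
}

#' @export
print.enthalpy_estimate <- function(x, ...) {
  cat(sprintf("Apparent enthalpy: %.5g cal/mol (%d injections, %.4g cal over %.4g mol)\n",
              x$delta_h_app, nrow(x$per_injection), x$total_heat, x$converted_moles))
  invisible(x)
}

#' Convert differential power to reaction rate
#'
#' Pointwise conversion of thermal power to the rate of product formation,
#' `rate = d[P]/dt = (1 / (V * delta_H_app)) * dQ/dt`, returned in uM/s.
#' With matching sign conventions (exothermic: both negative) rates are
#' positive; rates more negative than `-3 * propagated noise` are flagged.
#'
#' @param tg a corrected (and, if the instrument lag matters, deconvolved)
#'   [thermogram()].
#' @param dh an [estimate_delta_h_app()] result, or a numeric enthalpy in
#'   cal/mol.
#' @param cell a [cell_config()].
#' @param noise_sd power noise SD in ucal/s (default: attached value or 0).
#' @return data.frame with columns `time_s`, `rate_uM_per_s`, `flagged`.
#' @export
power_to_rate <- function(tg, dh, cell, noise_sd = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  delta_h <- if (inherits(dh, "enthalpy_estimate")) dh$delta_h_app else dh
  check_scalar(delta_h, "delta_h_app")
  if (delta_h == 0)
    stop(paste0("delta_H_app is zero; the power-to-rate conversion divides by ",
                "it. Estimate the enthalpy from a single-injection experiment ",
                "with measurable heat first."), call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- attr(tg, "noise_sd") %||% 0
  V <- cell$volume
  rate <- tg$power / (delta_h * V) * 1e6          # uM/s
  rate_noise <- noise_sd / abs(delta_h * V) * 1e6
  data.frame(time_s = tg$time, rate_uM_per_s = rate,
             flagged = rate < -3 * rate_noise - 1e-12)
}

#' Residual substrate concentration from cumulative heat
#'
#' Implements the residual-substrate bookkeeping
#' `[S]_t = [S]_total - [P]_t`, with `[P]_t` obtained from the running
#' cumulative heat, `[P]_t = Q(t) / (delta_H_app * V)`. `[S]_total` is a
#' step function raised at each injection; the displacement dilution of an
#' injection is applied to the substrate and product already in the cell,
#' exactly mirroring [apply_injection()], so the reconstruction matches the
#' true in-cell concentrations.
#'
#' @inheritParams power_to_rate
#' @param schedule the [injection_schedule()] of the experiment.
#' @param tol negative-concentration tolerance in uM; `[S]_t` below `-tol`
#'   raises a sign-convention/enthalpy inconsistency error. Default:
#'   `max(3 * propagated noise, 1e-6 * max [S]_total)`.
#' @return data.frame with columns `time_s`, `S_total_uM`, `P_uM`, `S_uM`.
#' @export
substrate_trajectory <- function(tg, dh, schedule, cell, noise_sd = NULL,
                                 tol = NULL) {
  stopifnot(inherits(tg, "thermogram"), inherits(schedule, "injection_schedule"))
  delta_h <- if (inherits(dh, "enthalpy_estimate")) dh$delta_h_app else dh
  check_scalar(delta_h, "delta_h_app")
  if (delta_h == 0) stop("delta_H_app is zero", call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- attr(tg, "noise_sd") %||% 0
  V <- cell$volume
  tt <- tg$time
  Q <- cumtrapz_(tt, tg$power)                              # ucal
  Phat <- Q / (delta_h * V) * 1e6                           # uM, undiluted ledger
                                                            # (same scaling as power_to_rate)
  n <- length(tt)
  S_total <- P <- numeric(n)
  st <- 0; p <- 0
  ev <- schedule$time_s; k <- 1L
  for (i in seq_len(n)) {
    # no substrate is present before the first injection; heat increments
    # before it (numerical leakage of the deconvolution filter) are ignored
    dP <- if (i == 1L) Phat[1L] else Phat[i] - Phat[i - 1L]
    if (tt[i] > ev[1L] + 1e-9) p <- p + dP
    while (k <= length(ev) && tt[i] >= ev[k] - 1e-9) {
      v <- schedule$volume_uL[k]
      st <- st * (1 - v / V) + schedule$syringe_conc_uM[k] * v / V
      p <- p * (1 - v / V)
      k <- k + 1L
    }
    S_total[i] <- st
    P[i] <- p
  }
  S <- S_total - P
  if (is.null(tol)) {
    # propagated noise on cumulative heat at the end of the trace, in uM,
    # plus the contribution of the enthalpy calibration's own uncertainty
    # (a relative error on delta_H scales the whole [P]_t ledger)
    q_noise <- noise_sd * tg$sample_interval * sqrt(n)       # ucal
    dh_rel <- if (inherits(dh, "enthalpy_estimate") && is.finite(dh$se %||% NA))
      dh$se / abs(delta_h) else 0
    tol <- max(3 * (q_noise / abs(delta_h * V) * 1e6 + dh_rel * max(abs(Phat))),
               1e-6 * max(S_total, 1))
  }
  if (any(S < -tol)) {
    i <- which(S < -tol)[1L]
    stop(sprintf(paste0("residual substrate becomes negative (%.4g uM at ",
                        "t = %g s): the enthalpy value and the power sign ",
                        "convention are inconsistent with the schedule"),
                 S[i], tt[i]), call. = FALSE)
  }
  data.frame(time_s = tt, S_total_uM = S_total, P_uM = P, S_uM = S)
}

#' Assemble a rate curve for Michaelis-Menten fitting
#'
#' Pairs the residual substrate concentrations with the pointwise rates on
#' their shared time grid, excluding the pre-first-injection span and a
#' post-injection settling window after every injection (instrument lag and
#' mixing make those samples unreliable). Exclusions are recorded with
#' reason codes.
#'
#' Optionally, a pre-injection guard window can exclude the samples just
#' before each injection, where a smoothing-based deconvolution derivative
#' is contaminated by the next injection's power jump; and when the cell
#' configuration is supplied, each rate is also normalized to the starting
#' enzyme concentration (column `rate_E0_uM_per_s`) using the cumulative
#' displacement dilution factor of the enzyme, so that a single
#' Michaelis-Menten curve with `Vmax = kcat * E0` describes the whole
#' titration despite the ~0.5% enzyme dilution per injection.
#'
#' @param rates a [power_to_rate()] data.frame.
#' @param traj a [substrate_trajectory()] data.frame on the same grid.
#' @param schedule the [injection_schedule()].
#' @param settle settling window in s excluded after each injection;
#'   default `max(5 * tau, 20)`.
#' @param tau instrument time constant in s used for the default window.
#' @param guard exclusion window in s before each subsequent injection
#'   (default 0; set to half the deconvolution smoothing span when rates
#'   come from [deconvolve_tian()]).
#' @param cell a [cell_config()]; when supplied, adds the enzyme dilution
#'   factor `E_factor` and dilution-normalized `rate_E0_uM_per_s` columns.
#' @return an object of class `rate_curve`: a data.frame with columns
#'   `time_s`, `S_uM`, `rate_uM_per_s`, `injection_idx`, `retained` (plus
#'   `E_factor`, `rate_E0_uM_per_s` when `cell` is given), with the
#'   excluded windows (and reason codes) as attribute `excluded_windows`.
#' @export
build_rate_curve <- function(rates, traj, schedule, settle = NULL, tau = 6,
                             guard = 0, cell = NULL) {
  if (!isTRUE(all.equal(rates$time_s, traj$time_s)))
    stop("rate and substrate series must share the same time grid", call. = FALSE)
  if (is.null(settle)) settle <- max(5 * tau, 20)
  check_scalar(settle, "settle", nonneg = TRUE)
  check_scalar(guard, "guard", nonneg = TRUE)
  tt <- rates$time_s
  ev <- schedule$time_s
  retained <- rep(TRUE, length(tt))
  reason <- rep(NA_character_, length(tt))
  pre <- tt < min(ev)
  retained[pre] <- FALSE; reason[pre] <- "pre_injection"
  excl <- list(list(start = min(tt), end = min(ev), reason = "pre_injection"))
  if (settle > 0) {
    for (e in ev) {
      inwin <- tt >= e - 1e-9 & tt < e + settle - 1e-9
      retained[inwin] <- FALSE
      reason[inwin] <- ifelse(is.na(reason[inwin]), "settling", reason[inwin])
      excl <- c(excl, list(list(start = e, end = e + settle, reason = "settling")))
    }
  }
  if (guard > 0) {
    for (e in ev[-1L]) {
      inwin <- tt >= e - guard - 1e-9 & tt < e - 1e-9
      retained[inwin] <- FALSE
      reason[inwin] <- ifelse(is.na(reason[inwin]), "pre_injection_guard",
                              reason[inwin])
      excl <- c(excl, list(list(start = e - guard, end = e,
                                reason = "pre_injection_guard")))
    }
  }
  if (!any(retained))
    stop("all points excluded; shorten the settling window", call. = FALSE)
  inj_idx <- findInterval(tt + 1e-9, ev)
  out <- data.frame(time_s = tt, S_uM = traj$S_uM,
                    rate_uM_per_s = rates$rate_uM_per_s,
                    injection_idx = inj_idx, retained = retained,
                    reason = reason)
  if (!is.null(cell)) {
    dilution <- cumprod(1 - schedule$volume_uL / cell$volume)
    out$E_factor <- ifelse(inj_idx > 0, dilution[pmax(inj_idx, 1L)], 1)
    out$rate_E0_uM_per_s <- out$rate_uM_per_s / out$E_factor
  }
  out <- out[order(out$time_s), ]
  structure(out, excluded_windows = excl,
            class = c("rate_curve", "data.frame"))
}

#' @export
print.rate_curve <- function(x, ...) {
  cat(sprintf("Rate curve: %d points (%d retained); S %.3g-%.3g uM, rate %.3g-%.3g uM/s\n",
              nrow(x), sum(x$retained),
              min(x$S_uM[x$retained]), max(x$S_uM[x$retained]),
              min(x$rate_uM_per_s[x$retained]), max(x$rate_uM_per_s[x$retained])))
  invisible(x)
}

#' Write / read a rate curve as delimited text
#'
#' @param rc a [build_rate_curve()] result.
#' @param path output path.
#' @return `path` invisibly (write); a data.frame (read).
#' @export
write_rate_curve <- function(rc, path) {
  utils::write.csv(as.data.frame(rc)[, c("time_s", "S_uM", "rate_uM_per_s",
                                         "injection_idx", "retained")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_curve
#' @export
read_rate_curve <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  utils::read.csv(path)
}
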