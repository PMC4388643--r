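# Michaelis-Menten parameter estimation. The nonlinear fit runs in
# log-parameter space (positivity without constraints) via
# Levenberg-Marquardt; Lineweaver-Burk and Eadie-Hofstee linearizations
# supply starting values and diagnostics only.

#' Fit configuration for Michaelis-Menten regression
#'
#' @param init `"auto"` (Eadie-Hofstee with Lineweaver-Burk fallback, the
#'   lower-RSS candidate wins) or a numeric `c(Vmax0, Km0)`.
#' @param reltol relative convergence tolerance (default 1e-8).
#' @param max_iter maximum iterations (default 200).
#' @param weights `"none"` (unweighted, the default) or `"inv_rate2"`
#'   (1/rate^2).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(init = "auto", reltol = 1e-8, max_iter = 200,
                       weights = c("none", "inv_rate2")) {
  check_scalar(reltol, "reltol", positive = TRUE)
  weights <- match.arg(weights)
  if (!identical(init, "auto")) {
    check_finite(init, "init")
    if (length(init) != 2L || any(init <= 0))
      stop("'init' must be \"auto\" or positive c(Vmax0, Km0)", call. = FALSE)
  }
  structure(list(init = init, reltol = reltol, max_iter = as.integer(max_iter),
                 weights = weights), class = "fit_config")
}

#' @keywords internal
mm_rate <- function(S, Vmax, Km) Vmax * S / (Km + S)

#' @keywords internal
mm_init_candidates <- function(S, rate) {
  cands <- list()
  ok <- S > 0 & rate > 0
  if (sum(ok) >= 3L) {
    # Eadie-Hofstee: rate = Vmax - Km * (rate/S)
    eh <- tryCatch(stats::lm.fit(cbind(1, rate[ok] / S[ok]), rate[ok])$coefficients,
                   error = function(e) NULL)
    if (!is.null(eh) && eh[1L] > 0 && -eh[2L] > 0)
      cands <- c(cands, list(unname(c(eh[1L], -eh[2L]))))
    # Lineweaver-Burk: 1/rate = 1/Vmax + (Km/Vmax) * (1/S)
    lb <- tryCatch(stats::lm.fit(cbind(1, 1 / S[ok]), 1 / rate[ok])$coefficients,
                   error = function(e) NULL)
    if (!is.null(lb) && lb[1L] > 0 && lb[2L] / lb[1L] > 0)
      cands <- c(cands, list(unname(c(1 / lb[1L], lb[2L] / lb[1L]))))
  }
  # crude fallback: saturating rate and mid-range S
  cands <- c(cands, list(c(max(rate[rate > 0], 1e-6) * 1.2,
                           max(stats::median(S[S > 0]), 1e-6))))
  cands
}

#' Nonlinear Michaelis-Menten fit
#'
#' Least-squares fit of `rate = Vmax * S / (Km + S)` by damped Gauss-Newton
#' (Levenberg-Marquardt) on `log(Vmax)`, `log(Km)`, which enforces
#' positivity without constrained optimisation. Standard errors come from
#' the Jacobian at the optimum (delta method back to the natural scale).
#' The convergence flag is honest: a fit that stops on the iteration limit
#' is returned flagged, not raised.
#'
#' @param S substrate concentrations in uM (or a `rate_curve`, whose
#'   retained points are used).
#' @param rate reaction rates in uM/s (omit when `S` is a `rate_curve`).
#' @param cfg a [fit_config()].
#' @return an object of class `mm_fit`: list with `Vmax` (uM/s), `Km` (uM),
#'   `se` (named, Vmax/Km), `rss`, `converged`, `iterations`, `reliable`,
#'   `n`, `data`, and NA placeholders for the derived constants filled by
#'   [derive_catalytic_constants()].
#' @export
#' @examples
#' S <- c(5, 10, 20, 40, 80, 160)
#' fit <- fit_michaelis_menten(S, 0.325 * S / (56.7 + S))
#' c(fit$Vmax, fit$Km)
fit_michaelis_menten <- function(S, rate = NULL, cfg = fit_config()) {
  if (inherits(S, "rate_curve")) {
    rc <- S[S$retained, ]
    S <- rc$S_uM
    # prefer rates normalized to the starting enzyme concentration
    rate <- if (!is.null(rc$rate_E0_uM_per_s)) rc$rate_E0_uM_per_s
            else rc$rate_uM_per_s
  }
  check_finite(S, "S"); check_finite(rate, "rate")
  if (length(S) != length(rate)) stop("'S' and 'rate' lengths differ", call. = FALSE)
  if (length(S) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(S < 0) || any(rate < 0))
    stop("'S' and 'rate' must be non-negative", call. = FALSE)
  if (length(unique(S)) < 2L)
    stop("degenerate design: all substrate concentrations are equal", call. = FALSE)
  w <- if (cfg$weights == "inv_rate2") {
    if (any(rate == 0)) stop("1/rate^2 weighting requires all rates > 0", call. = FALSE)
    1 / rate^2
  } else rep(1, length(S))
  sw <- sqrt(w)
  resid_fn <- function(lp) sw * (rate - mm_rate(S, exp(lp[1L]), exp(lp[2L])))
  cands <- if (identical(cfg$init, "auto")) mm_init_candidates(S, rate)
           else list(cfg$init)
  rss_of <- function(th) sum(resid_fn(log(th))^2)
  start <- cands[[which.min(vapply(cands, rss_of, numeric(1)))]]
  ctl <- minpack.lm::nls.lm.control(ftol = cfg$reltol, ptol = cfg$reltol,
                                    maxiter = cfg$max_iter)
  # nls.lm warns on iteration-cap stops; convergence is reported honestly
  # through the returned flag instead
  res <- suppressWarnings(minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                                             control = ctl))
  lp <- res$par
  Vmax <- exp(lp[1L]); Km <- exp(lp[2L])
  converged <- res$info %in% 1:4
  rss <- sum(res$fvec^2)
  n <- length(S)
  se <- c(Vmax = NA_real_, Km = NA_real_)
  se_log <- c(NA_real_, NA_real_)
  covl <- tryCatch({
    sigma2 <- rss / max(n - 2L, 1L)
    sigma2 * solve(res$hessian)       # nls.lm's hessian is the J'J approximation
  }, error = function(e) NULL)
  if (is.null(covl)) covl <- tryCatch({
    J <- numeric_jacobian(resid_fn, lp)
    sigma2 <- rss / max(n - 2L, 1L)
    sigma2 * solve(crossprod(J))
  }, error = function(e) NULL)
  if (!is.null(covl) && all(diag(covl) >= 0)) {
    se_log <- unname(sqrt(diag(covl)))
    se <- c(Vmax = Vmax * se_log[1L], Km = Km * se_log[2L])
  }
  # parameters are declared unreliable when a log-scale SE exceeds 0.5
  # (a 1-sigma interval spanning more than a factor 1.65), as in the
  # saturation limit where Km is unidentifiable
  reliable <- converged && !anyNA(se_log) && all(se_log < 0.5)
  structure(list(Vmax = Vmax, Km = Km, se = se, se_log = se_log, rss = rss,
                 converged = converged, iterations = res$niter,
                 reliable = reliable, n = n,
                 kcat = NA_real_, efficiency = NA_real_,
                 specific_activity = NA_real_, E0 = NA_real_, MW = NA_real_,
                 data = data.frame(S_uM = S, rate_uM_per_s = rate)),
            class = "mm_fit")
}

#' @keywords internal
numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d): Vmax = %.5g +/- %.2g uM/s, Km = %.5g +/- %.2g uM\n",
              x$n, x$Vmax, x$se[["Vmax"]], x$Km, x$se[["Km"]]))
  cat(sprintf("  RSS %.4g; %s in %d iterations%s\n", x$rss,
              if (x$converged) "converged" else "NOT converged", x$iterations,
              if (!x$reliable) " [parameters flagged unreliable]" else ""))
  if (!is.na(x$kcat)) {
    cat(sprintf("  kcat = %.4g s^-1, kcat/Km = %.3g s^-1 uM^-1 (reported: %.2g)\n",
                x$kcat, x$efficiency, round_efficiency(x$efficiency)))
    if (!is.na(x$specific_activity))
      cat(sprintf("  specific activity = %.4g U/mg\n", x$specific_activity))
  }
  invisible(x)
}

#' Lineweaver-Burk linearization (diagnostic only)
#'
#' Ordinary least squares on the double-reciprocal plot
#' `1/rate = 1/Vmax + (Km/Vmax) * (1/S)`. Points with zero rate or zero
#' substrate are dropped with a warning. Linearization distorts the error
#' structure, so the returned parameters are diagnostics, not estimates; use
#' [fit_michaelis_menten()] for inference.
#'
#' @param S substrate concentrations in uM.
#' @param rate rates in uM/s.
#' @return list with `slope` (s), `intercept` (s uM^-1... i.e. 1/Vmax),
#'   `Km` (uM), `Vmax` (uM/s), `n`, and `diagnostic_only = TRUE`.
#' @export
lineweaver_burk <- function(S, rate) {
  check_finite(S, "S"); check_finite(rate, "rate")
  drop <- S <= 0 | rate <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d point(s) with zero/negative S or rate", sum(drop)))
    S <- S[!drop]; rate <- rate[!drop]
  }
  if (length(S) < 2L) stop("need at least 2 usable points", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, 1 / S), 1 / rate)
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  list(slope = slope, intercept = intercept,
       Km = slope / intercept, Vmax = 1 / intercept, n = length(S),
       diagnostic_only = TRUE)
}

#' Derive catalytic constants from a Michaelis-Menten fit
#'
#' Augments an [fit_michaelis_menten()] result (or bare Vmax/Km) with the
#' turnover number `kcat = Vmax / E0` (s^-1), the catalytic efficiency
#' `kcat / Km` (s^-1 uM^-1), and, when the molecular weight is available,
#' the specific activity in U/mg, where one unit (U) is the amount of
#' enzyme that oxidizes 1 umol of substrate per minute:
#' `specific activity = kcat * 60 * 1000 / MW`.
#'
#' @param fit an `mm_fit`, or a list/vector with `Vmax` and `Km`.
#' @param E0 enzyme concentration in uM (> 0).
#' @param MW enzyme molecular weight in g/mol; when absent the specific
#'   activity is omitted (NA), never reported as zero.
#' @return the augmented `mm_fit`.
#' @export
#' @examples
#' fit <- list(Vmax = 3382 * 0.01, Km = 65.0)
#' out <- derive_catalytic_constants(fit, E0 = 0.01, MW = 67700)
#' round_efficiency(out$efficiency)
derive_catalytic_constants <- function(fit, E0, MW = NULL) {
  check_scalar(E0, "E0", positive = TRUE)
  if (!is.null(MW)) check_scalar(MW, "MW", positive = TRUE)
  if (!inherits(fit, "mm_fit")) {
    fit2 <- structure(list(Vmax = fit$Vmax %||% fit[["Vmax"]],
                           Km = fit$Km %||% fit[["Km"]],
                           se = c(Vmax = NA_real_, Km = NA_real_),
                           rss = NA_real_, converged = TRUE, iterations = 0L,
                           reliable = TRUE, n = NA_integer_,
                           kcat = NA_real_, efficiency = NA_real_,
                           specific_activity = NA_real_,
                           E0 = NA_real_, MW = NA_real_, data = NULL),
                      class = "mm_fit")
    fit <- fit2
  }
  fit$E0 <- E0
  fit$kcat <- fit$Vmax / E0                 # s^-1
  fit$efficiency <- fit$kcat / fit$Km       # s^-1 uM^-1
  if (!is.null(MW)) {
    fit$MW <- MW
    fit$specific_activity <- fit$kcat * 60 * 1000 / MW   # U/mg
  }
  fit
}
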