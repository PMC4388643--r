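# Canonical units used throughout the package:
#   time s, power ucal/s, concentration uM, volume uL, enthalpy cal/mol,
#   rate uM/s, heat cal, absorbance AU, extinction M^-1 cm^-1.
# Conversions happen only at I/O boundaries (readers) and in the few
# documented formulas below.

#' @keywords internal
check_finite <- function(x, what) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", what), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains NA/NaN/infinite values", what), call. = FALSE)
  invisible(x)
}

#' @keywords internal
check_scalar <- function(x, what, positive = FALSE, nonneg = FALSE) {
  check_finite(x, what)
  if (length(x) != 1L) stop(sprintf("'%s' must be a single number", what), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", what), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", what), call. = FALSE)
  invisible(x)
}

# Trapezoidal integral of y over x (same as pracma::trapz; kept local so the
# integration rule used for Eq 1 is explicit and dependency-free).
#' @keywords internal
trapz_ <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' @keywords internal
cumtrapz_ <- function(x, y) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  c(0, cumsum((x[-1L] - x[-n]) * (y[-1L] + y[-n]) / 2))
}

# Heat in cal from a power trace in ucal/s over time in s.
#' @keywords internal
power_trapz_cal <- function(time, power) trapz_(time, power) * 1e-6

# moles of a species at concentration conc_uM in a volume vol_uL
#' @keywords internal
moles_from_conc <- function(conc_uM, vol_uL) conc_uM * vol_uL * 1e-12

# Rounding convention used for reported catalytic efficiencies: two
# significant figures, one when the value is below 0.01 in magnitude.
#' Round a catalytic efficiency for reporting
#'
#' Reported catalytic efficiencies (kcat/Km) are conventionally quoted at two
#' significant figures, and at one significant figure for values below 0.01
#' s^-1 uM^-1. Full precision is always retained in fit objects; this helper
#' only formats values for report output.
#'
#' @param x numeric vector of efficiencies (s^-1 uM^-1).
#' @return numeric vector rounded per the convention.
#' @export
#' @examples
#' round_efficiency(c(52.03, 0.3252, 0.004127))
round_efficiency <- function(x) {
  check_finite(x, "x")
  ifelse(abs(x) < 0.01, signif(x, 1), signif(x, 2))
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
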