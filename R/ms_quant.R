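# Mass-spec quantification: conversions between IMP-per-10^6-AMP nucleoside
# levels and per-base inosine incorporation rates ("1 in N bases"), the
# A-fraction calibration that links them, and the 1/x-weighted linear
# calibration fit used for instrument response curves.
#
# Derivation of the conversion: IMP is reported per 10^6 AMP, so
#   per-base inosine frequency = (IMP / AMP) * (A / total bases)
#                              = level * 1e-6 * f_A.
# This is the only formula consistent with every printed level/denominator
# pair, and "1 in N" denominators follow by nearest-integer rounding.

#' Convert a nucleoside level to a per-base incorporation rate
#'
#' @param level IMP per 10^6 AMP (non-negative).
#' @param f_A Fraction of A among all bases, in (0, 1). For in vitro
#'   transcripts this is the reference composition ([a_fraction()]); for
#'   total RNA calibrate it from a known (level, denominator) pair with
#'   [calibrate_f_A()].
#' @return An object of class `incorporation_rate`: list with
#'   `freq_per_base` and `denominator` (nearest integer to
#'   `1/freq_per_base`; `NA` and flagged when the level is 0).
#' @export
rate_from_level <- function(level, f_A) {
  if (!is_scalar_number(level) || level < 0) stop("level must be >= 0")
  if (!is_scalar_number(f_A) || f_A <= 0 || f_A >= 1)
    stop("f_A must be in (0, 1)")
  freq <- level * 1e-6 * f_A
  denom <- if (freq > 0) round(1 / freq) else NA_real_
  structure(list(freq_per_base = freq, denominator = denom, f_A = f_A,
                 level = level),
            class = "incorporation_rate")
}

#' @export
print.incorporation_rate <- function(x, ...) {
  if (is.na(x$denominator))
    cat("<incorporation_rate> zero level: frequency 0, denominator undefined\n")
  else
    cat(sprintf("<incorporation_rate> %.4g per base (~1 in %d bases), f_A = %.4f\n",
                x$freq_per_base, as.integer(x$denominator), x$f_A))
  invisible(x)
}

#' Convert a per-base incorporation rate to a nucleoside level
#'
#' Inverse of [rate_from_level()]: `level = freq * 1e6 / f_A`.
#'
#' @param freq_per_base Per-base inosine frequency in `[0, 1]`.
#' @param f_A Fraction of A among all bases, in (0, 1).
#' @return Level in IMP per 10^6 AMP.
#' @export
level_from_rate <- function(freq_per_base, f_A) {
  if (!is_scalar_number(f_A) || f_A <= 0 || f_A >= 1)
    stop("f_A must be in (0, 1)")
  if (!is_scalar_number(freq_per_base) || freq_per_base < 0 ||
      freq_per_base > 1)
    stop("freq_per_base must be in [0, 1]")
  freq_per_base * 1e6 / f_A
}

#' Calibrate the A fraction from a paired level and denominator
#'
#' Inverts the level-to-rate conversion on a known pair:
#' `f_A = 1e6 / (level * denominator)`. Useful for total RNA where the
#' transcriptome-wide A fraction is not directly known.
#'
#' @param level IMP per 10^6 AMP (> 0).
#' @param denominator "1 in N" denominator (> 0).
#' @return The implied A fraction.
#' @export
calibrate_f_A <- function(level, denominator) {
  if (!is_scalar_number(level) || level <= 0) stop("level must be > 0")
  if (!is_scalar_number(denominator) || denominator <= 0)
    stop("denominator must be > 0")
  1e6 / (level * denominator)
}

#' A fraction of a transcript reference
#'
#' @param ref A [transcript_ref()].
#' @return Count of A divided by length.
#' @export
a_fraction <- function(ref) {
  unname(ref$base_fractions["A"])
}

#' 1/x-weighted linear calibration fit
#'
#' Weighted least squares minimizing `sum((1/x_i) * (y_i - a - b x_i)^2)`,
#' the standard weighting for calibration curves whose noise grows with
#' concentration. Fitted via `stats::lm(y ~ x, weights = 1/x)`.
#'
#' @param x Concentrations; all > 0, at least 2 distinct values.
#' @param y Instrument responses.
#' @return An object of class `calibration_curve`: list with `slope`,
#'   `intercept`, `r_squared` (weighted), `residual_sd` and the underlying
#'   `fit`.
#' @export
weighted_linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(x <= 0)) stop("all x must be > 0 (1/x weighting)")
  if (length(unique(x)) < 2L) stop("need at least 2 distinct x values")
  fit <- stats::lm(y ~ x, weights = 1 / x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared,
                 residual_sd = s$sigma,
                 fit = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> y = %.6g + %.6g x  (1/x-weighted, R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Inverse prediction from a calibration curve
#'
#' @param curve A [calibration_curve()].
#' @param response Instrument response(s).
#' @return `(response - intercept) / slope`.
#' @export
quantify_unknown <- function(curve, response) {
  if (curve$slope == 0) stop("calibration slope is zero; cannot invert")
  (response - curve$intercept) / curve$slope
}
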