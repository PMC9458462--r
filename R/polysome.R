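# Polysome-profile quantification: baseline normalization by the lowest
# point between the 40S and 60S peaks, peak boundaries at the lowest
# abutting points (valley argmin between apexes), the polysome region
# sized as a fixed multiple (default 1.42x) of the 60S-to-(80S&disome)
# apex distance, trapezoid areas and the polysome:(80S&disome) AUC ratio
# as a proxy for active translation, plus the replicate group t-test.

#' Peak landmarks for a polysome trace
#'
#' Approximate apex positions of the 40S, 60S and merged 80S&disome peaks
#' (user-supplied; the monosome and disome peaks are considered together
#' when they are not resolvable).
#'
#' @param x40s,x60s,x80s_disome Strictly increasing apex positions.
#' @return Named numeric vector of class `peak_landmarks`.
#' @export
peak_landmarks <- function(x40s, x60s, x80s_disome) {
  v <- c(`40S` = x40s, `60S` = x60s, `80S_disome` = x80s_disome)
  if (any(diff(v) <= 0)) stop("landmarks must be strictly increasing")
  structure(v, class = "peak_landmarks")
}

check_landmarks_in_trace <- function(trace, landmarks) {
  rng <- range(trace$position)
  if (any(landmarks < rng[1L]) || any(landmarks > rng[2L]))
    stop("landmarks fall outside the trace range")
}

#' Baseline-normalize a polysome trace
#'
#' Subtracts the minimum absorbance found between the 40S and 60S apexes
#' (the lowest point abutting those peaks) from the whole trace.
#' Idempotent: after subtraction that minimum is 0.
#'
#' @param trace A [profile_trace()].
#' @param landmarks A [peak_landmarks()].
#' @return The normalized trace with attribute `baseline_offset`.
#' @export
normalize_trace <- function(trace, landmarks) {
  check_landmarks_in_trace(trace, landmarks)
  i <- trace$position >= landmarks[["40S"]] &
    trace$position <= landmarks[["60S"]]
  offset <- min(trace$absorbance[i])
  out <- profile_trace(trace$position, trace$absorbance - offset)
  attr(out, "baseline_offset") <- offset
  out
}

argmin_between <- function(trace, lo, hi) {
  i <- which(trace$position >= lo & trace$position <= hi)
  i[which.min(trace$absorbance[i])]  # leftmost on ties
}

trace_value_at <- function(trace, x) {
  stats::approx(trace$position, trace$absorbance, xout = x)$y
}

#' Peak boundaries at the lowest abutting points
#'
#' The boundary between adjacent peaks is the position of the minimum
#' absorbance between their apexes (leftmost on ties). The leading
#' boundary of the 40S peak is the minimum before its apex; the trailing
#' boundary of the 80S&disome peak is the minimum within a symmetric
#' search span mirroring the 60S-to-apex distance (clipped to the trace
#' end). Each apex must sit strictly above its bounding minima, otherwise
#' the landmarks are inconsistent with the trace.
#'
#' @param trace A (normalized) [profile_trace()].
#' @param landmarks A [peak_landmarks()].
#' @return An object of class `peak_boundaries`: list with `points`
#'   (named boundary positions), `intervals` (list of `c(start, end)` for
#'   `40S`, `60S`, `80S_disome`), `landmarks` and `trace_end`.
#' @export
find_boundaries <- function(trace, landmarks) {
  check_landmarks_in_trace(trace, landmarks)
  a40 <- landmarks[["40S"]]; a60 <- landmarks[["60S"]]
  a80 <- landmarks[["80S_disome"]]
  x <- trace$position
  i0 <- argmin_between(trace, x[1L], a40)
  i1 <- argmin_between(trace, a40, a60)
  i2 <- argmin_between(trace, a60, a80)
  span_end <- min(a80 + (a80 - a60), x[length(x)])
  i3 <- argmin_between(trace, a80, span_end)
  p <- c(lead_40S = x[i0], b_40S_60S = x[i1], b_60S_80S = x[i2],
         trail_80S = x[i3])
  apex_val <- trace_value_at(trace, c(a40, a60, a80))
  min_val <- trace$absorbance[c(i0, i1, i2, i3)]
  ok <- apex_val[1L] > min_val[1L] && apex_val[1L] > min_val[2L] &&
    apex_val[2L] > min_val[2L] && apex_val[2L] > min_val[3L] &&
    apex_val[3L] > min_val[3L] && apex_val[3L] > min_val[4L]
  if (!ok)
    stop("landmarks inconsistent with trace: no valley separates the peaks")
  structure(list(points = p,
                 intervals = list(`40S` = c(p[["lead_40S"]], p[["b_40S_60S"]]),
                                  `60S` = c(p[["b_40S_60S"]], p[["b_60S_80S"]]),
                                  `80S_disome` = c(p[["b_60S_80S"]],
                                                   p[["trail_80S"]])),
                 landmarks = landmarks,
                 trace_end = x[length(x)]),
            class = "peak_boundaries")
}

#' Polysome region from peak boundaries
#'
#' Starts at the trailing boundary of the 80S&disome peak and extends for
#' `factor` times the 60S-to-(80S&disome) apex distance (default 1.42),
#' clipped to the trace end with a warning.
#'
#' @param boundaries A [find_boundaries()] result.
#' @param factor Length multiplier (default 1.42).
#' @return `c(start, end)` interval.
#' @export
polysome_region <- function(boundaries, factor = 1.42) {
  d <- boundaries$landmarks[["80S_disome"]] - boundaries$landmarks[["60S"]]
  if (d <= 0) stop("zero 60S-(80S&disome) distance")
  start <- boundaries$points[["trail_80S"]]
  end <- start + factor * d
  if (end > boundaries$trace_end) {
    warning("polysome region truncated at trace end", call. = FALSE)
    end <- boundaries$trace_end
  }
  c(start = start, end = end)
}

#' Trapezoid area under a trace over an interval
#'
#' Composite trapezoid rule on the sampled points, with linear
#' interpolation at interval endpoints falling between samples. Additive:
#' `auc(t, [a,b]) + auc(t, [b,c]) == auc(t, [a,c])`.
#'
#' @param trace A [profile_trace()].
#' @param interval `c(start, end)` within the trace range.
#' @return The area (0 for an empty interval).
#' @export
auc <- function(trace, interval) {
  a <- interval[1L]; b <- interval[2L]
  if (b <= a) return(0)
  rng <- range(trace$position)
  if (a < rng[1L] || b > rng[2L])
    stop("interval extends beyond the trace")
  inner <- trace$position > a & trace$position < b
  xs <- c(a, trace$position[inner], b)
  ys <- c(trace_value_at(trace, a), trace$absorbance[inner],
          trace_value_at(trace, b))
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Polysome-to-monosome translation metrics for one trace
#'
#' Full pipeline: baseline normalization, boundary detection, polysome
#' region construction, trapezoid AUCs and the
#' polysome:(80S&disome) ratio. The ratio is invariant to scaling the
#' whole trace and is `NA` when the 80S&disome area is not positive.
#'
#' @param trace A raw [profile_trace()].
#' @param landmarks A [peak_landmarks()].
#' @param factor Polysome region multiplier (default 1.42).
#' @return An object of class `translation_metrics`: list with
#'   `auc_polysome`, `auc_80s_disome`, `ratio`, `boundaries`, `region`.
#' @export
translation_ratio <- function(trace, landmarks, factor = 1.42) {
  norm <- normalize_trace(trace, landmarks)
  bounds <- find_boundaries(norm, landmarks)
  region <- polysome_region(bounds, factor = factor)
  a_poly <- auc(norm, region)
  a_mono <- auc(norm, bounds$intervals[["80S_disome"]])
  structure(list(auc_polysome = a_poly,
                 auc_80s_disome = a_mono,
                 ratio = if (a_mono > 0) a_poly / a_mono else NA_real_,
                 boundaries = bounds, region = region),
            class = "translation_metrics")
}

#' @export
print.translation_metrics <- function(x, ...) {
  cat(sprintf("<translation_metrics> polysome AUC %.4g, 80S&disome AUC %.4g, ratio %.4g\n",
              x$auc_polysome, x$auc_80s_disome, x$ratio))
  invisible(x)
}

#' Compare translation ratios between two groups
#'
#' Unpaired two-tailed Student's t-test (equal variance; Welch behind a
#' flag). Zero pooled variance with separated means raises the
#' `exact_separation` flag instead of a p-value.
#'
#' @param ratios_a,ratios_b Numeric vectors, at least 2 values each.
#' @param welch Logical; Welch's unequal-variance test.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `exact_separation`.
#' @export
compare_groups <- function(ratios_a, ratios_b, welch = FALSE) {
  if (length(ratios_a) < 2L || length(ratios_b) < 2L)
    stop("need at least 2 values per group")
  ma <- mean(ratios_a); mb <- mean(ratios_b)
  if (stats::var(ratios_a) == 0 && stats::var(ratios_b) == 0) {
    if (ma == mb)
      return(list(t = 0, df = length(ratios_a) + length(ratios_b) - 2L,
                  p = 1, mean_a = ma, mean_b = mb, exact_separation = FALSE))
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_a = ma, mean_b = mb, exact_separation = TRUE))
  }
  tt <- stats::t.test(ratios_a, ratios_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = ma, mean_b = mb, exact_separation = FALSE)
}
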