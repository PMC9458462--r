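# Core substitution statistics: per-position substitution frequency,
# per-base accuracy, class-specific (ref>alt) frequencies, two-condition
# deltas with enrichment tallies, and fold changes. The denominator
# everywhere is matches + mismatches (deletions and N calls excluded);
# positions with a zero denominator are undefined, excluded from means and
# tallies, and reported in the QC count.

#' Per-position base substitution frequency
#'
#' `100 * mismatches / (matches + mismatches)`, the proxy statistic for
#' misincorporation. Undefined (NA) when the total is zero.
#'
#' @param matches,mismatches Non-negative counts (vectorized).
#' @return Percent in `[0, 100]`, `NA` where `matches + mismatches == 0`.
#' @export
substitution_frequency <- function(matches, mismatches) {
  if (any(matches < 0) || any(mismatches < 0))
    stop("matches and mismatches must be non-negative")
  total <- matches + mismatches
  ifelse(total > 0, 100 * mismatches / total, NA_real_)
}

#' Substitution profile of a pileup table
#'
#' Computes the per-position substitution frequency, the per-base accuracy
#' (`100 -` mean of the positional frequencies over positions sharing that
#' reference base; unweighted by default, depth-weighted behind a flag) and
#' the mean class-specific frequency for each of the 12 ref>alt classes.
#'
#' @param table A [pileup_table()].
#' @param depth_weighted Logical; when `TRUE` per-base accuracies weight
#'   positional frequencies by `matches + mismatches`.
#' @return An object of class `substitution_profile`: list with `ref_id`,
#'   `by_position` (pos, ref_base, total, freq), `per_base_accuracy`
#'   (named percent, NA for absent bases), `class_mean` (named "X>Y"
#'   percents), `n_undefined` and `depth_weighted`.
#' @export
substitution_profile <- function(table, depth_weighted = FALSE) {
  total <- table$matches + table$mismatches
  freq <- substitution_frequency(table$matches, table$mismatches)
  acc <- sapply(RNA_BASES, function(b) {
    i <- table$ref_base == b & !is.na(freq)
    if (!any(i)) return(NA_real_)
    m <- if (depth_weighted) stats::weighted.mean(freq[i], total[i])
         else mean(freq[i])
    100 - m
  })
  classes <- unlist(lapply(RNA_BASES, function(r)
    paste0(r, ">", setdiff(RNA_BASES, r))))
  class_mean <- vapply(classes, function(cl) {
    rb <- substr(cl, 1L, 1L); ab <- substr(cl, 3L, 3L)
    cf <- class_frequency(table, rb, ab)
    cf$mean
  }, numeric(1))
  structure(list(ref_id = attr(table, "ref_id"),
                 by_position = data.frame(pos = table$pos,
                                          ref_base = table$ref_base,
                                          total = total, freq = freq),
                 per_base_accuracy = acc,
                 class_mean = class_mean,
                 n_undefined = sum(is.na(freq)),
                 depth_weighted = depth_weighted),
            class = "substitution_profile")
}

#' @export
print.substitution_profile <- function(x, ...) {
  cat(sprintf("<substitution_profile> %s: %d positions (%d undefined)\n",
              x$ref_id, nrow(x$by_position), x$n_undefined))
  cat(sprintf("  mean substitution frequency: %.3f%%\n",
              mean(x$by_position$freq, na.rm = TRUE)))
  cat("  per-base accuracy (%):",
      paste(sprintf("%s=%.2f", names(x$per_base_accuracy),
                    x$per_base_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Class-specific substitution frequency
#'
#' Frequency of a specific `ref > alt` substitution:
#' `100 * count_alt / (matches + mismatches)` at each position whose
#' reference is `ref_base`.
#'
#' @param table A [pileup_table()].
#' @param ref_base,alt_base Distinct bases in A, C, G, U (T accepted).
#' @return List with `ref_base`, `alt_base`, `by_position` (pos, freq) and
#'   `mean` (NA-excluded mean; NA when no positions carry `ref_base`).
#' @export
class_frequency <- function(table, ref_base, alt_base) {
  ref_base <- check_base(ref_base); alt_base <- check_base(alt_base)
  if (ref_base == alt_base) stop("ref_base and alt_base must differ")
  i <- table$ref_base == ref_base
  total <- table$matches[i] + table$mismatches[i]
  alt_col <- paste0("count_", alt_base)
  freq <- ifelse(total > 0, 100 * table[[alt_col]][i] / total, NA_real_)
  list(ref_base = ref_base, alt_base = alt_base,
       by_position = data.frame(pos = table$pos[i], freq = freq),
       mean = if (any(!is.na(freq))) mean(freq, na.rm = TRUE) else NA_real_)
}

#' Between-condition delta profile with enrichment tallies
#'
#' Positionwise difference of substitution frequencies (treated minus
#' control) with a tally of positions enriched in each condition. Positions
#' undefined in either profile are excluded from deltas and counted
#' separately; ties (`|delta| <= tie_epsilon`) get their own tally so that
#' `n_enriched_treated + n_enriched_control + n_ties` equals the number of
#' evaluated positions.
#'
#' @param control,treated [substitution_profile()]s over the same
#'   reference and position set.
#' @param tie_epsilon Absolute delta at or below which a position counts
#'   as a tie (default 0, exact ties only).
#' @return An object of class `delta_profile`.
#' @export
delta_profile <- function(control, treated, tie_epsilon = 0) {
  if (!identical(control$ref_id, treated$ref_id))
    stop("profiles computed against different references")
  if (!identical(control$by_position$pos, treated$by_position$pos))
    stop("profiles cover different position sets")
  fc <- control$by_position$freq; ft <- treated$by_position$freq
  defined <- !is.na(fc) & !is.na(ft)
  delta <- ft[defined] - fc[defined]
  structure(list(ref_id = control$ref_id,
                 by_position = data.frame(pos = control$by_position$pos[defined],
                                          delta = delta),
                 n_enriched_treated = sum(delta > tie_epsilon),
                 n_enriched_control = sum(delta < -tie_epsilon),
                 n_ties = sum(abs(delta) <= tie_epsilon),
                 n_undefined = sum(!defined),
                 tie_epsilon = tie_epsilon),
            class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat(sprintf("<delta_profile> %s: %d evaluated positions (%d undefined)\n",
              x$ref_id, nrow(x$by_position), x$n_undefined))
  cat(sprintf("  enriched treated: %d | enriched control: %d | ties: %d\n",
              x$n_enriched_treated, x$n_enriched_control, x$n_ties))
  invisible(x)
}

#' Fold change of substitution frequencies
#'
#' Ratio of the frequency in the test (e.g. Itpa-null) library to its
#' counterpart control (wild-type) library. Undefined (`NA`) where the
#' denominator is zero; never an error in batch use.
#'
#' @param freq_null,freq_wt Frequencies (vectorized).
#' @return `freq_null / freq_wt`, `NA` where `freq_wt == 0`.
#' @export
fold_change <- function(freq_null, freq_wt) {
  ifelse(freq_wt > 0, freq_null / freq_wt, NA_real_)
}

#' Accuracy hierarchy of a substitution profile
#'
#' Bases ordered by decreasing per-base accuracy. Ties are broken
#' alphabetically and flagged; bases absent from the reference are dropped
#' with a warning (partial hierarchy).
#'
#' @param profile A [substitution_profile()].
#' @return Character vector of bases, most accurate first, with attribute
#'   `ties` (logical).
#' @export
accuracy_hierarchy <- function(profile) {
  acc <- profile$per_base_accuracy
  missing <- names(acc)[is.na(acc)]
  if (length(missing)) {
    warning(sprintf("base(s) %s absent from reference; partial hierarchy",
                    paste(missing, collapse = ", ")), call. = FALSE)
    acc <- acc[!is.na(acc)]
  }
  ord <- order(-acc, names(acc))
  structure(names(acc)[ord], ties = anyDuplicated(acc) > 0)
}
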