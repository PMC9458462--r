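# Candidate-gene windowed substitution analysis (short-read arm): variant
# quality filtering, class tallies, the first contiguous window from the
# 5' end where every position clears a depth threshold, pooled window
# class frequencies, and replicate group comparison (two-sample t-test, or
# one-way ANOVA with Dunnett's multiple comparisons against a designated
# control for a multi-gene panel).

#' Filter variant records by quality
#'
#' Keeps records with `qual >= min_q` (boundary inclusive), preserving
#' order. Records flagged as missing-QUAL carry `qual = 0` and are thus
#' excluded at any positive threshold.
#'
#' @param records Data frame as from [read_vcf_minimal()].
#' @param min_q Minimum Q score (default 20).
#' @return The filtered data frame.
#' @export
filter_variants <- function(records, min_q = 20) {
  records[records$qual >= min_q, , drop = FALSE]
}

#' Count variants by substitution class
#'
#' Classes are keyed `"X>Y"` with bases normalized to the RNA alphabet
#' (`T` reported as `U`). When `classes` is supplied, absent classes are
#' reported as 0 rather than dropped.
#'
#' @param records (Q-filtered) variant records.
#' @param classes Optional character vector of classes to report.
#' @return List with `counts` (named integer vector) and `total`.
#' @export
count_variants_by_class <- function(records, classes = NULL) {
  key <- paste0(normalize_rna(records$ref), ">", normalize_rna(records$alt))
  tab <- table(key)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (!is.null(classes)) {
    out <- stats::setNames(integer(length(classes)), classes)
    hit <- intersect(classes, names(counts))
    out[hit] <- counts[hit]
    counts <- out
  }
  list(counts = counts, total = nrow(records))
}

#' First depth-qualified window from the 5' end
#'
#' Scans per-position depths from position 1 and returns the first
#' (smallest-start) run of exactly `window_len` consecutive positions that
#' all meet the depth threshold (`rule = "pointwise"`, the default reading
#' of a "continuous 50x stretch"), or whose mean depth meets it
#' (`rule = "mean"`).
#'
#' @param depths Per-position depths indexed 1..L in transcript
#'   coordinates (5' end first).
#' @param window_len Window length (default 1000, i.e. 1 kb).
#' @param min_depth Depth threshold (default 50).
#' @param rule `"pointwise"` or `"mean"`.
#' @return `c(start, end)` (1-based inclusive, `end - start + 1 ==
#'   window_len`) or `NULL` when no window qualifies.
#' @export
find_window <- function(depths, window_len = 1000L, min_depth = 50,
                        rule = c("pointwise", "mean")) {
  rule <- match.arg(rule)
  L <- length(depths)
  if (window_len > L) {
    warning("window_len exceeds track length; no window", call. = FALSE)
    return(NULL)
  }
  if (rule == "pointwise") {
    ok <- depths >= min_depth
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= window_len)
    if (!length(hit)) return(NULL)
    s <- starts[hit[1L]]
  } else {
    csum <- c(0, cumsum(as.numeric(depths)))
    means <- (csum[(window_len + 1L):(L + 1L)] - csum[1:(L - window_len + 1L)]) /
      window_len
    idx <- which(means >= min_depth)
    if (!length(idx)) return(NULL)
    s <- idx[1L]
  }
  c(start = s, end = s + window_len - 1L)
}

#' Pooled class-specific substitution frequency within a window
#'
#' Pools counts across the window before dividing (robust at modest
#' depth): `100 * sum(count_alt) / sum(matches + mismatches)` over window
#' positions whose reference base is `ref_base`. Equals the depth-weighted
#' mean of positional class frequencies.
#'
#' @param table A [pileup_table()].
#' @param window `c(start, end)`, 1-based inclusive.
#' @param ref_base,alt_base Distinct bases.
#' @return Percent, or `NA` (with a warning) when the window contains no
#'   `ref_base` positions or no calls at them.
#' @export
window_class_frequency <- function(table, window, ref_base, alt_base) {
  ref_base <- check_base(ref_base); alt_base <- check_base(alt_base)
  if (ref_base == alt_base) stop("ref_base and alt_base must differ")
  i <- table$pos >= window[1L] & table$pos <= window[2L] &
    table$ref_base == ref_base
  if (!any(i)) {
    warning(sprintf("no %s positions in window [%d, %d]",
                    ref_base, window[1L], window[2L]), call. = FALSE)
    return(NA_real_)
  }
  denom <- sum(table$matches[i] + table$mismatches[i])
  if (denom == 0) {
    warning("no calls at window positions; frequency undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(table[[paste0("count_", alt_base)]][i]) / denom
}

#' Compare window frequencies between replicate groups
#'
#' With exactly two groups, an unpaired two-sided t-test (Student's
#' equal-variance by default, Welch behind a flag). With more than two
#' groups a designated control is required: a one-way ANOVA is fitted and
#' each non-control group is compared against the control with Dunnett's
#' multiple comparisons (multivariate-t adjustment). Groups with fewer
#' than 2 replicates yield descriptive output only; zero within-group
#' variance with separated means raises the `exact_separation` flag
#' instead of a p-value.
#'
#' @param groups Named list of numeric replicate vectors.
#' @param control Name of the control group (required for > 2 groups).
#' @param welch Logical; Welch t-test for the two-group case.
#' @return An object of class `window_comparison`: list with `method`,
#'   `means`, `comparisons` (data frame: contrast, diff, stat, df, p) and
#'   `exact_separation`.
#' @export
compare_windows <- function(groups, control = NULL, welch = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  small <- vapply(groups, length, integer(1)) < 2L
  if (any(small)) {
    return(structure(list(method = "descriptive", means = means,
                          comparisons = NULL, exact_separation = FALSE),
                     class = "window_comparison"))
  }
  vars <- vapply(groups, stats::var, numeric(1))
  if (length(groups) == 2L) {
    d <- means[2L] - means[1L]
    if (all(vars == 0)) {
      if (d == 0) {
        cmp <- data.frame(contrast = paste(names(groups)[2L], "-",
                                           names(groups)[1L]),
                          diff = 0, stat = 0,
                          df = sum(lengths(groups)) - 2L, p = 1)
        return(structure(list(method = "t", means = means, comparisons = cmp,
                              exact_separation = FALSE),
                         class = "window_comparison"))
      }
      return(structure(list(method = "t", means = means, comparisons = NULL,
                            exact_separation = TRUE),
                       class = "window_comparison"))
    }
    tt <- stats::t.test(groups[[2L]], groups[[1L]], var.equal = !welch)
    cmp <- data.frame(contrast = paste(names(groups)[2L], "-", names(groups)[1L]),
                      diff = d, stat = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value)
    return(structure(list(method = if (welch) "welch" else "t",
                          means = means, comparisons = cmp,
                          exact_separation = FALSE),
                     class = "window_comparison"))
  }
  if (is.null(control) || !control %in% names(groups))
    stop("a control group name is required for more than two groups")
  if (all(vars == 0)) {
    sep <- any(means != means[control])
    return(structure(list(method = "dunnett", means = means,
                          comparisons = NULL, exact_separation = sep),
                     class = "window_comparison"))
  }
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups), lengths(groups)),
                                  levels = c(control,
                                             setdiff(names(groups), control))))
  fit <- stats::aov(value ~ group, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
  sm <- summary(gl)
  cmp <- data.frame(contrast = names(sm$test$coefficients),
                    diff = unname(sm$test$coefficients),
                    stat = unname(sm$test$tstat),
                    df = stats::df.residual(fit),
                    p = unname(sm$test$pvalues))
  structure(list(method = "dunnett", means = means, comparisons = cmp,
                 anova_F = unname(summary(fit)[[1L]][["F value"]][1L]),
                 exact_separation = FALSE),
            class = "window_comparison")
}

#' @export
print.window_comparison <- function(x, ...) {
  cat(sprintf("<window_comparison> method: %s\n", x$method))
  cat("  group means:",
      paste(sprintf("%s=%.4g", names(x$means), x$means), collapse = " "), "\n")
  if (isTRUE(x$exact_separation))
    cat("  zero within-group variance with separated means (no p-value)\n")
  else if (!is.null(x$comparisons)) {
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
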