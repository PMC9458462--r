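# Builders and independent oracles shared across tests. Oracles are
# written naively (per-row recounts, brute-force scans) on purpose: they
# must not share code paths with the implementation they check.

make_random_pileup <- function(n_pos, seed, max_count = 50L,
                               p_zero_coverage = 0.05) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "U"), n_pos, replace = TRUE)
  counts <- matrix(sample(0:max_count, 4L * n_pos, replace = TRUE),
                   ncol = 4L, dimnames = list(NULL, c("A", "C", "G", "U")))
  zero <- runif(n_pos) < p_zero_coverage
  counts[zero, ] <- 0L
  pileup_table(ref_id = "fuzz", pos = seq_len(n_pos), ref_base = bases,
               count_A = counts[, "A"], count_C = counts[, "C"],
               count_G = counts[, "G"], count_U = counts[, "U"])
}

# Independent per-row recount of substitution frequencies and per-base
# accuracies (no shared code with substitution_profile()).
naive_profile <- function(tab) {
  bases <- c("A", "C", "G", "U")
  freq <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cnt <- c(tab$count_A[i], tab$count_C[i], tab$count_G[i], tab$count_U[i])
    total <- sum(cnt)
    m <- cnt[match(tab$ref_base[i], bases)]
    freq[i] <- if (total > 0) 100 * (total - m) / total else NA_real_
  }
  acc <- sapply(bases, function(b) {
    f <- freq[tab$ref_base == b]
    f <- f[!is.na(f)]
    if (!length(f)) NA_real_ else 100 - sum(f) / length(f)
  })
  list(freq = freq, accuracy = acc)
}

# Brute-force first qualifying window: try every start.
brute_force_window <- function(depths, window_len, min_depth) {
  L <- length(depths)
  if (window_len > L) return(NULL)
  for (s in 1:(L - window_len + 1L)) {
    if (all(depths[s:(s + window_len - 1L)] >= min_depth))
      return(c(start = s, end = s + window_len - 1L))
  }
  NULL
}

make_gaussian_trace <- function(centers, widths, heights, baseline = 0,
                                n_points = 400L, xlim = NULL) {
  if (is.null(xlim)) xlim <- c(min(centers) - 5 * max(widths),
                               max(centers) + 5 * max(widths))
  x <- seq(xlim[1L], xlim[2L], length.out = n_points)
  y <- rep(baseline, n_points)
  for (k in seq_along(centers))
    y <- y + heights[k] * exp(-(x - centers[k])^2 / (2 * widths[k]^2))
  profile_trace(x, y)
}
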