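# Substitution statistics: forced arithmetic, hand-count oracles, the
# naive-recount equivalence, partition and tally-conservation properties.

test_that("substitution_frequency handles boundaries and degenerate input", {
  expect_equal(substitution_frequency(90, 10), 10)
  expect_equal(substitution_frequency(0, 5), 100)
  expect_true(is.na(substitution_frequency(0, 0)))
  expect_error(substitution_frequency(-1, 2), "non-negative")
  # complement identity at every defined position
  m <- c(10, 3, 0); mm <- c(5, 0, 9)
  expect_equal(substitution_frequency(m, mm) + 100 * m / (m + mm),
               rep(100, 3), tolerance = 1e-9)
})

test_that("profile of an all-match table is trivial", {
  tab <- pileup_table("r", 1:4, c("A", "C", "G", "U"),
                      count_A = c(10, 0, 0, 0), count_C = c(0, 10, 0, 0),
                      count_G = c(0, 0, 10, 0), count_U = c(0, 0, 0, 10))
  prof <- substitution_profile(tab)
  expect_true(all(prof$by_position$freq == 0))
  expect_true(all(prof$per_base_accuracy == 100))
})

test_that("hand-built table reproduces hand-counted frequencies and accuracy", {
  # two A positions (one with 1 mismatch in 10 calls), one C, one G
  tab <- pileup_table("r", 1:4, c("A", "A", "C", "G"),
                      count_A = c(9, 10, 0, 0), count_C = c(0, 0, 10, 0),
                      count_G = c(1, 0, 0, 10), count_U = c(0, 0, 0, 0))
  prof <- substitution_profile(tab)
  expect_equal(prof$by_position$freq, c(10, 0, 0, 0))
  # A accuracy: 100 - mean(10, 0) over its 2 positions
  expect_equal(unname(prof$per_base_accuracy["A"]), 95)
  expect_equal(unname(prof$per_base_accuracy["C"]), 100)
  expect_true(is.na(prof$per_base_accuracy["U"]))
})

test_that("profile agrees exactly with a naive per-row recount", {
  for (seed in 1:20) {
    tab <- make_random_pileup(sample(5:50, 1), seed = seed)
    prof <- substitution_profile(tab)
    oracle <- naive_profile(tab)
    expect_equal(prof$by_position$freq, oracle$freq)
    expect_equal(prof$per_base_accuracy, oracle$accuracy)
  }
})

test_that("class frequencies are forced by counts and partition the total", {
  tab <- pileup_table("r", 1:2, c("A", "A"),
                      count_A = c(95, 90), count_C = c(0, 4),
                      count_G = c(5, 6), count_U = c(0, 0))
  ag <- class_frequency(tab, "A", "G")
  expect_equal(ag$by_position$freq, c(5, 6))
  expect_equal(ag$mean, 5.5)
  expect_equal(class_frequency(tab, "A", "C")$by_position$freq, c(0, 4))
  # no positions of the requested reference base: empty, not an error
  empty <- class_frequency(tab, "U", "G")
  expect_equal(nrow(empty$by_position), 0L)
  expect_true(is.na(empty$mean))
  expect_error(class_frequency(tab, "A", "A"), "differ")

  # partition identity on fuzzed tables: sum over alt bases equals the total
  for (seed in 21:30) {
    tab <- make_random_pileup(30, seed = seed)
    freq <- substitution_profile(tab)$by_position$freq
    for (b in c("A", "C", "G", "U")) {
      i <- tab$ref_base == b
      if (!any(i)) next
      alts <- setdiff(c("A", "C", "G", "U"), b)
      parts <- Reduce(`+`, lapply(alts, function(a)
        class_frequency(tab, b, a)$by_position$freq))
      expect_equal(parts, freq[i])
    }
  }
})

test_that("depth-weighted accuracy variant weights by calls", {
  tab <- pileup_table("r", 1:2, c("A", "A"),
                      count_A = c(9, 900), count_C = c(1, 0),
                      count_G = c(0, 100), count_U = c(0, 0))
  # unweighted: mean(10, 10) -> 90; weighted: same here
  expect_equal(unname(substitution_profile(tab)$per_base_accuracy["A"]), 90)
  tab2 <- pileup_table("r", 1:2, c("A", "A"),
                       count_A = c(9, 1000), count_C = c(1, 0),
                       count_G = c(0, 0), count_U = c(0, 0))
  # unweighted mean(10, 0) = 5; weighted 1/1010 * 100
  expect_equal(unname(substitution_profile(tab2)$per_base_accuracy["A"]), 95)
  expect_equal(
    unname(substitution_profile(tab2, depth_weighted = TRUE)$per_base_accuracy["A"]),
    100 - 100 * 1 / 1010)
})

test_that("delta profile tallies and excludes undefined positions", {
  tab <- make_random_pileup(40, seed = 99, p_zero_coverage = 0.2)
  prof <- substitution_profile(tab)
  d_same <- delta_profile(prof, prof)
  expect_equal(d_same$n_ties, nrow(d_same$by_position))
  expect_true(all(d_same$by_position$delta == 0))

  # control all 0, treated all 2 -> everything enriched in treated
  t0 <- pileup_table("r", 1:5, rep("A", 5), count_A = rep(100, 5),
                     count_C = 0, count_G = 0, count_U = 0)
  t2 <- pileup_table("r", 1:5, rep("A", 5), count_A = rep(98, 5),
                     count_C = 0, count_G = rep(2, 5), count_U = 0)
  d <- delta_profile(substitution_profile(t0), substitution_profile(t2))
  expect_equal(d$n_enriched_treated, 5L)
  expect_equal(d$n_enriched_control, 0L)

  # mismatched references
  ta <- substitution_profile(make_random_pileup(10, seed = 1))
  tb <- substitution_profile(make_random_pileup(10, seed = 2))
  tb$ref_id <- "other"
  expect_error(delta_profile(ta, tb), "different references")
})

test_that("tie epsilon widens the tie band", {
  t0 <- pileup_table("r", 1:2, c("A", "A"), count_A = c(999, 999),
                     count_C = 0, count_G = c(1, 1), count_U = 0)
  t1 <- pileup_table("r", 1:2, c("A", "A"), count_A = c(998, 999),
                     count_C = 0, count_G = c(2, 1), count_U = 0)
  d0 <- delta_profile(substitution_profile(t0), substitution_profile(t1))
  expect_equal(d0$n_enriched_treated, 1L)
  d1 <- delta_profile(substitution_profile(t0), substitution_profile(t1),
                      tie_epsilon = 0.5)
  expect_equal(d1$n_ties, 2L)
})

test_that("fold change is a guarded ratio", {
  expect_equal(fold_change(4, 2), 2)
  expect_equal(fold_change(0, 2), 0)
  expect_true(is.na(fold_change(1, 0)))
  expect_equal(fold_change(c(4, 0, 1), c(2, 2, 0)), c(2, 0, NA))
})

test_that("accuracy hierarchy sorts, breaks ties alphabetically and warns on gaps", {
  prof <- list(per_base_accuracy = c(A = 98, C = 96.5, G = 97, U = 96))
  class(prof) <- "substitution_profile"
  h <- accuracy_hierarchy(prof)
  expect_equal(as.character(h), c("A", "G", "C", "U"))
  expect_false(attr(h, "ties"))

  prof$per_base_accuracy <- c(A = 97, C = 97, G = 97, U = 97)
  h <- accuracy_hierarchy(prof)
  expect_equal(as.character(h), c("A", "C", "G", "U"))
  expect_true(attr(h, "ties"))

  prof$per_base_accuracy <- c(A = 98, C = 97, G = 96, U = NA)
  expect_warning(h <- accuracy_hierarchy(prof), "partial")
  expect_equal(as.character(h), c("A", "C", "G"))
})
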