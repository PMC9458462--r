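# Generators: determinism, analytic rate conservation, compositional
# bias, readout separability, and agreement with binomial/closed-form
# oracles at small scale.

test_that("gen_transcript is deterministic and honours base probabilities", {
  a <- gen_transcript(1650, seed = 3)
  b <- gen_transcript(1650, seed = 3)
  expect_identical(a, b)
  expect_equal(a$length, 1650L)

  only_a <- gen_transcript(10, base_probs = c(A = 1, C = 0, G = 0, U = 0),
                           seed = 1)
  expect_equal(only_a$seq, strrep("A", 10))

  expect_error(gen_transcript(0), ">= 1")
  # composition approaches the sampling probabilities
  long <- gen_transcript(20000, base_probs = c(A = 0.4, C = 0.3, G = 0.2,
                                               U = 0.1), seed = 9)
  expect_equal(unname(long$base_fractions), c(0.4, 0.3, 0.2, 0.1),
               tolerance = 0.02)
})

test_that("misincorporation model conserves the overall rate analytically", {
  for (seed in 1:5) {
    ref <- gen_transcript(500, base_probs = c(A = 0.3, C = 0.2, G = 0.35,
                                              U = 0.15), seed = seed)
    model <- misincorporation_model(1 / 185)
    p <- per_base_inosine_prob(model, ref)
    expect_equal(sum(ref$base_fractions * p), 1 / 185, tolerance = 1e-12)
    # compositional bias follows the configured hierarchy G>C>A>U
    expect_true(p[["G"]] > p[["C"]] && p[["C"]] > p[["A"]] &&
                  p[["A"]] > p[["U"]])
  }
  expect_error(misincorporation_model(1.2), "overall_rate")
  expect_error(misincorporation_model(0.01, c(A = 1, C = 1, G = 0, U = 1)),
               "> 0")
})

test_that("simulate_molecules matches the binomial oracle", {
  ref <- gen_transcript(1650, seed = 2)
  # null model
  inc0 <- simulate_molecules(ref, misincorporation_model(0), 100, seed = 1)
  expect_true(all(inc0$counts == 0))
  # support constraint: near-total G weighting puts inosine (almost) only at G
  mG <- misincorporation_model(0.01, c(G = 1, C = 1e-12, A = 1e-12, U = 1e-12))
  incG <- simulate_molecules(ref, mG, 2000, seed = 2)
  bases <- strsplit(ref$seq, "")[[1]]
  expect_true(all(incG$counts[bases != "G"] == 0))
  # rate conservation within 3 binomial SE (total inosine over all bases)
  rate <- 1 / 185
  n_mol <- 600L
  inc <- simulate_molecules(ref, misincorporation_model(rate), n_mol, seed = 3)
  n_trials <- n_mol * ref$length
  se <- sqrt(rate * (1 - rate) / n_trials)
  expect_lt(abs(sum(inc$counts) / n_trials - rate), 3 * se)
})

test_that("simulate_pileup null case and binomial expectation", {
  ref <- gen_transcript(60, seed = 4)
  quiet <- readout_model("short_read", background_miscall = 0)
  p0 <- simulate_pileup(ref, rep(0, 60), quiet, depth = 50, seed = 1)
  expect_true(all(p0$mismatches == 0))
  expect_true(all(substitution_profile(p0)$per_base_accuracy == 100,
                  na.rm = TRUE))

  # short_read, background 0: expected count_G = f * d at an A position
  refA <- transcript_ref("a", strrep("A", 200))
  f <- 0.1; d <- 400L
  tab <- simulate_pileup(refA, rep(f, 200), quiet, depth = d, seed = 2)
  se <- sqrt(f * (1 - f) / (200 * d))
  expect_lt(abs(mean(tab$count_G / d) - f), 3 * se)
  # readout separability: every mismatch is a G call
  expect_equal(tab$mismatches, tab$count_G)
  expect_true(all(tab$count_C == 0) && all(tab$count_U == 0))
})

test_that("direct-RNA background reproduces the 96-98% accuracy band", {
  ref <- gen_transcript(800, seed = 6)
  tab <- simulate_pileup(ref, rep(0, 800), readout_model("direct_rna"),
                         depth = 400, seed = 7)
  acc <- substitution_profile(tab)$per_base_accuracy
  expect_true(all(acc > 96 & acc < 98))
  expect_equal(unname(mean(acc)), 97, tolerance = 0.01)
})

test_that("two-condition simulation is deterministic and ordered", {
  s1 <- simulate_two_condition(depth = 60, length = 120, seed = 10)
  s2 <- simulate_two_condition(depth = 60, length = 120, seed = 10)
  expect_identical(s1, s2)

  # exchangeable rates give a delta centred on zero
  s0 <- simulate_two_condition(rate_control = 0, rate_treated = 0,
                               depth = 200, length = 400, seed = 11)
  d0 <- delta_profile(substitution_profile(s0$control),
                      substitution_profile(s0$treated))
  expect_lt(abs(mean(d0$by_position$delta)), 0.3)

  # treated mean substitution frequency strictly greater under 1/185
  s <- simulate_two_condition(rate_control = 0, rate_treated = 1 / 185,
                              depth = 200, length = 400, seed = 12)
  expect_gt(mean(substitution_profile(s$treated)$by_position$freq),
            mean(substitution_profile(s$control)$by_position$freq))
})

test_that("mean substitution frequency is non-decreasing in the configured rate", {
  rates <- c(0, 1 / 2000, 1 / 500, 1 / 185, 1 / 80)
  means <- vapply(rates, function(r) {
    s <- simulate_two_condition(rate_control = 0, rate_treated = r,
                                depth = 300, length = 300, seed = 42)
    mean(substitution_profile(s$treated)$by_position$freq)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("simulate_ms reproduces the analytic level and noise scale", {
  # noiseless replicates equal the analytic level exactly
  expect_equal(simulate_ms(1 / 500, 0.25, sd = 0, n = 3), rep(8000, 3))
  # printed cellular rate: 1 in 9037 at f_A 0.2504 corresponds to ~442
  expect_equal(simulate_ms(1 / 9037, 0.2504, sd = 0, n = 1), 442,
               tolerance = 1e-3)
  # sample SD recovers the configured noise within sampling error
  x <- simulate_ms(1 / 9037, 0.25, sd = 25, n = 400, seed = 8)
  se_sd <- 25 / sqrt(2 * (400 - 1))
  expect_lt(abs(sd(x) - 25), 3 * se_sd)
  expect_error(simulate_ms(0.01, 0), "f_A")
})

test_that("polysome trace generator matches closed-form Gaussians", {
  tr <- simulate_polysome_trace(data.frame(center = 0, width = 1, height = 1),
                                n_points = 2001, xlim = c(-8, 8))
  expect_equal(max(tr$absorbance), 1, tolerance = 1e-6)
  # trapezoid AUC over a wide window matches h * sigma * sqrt(2*pi) within 1%
  expect_equal(auc(tr, c(-6, 6)), sqrt(2 * pi), tolerance = 0.01)
  # determinism with noise
  t1 <- simulate_polysome_trace(data.frame(center = 0, width = 1, height = 1),
                                noise_sd = 0.05, n_points = 50, seed = 3)
  t2 <- simulate_polysome_trace(data.frame(center = 0, width = 1, height = 1),
                                noise_sd = 0.05, n_points = 50, seed = 3)
  expect_identical(t1, t2)
  expect_error(simulate_polysome_trace(data.frame(center = 0, width = 1,
                                                  height = 1), n_points = 5),
               ">= 10")
})
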