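# Synthetic-data generator: transcripts, inosine-containing molecule
# populations, sequencing pileups (direct-RNA or short-read readout),
# mass-spec levels and polysome traces with the statistical structure the
# downstream analyses assume. All generators take an explicit seed and are
# byte-reproducible; seeds for compound simulations are derived from a
# single master seed by fixed offsets.

#' Stochastic misincorporation model
#'
#' Inosine replaces template bases independently (per molecule, per
#' position). `overall_rate` is the expected fraction of inosine over all
#' bases; `template_weights` give the relative propensity for inosine to
#' replace each template base (hierarchy G>C>A>U by default). Per-base
#' probabilities are normalized against a transcript's composition so the
#' composition-weighted mean equals `overall_rate` exactly, making the rate
#' directly comparable with "1 in N bases" figures.
#'
#' @param overall_rate Probability of inosine per transcribed base
#'   (e.g. `1/185`).
#' @param template_weights Named positive weights for A, C, G, U. The
#'   default `c(G = 1, C = 0.6, A = 0.35, U = 0.25)` encodes the
#'   qualitative G>C>A>U hierarchy; any strictly positive vector works.
#' @return An object of class `misincorporation_model`.
#' @export
misincorporation_model <- function(overall_rate,
                                   template_weights = c(G = 1, C = 0.6,
                                                        A = 0.35, U = 0.25)) {
  if (!is_scalar_number(overall_rate) || overall_rate < 0 || overall_rate >= 1)
    stop("overall_rate must be in [0, 1)")
  if (!all(RNA_BASES %in% names(template_weights)))
    stop("template_weights must name all of A, C, G, U")
  template_weights <- template_weights[RNA_BASES]
  if (any(template_weights <= 0)) stop("template_weights must be > 0")
  structure(list(overall_rate = overall_rate,
                 template_weights = template_weights),
            class = "misincorporation_model")
}

#' Per-template-base inosine probabilities for a reference
#'
#' Probability that a given position with template base `b` carries inosine
#' in a random molecule: `overall_rate * w(b) / sum_b f_b * w(b)` where
#' `f_b` is the reference base composition. The composition-weighted mean
#' of these probabilities equals `overall_rate` analytically.
#'
#' @param model A [misincorporation_model()].
#' @param ref A [transcript_ref()].
#' @return Named probabilities for A, C, G, U.
#' @export
per_base_inosine_prob <- function(model, ref) {
  w <- model$template_weights
  f <- ref$base_fractions[RNA_BASES]
  p <- model$overall_rate * w / sum(f * w)
  if (any(p > 1))
    stop(sprintf("overall_rate %.4g implies per-base probability > 1 for base %s",
                 model$overall_rate, names(p)[which.max(p)]))
  p
}

#' Readout (base-calling) model for pileup simulation
#'
#' In `direct_rna` mode a canonical base is miscalled with probability
#' `background_miscall` (uniform over the three other bases), and an
#' inosine position is miscalled with probability `inosine_miscall`, with
#' called-base probabilities `alt_call` renormalized to exclude the
#' template base. In `short_read` mode inosine is read out as guanosine
#' with probability 1 (it pairs with cytosine during reverse
#' transcription), on top of the background error.
#'
#' @param mode `"direct_rna"` or `"short_read"`.
#' @param background_miscall Background miscall probability per call;
#'   defaults to 0.03 for direct RNA (a 2--4% raw error band) and 0.001
#'   for short reads.
#' @param inosine_miscall Probability an inosine position is called as a
#'   non-template base (direct RNA only).
#' @param alt_call Called-base distribution at miscalled inosine positions
#'   before excluding the template base.
#' @return An object of class `readout_model`.
#' @export
readout_model <- function(mode = c("direct_rna", "short_read"),
                          background_miscall = NULL,
                          inosine_miscall = 0.85,
                          alt_call = c(G = 0.5, C = 0.25, A = 0.15, U = 0.10)) {
  mode <- match.arg(mode)
  if (is.null(background_miscall))
    background_miscall <- if (mode == "direct_rna") 0.03 else 0.001
  stopifnot(background_miscall >= 0, background_miscall <= 1,
            inosine_miscall >= 0, inosine_miscall <= 1)
  if (!all(RNA_BASES %in% names(alt_call)))
    stop("alt_call must name all of A, C, G, U")
  alt_call <- alt_call[RNA_BASES]
  if (any(alt_call < 0) || sum(alt_call) <= 0)
    stop("alt_call must be a non-negative distribution")
  alt_call <- alt_call / sum(alt_call)
  structure(list(mode = mode, background_miscall = background_miscall,
                 inosine_miscall = inosine_miscall, alt_call = alt_call),
            class = "readout_model")
}

#' Generate a random transcript reference
#'
#' @param length Positive transcript length in nt (the in vitro system uses
#'   a 1650-nt luciferase transcript).
#' @param base_probs Named sampling probabilities for A, C, G, U (sum 1).
#' @param seed Integer seed; fixed seed gives an identical sequence.
#' @param id Record id.
#' @return A [transcript_ref()].
#' @export
gen_transcript <- function(length, base_probs = c(A = 0.25, C = 0.25,
                                                  G = 0.25, U = 0.25),
                           seed = 1L, id = "synthetic_transcript") {
  if (!is_scalar_number(length) || length < 1) stop("length must be >= 1")
  if (!all(RNA_BASES %in% names(base_probs)))
    stop("base_probs must name all of A, C, G, U")
  base_probs <- base_probs[RNA_BASES]
  if (abs(sum(base_probs) - 1) > 1e-8) stop("base_probs must sum to 1")
  seq <- with_seed(seed,
    paste(sample(RNA_BASES, length, replace = TRUE, prob = base_probs),
          collapse = ""))
  transcript_ref(id, seq)
}

#' Simulate inosine placement across a molecule population
#'
#' Each of `n_molecules` transcript copies carries independent Bernoulli
#' inosine substitutions with the per-template-base probabilities implied
#' by the model. Returns per-position incidence counts.
#'
#' @param ref A [transcript_ref()].
#' @param model A [misincorporation_model()].
#' @param n_molecules Number of molecules.
#' @param seed Integer seed.
#' @return An object of class `inosine_incidence`: list with `ref_id`,
#'   `counts` (inosine-bearing molecules per position), `n_molecules` and
#'   `fraction` (`counts / n_molecules`).
#' @export
simulate_molecules <- function(ref, model, n_molecules, seed = 1L) {
  if (!is_scalar_number(n_molecules) || n_molecules < 1)
    stop("n_molecules must be >= 1")
  p <- per_base_inosine_prob(model, ref)
  bases <- strsplit(ref$seq, "", fixed = TRUE)[[1L]]
  pv <- p[bases]
  counts <- with_seed(seed, stats::rbinom(ref$length, n_molecules, pv))
  structure(list(ref_id = ref$id, counts = counts,
                 n_molecules = n_molecules,
                 fraction = counts / n_molecules),
            class = "inosine_incidence")
}

call_distributions <- function(base, frac, readout) {
  ## 4-vector of call probabilities (A,C,G,U) at one position
  i <- match(base, RNA_BASES)
  canonical <- rep(readout$background_miscall / 3, 4L)
  canonical[i] <- 1 - readout$background_miscall
  if (readout$mode == "short_read") {
    ino <- c(0, 0, 0, 0); ino[3L] <- 1  # inosine read as G
  } else {
    ino <- readout$alt_call
    ino[i] <- 0
    if (sum(ino) > 0) ino <- ino / sum(ino) * readout$inosine_miscall
    ino[i] <- 1 - readout$inosine_miscall
  }
  frac * ino + (1 - frac) * canonical
}

#' Simulate a sequencing pileup over a reference
#'
#' Draws `depth` independent base calls per position from the readout
#' model, mixing inosine-derived and canonical calls according to the
#' per-position inosine incidence.
#'
#' @param ref A [transcript_ref()].
#' @param incidence An `inosine_incidence` from [simulate_molecules()], or
#'   a numeric vector of per-position inosine fractions.
#' @param readout A [readout_model()].
#' @param depth Reads per position (>= 1).
#' @param seed Integer seed.
#' @return A [pileup_table()].
#' @export
simulate_pileup <- function(ref, incidence, readout, depth, seed = 1L) {
  if (!is_scalar_number(depth) || depth < 1) stop("depth must be >= 1")
  frac <- if (inherits(incidence, "inosine_incidence")) incidence$fraction
          else as.numeric(incidence)
  if (length(frac) != ref$length)
    stop("incidence must cover every reference position")
  if (any(frac < 0) || any(frac > 1)) stop("inosine fractions must be in [0, 1]")
  bases <- strsplit(ref$seq, "", fixed = TRUE)[[1L]]
  counts <- with_seed(seed, {
    out <- matrix(0L, nrow = ref$length, ncol = 4L,
                  dimnames = list(NULL, RNA_BASES))
    for (i in seq_len(ref$length)) {
      p <- call_distributions(bases[i], frac[i], readout)
      out[i, ] <- stats::rmultinom(1L, depth, p)[, 1L]
    }
    out
  })
  pileup_table(ref_id = ref$id, pos = seq_len(ref$length), ref_base = bases,
               count_A = counts[, "A"], count_C = counts[, "C"],
               count_G = counts[, "G"], count_U = counts[, "U"])
}

#' Simulate a two-condition sequencing experiment
#'
#' Generates (or reuses) one transcript and produces a control and a
#' treated pileup sharing the reference and readout model but with
#' independent sampling noise and different misincorporation rates (the
#' motivating design: 0 vs 10 mM ITP in the transcription pool). Component
#' seeds are derived from the master seed by fixed offsets, so the same
#' master seed reproduces the pair exactly.
#'
#' @param rate_control,rate_treated Overall misincorporation rates.
#' @param readout A [readout_model()].
#' @param depth Reads per position.
#' @param seed Master seed.
#' @param ref Optional [transcript_ref()]; generated when `NULL`.
#' @param length,base_probs Transcript parameters used when `ref` is `NULL`.
#' @param template_weights Propensity hierarchy passed to
#'   [misincorporation_model()].
#' @param n_molecules Molecule population size per condition.
#' @return List with `ref`, `control` and `treated` pileup tables.
#' @export
simulate_two_condition <- function(rate_control = 0, rate_treated = 1/185,
                                   readout = readout_model("direct_rna"),
                                   depth = 500L, seed = 1L, ref = NULL,
                                   length = 1650L,
                                   base_probs = c(A = 0.25, C = 0.25,
                                                  G = 0.25, U = 0.25),
                                   template_weights = c(G = 1, C = 0.6,
                                                        A = 0.35, U = 0.25),
                                   n_molecules = 10000L) {
  if (is.null(ref))
    ref <- gen_transcript(length, base_probs, seed = seed + 11L)
  sim_one <- function(rate, seed_mol, seed_pile) {
    if (rate == 0) {
      frac <- rep(0, ref$length)
    } else {
      model <- misincorporation_model(rate, template_weights)
      frac <- simulate_molecules(ref, model, n_molecules, seed = seed_mol)
    }
    simulate_pileup(ref, frac, readout, depth, seed = seed_pile)
  }
  list(ref = ref,
       control = sim_one(rate_control, seed + 21L, seed + 22L),
       treated = sim_one(rate_treated, seed + 31L, seed + 32L))
}

#' Simulate replicate mass-spec nucleoside levels
#'
#' Generates IMP-per-10^6-AMP levels around the analytic level implied by a
#' true per-base incorporation rate and the A fraction of the RNA:
#' `level = rate / f_A * 1e6`, with Gaussian measurement noise.
#'
#' @param true_rate Per-base inosine frequency.
#' @param f_A Fraction of A among all bases (0 < f_A < 1).
#' @param sd Measurement noise SD (same units as the level).
#' @param n Number of replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `n` levels (IMP per 10^6 AMP).
#' @export
simulate_ms <- function(true_rate, f_A, sd = 0, n = 3L, seed = 1L) {
  if (!is_scalar_number(f_A) || f_A <= 0 || f_A >= 1)
    stop("f_A must be in (0, 1)")
  if (sd < 0) stop("sd must be >= 0")
  level <- true_rate / f_A * 1e6
  if (sd == 0) return(rep(level, n))
  with_seed(seed, stats::rnorm(n, mean = level, sd = sd))
}

#' Simulate a polysome absorbance trace
#'
#' Sum of Gaussian peaks on a constant baseline, sampled on a regular grid
#' with optional Gaussian noise. With `noise_sd = 0` the trace is the
#' analytic mixture.
#'
#' @param peaks Data frame (or list of length-3 vectors) with columns
#'   `center`, `width` (Gaussian sigma) and `height`.
#' @param baseline Constant baseline absorbance.
#' @param noise_sd Additive noise SD.
#' @param n_points Number of samples (>= 10).
#' @param xlim Trace range; defaults to covering all peaks +/- 5 sigma.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [profile_trace()].
#' @export
simulate_polysome_trace <- function(peaks, baseline = 0, noise_sd = 0,
                                    n_points = 500L, xlim = NULL, seed = 1L) {
  if (!is.data.frame(peaks))
    peaks <- as.data.frame(do.call(rbind, peaks))
  names(peaks) <- c("center", "width", "height")
  if (any(peaks$width <= 0)) stop("peak widths must be > 0")
  if (!is_scalar_number(n_points) || n_points < 10)
    stop("n_points must be >= 10")
  if (is.null(xlim))
    xlim <- c(min(peaks$center - 5 * peaks$width),
              max(peaks$center + 5 * peaks$width))
  x <- seq(xlim[1L], xlim[2L], length.out = n_points)
  y <- rep(baseline, n_points)
  for (k in seq_len(nrow(peaks)))
    y <- y + peaks$height[k] *
      exp(-(x - peaks$center[k])^2 / (2 * peaks$width[k]^2))
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
  profile_trace(x, y)
}
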