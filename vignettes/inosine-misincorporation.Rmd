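---
title: "Quantifying stochastic inosine misincorporation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stochastic inosine misincorporation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inoscan)
```

## The problem

Inosine triphosphate (ITP) is a non-canonical nucleotide normally kept
out of the pool by ITPase. When it accumulates — in vitro by spiking ITP
into a transcription reaction, in vivo by knocking out *Itpa* — RNA
polymerases stochastically incorporate inosine in place of canonical
bases, with a template-base preference ordered G>C>A>U. Inosine in RNA
is invisible to conventional sequencing chemistry as such, but it leaves
two distinct signatures that this package quantifies:

1. **Direct RNA (nanopore) sequencing** basecalls inosine poorly, so
   misincorporation appears as an excess of base substitutions over the
   platform's 2–4% background error, at essentially all positions
   (stochastic placement).
2. **Short-read (cDNA) sequencing** reads inosine as guanosine, because
   inosine pairs with cytosine during reverse transcription. C>G, A>G
   and U>G variant excesses therefore report misincorporation at C, A
   and U; misincorporation at G is masked.

A third, orthogonal readout is LC-MS/MS nucleoside quantification (IMP
per 10⁶ AMP), and the downstream functional readout is polysome
profiling, where reduced translation shows up as a smaller
polysome:(80S&disome) area ratio.

## Substitution statistics

All sequencing statistics operate on per-position pileup tables
(`pileup_table`), with 1-based inclusive coordinates and the RNA
alphabet (DNA `T` is normalized to `U` at every reader boundary). The
denominator everywhere is `matches + mismatches`: deletions and N calls
never enter numerator or denominator. Positions with a zero denominator
are *undefined*, excluded from means and tallies, and counted in a QC
field rather than silently treated as 0.

- `substitution_frequency(m, mm) = 100·mm/(m+mm)`.
- Per-base accuracy is `100 −` the **unweighted** mean of positional
  frequencies over positions sharing a reference base. Whether a
  depth-weighted mean is preferable is a genuinely open choice; both are
  provided (`depth_weighted = TRUE`), unweighted is the default because
  the quantity is conventionally an average of per-position values.
- `delta_profile()` tallies enriched positions by the sign of
  `treated − control`. `tie_epsilon` (default 0, exact ties only) exists
  because floating-point deltas essentially never tie once real noise is
  present, but exchangeable inputs should not be split arbitrarily.
- `fold_change()` returns `NA` (never an error) on a zero denominator,
  so batch tabulations survive empty controls.

When a pileup TSV's `matches`/`mismatches` columns disagree with its
per-base counts, the strict default refuses the file; lenient mode
(`strict = FALSE`) recomputes both from the per-base counts and warns.
The per-base counts are taken as ground truth because the derived
columns are the ones tools disagree on (e.g. whether deletions count).

## The candidate-window analysis

`find_window()` implements "the first contiguous 1 kb stretch from the
5′ end with ≥ 50× depth": every position in the window must meet the
threshold (`rule = "pointwise"`). We read "continuous … read depth
stretch" as a pointwise requirement; a mean-depth alternative
(`rule = "mean"`) is available. When several windows qualify the first
(5′-most) is returned; how overlapping candidates were originally
handled is not specified anywhere we could anchor, so the first-window
rule is our documented choice. Window class frequencies pool counts
across the window before dividing — this equals the depth-weighted mean
of positional frequencies (an identity the tests assert) and is more
stable at modest depth than averaging percentages.

Group comparison (`compare_windows()`) uses a two-sided unpaired t-test
for two groups and, for a panel of genes against a shared control, a
one-way ANOVA with Dunnett's multiple comparisons (multivariate-t
adjustment via `multcomp`). Equal variances are assumed by default, with
Welch behind a flag. Degenerate inputs are handled explicitly: fewer
than two replicates yields descriptive output only, and zero
within-group variance with separated means sets an `exact_separation`
flag instead of fabricating a p-value.

## Mass-spec conversions

IMP levels are reported per 10⁶ AMP, so converting to a per-all-bases
frequency requires the A fraction of the RNA:

`freq = level · 10⁻⁶ · f_A`, and `N = round(1/freq)`.

Nearest-integer rounding of the denominator is deliberate: it
reproduces the published "1 in N" figures from their printed inputs
where floor or ceiling do not. For a defined in vitro transcript `f_A`
comes from the sequence (`a_fraction()`); for total RNA the
transcriptome-wide A fraction is unknown, so we calibrate it from any
measured (level, denominator) pair (`calibrate_f_A()`) rather than
assuming 0.25. Reconstructions from printed, rounded means can be off
by ±2 in the denominator; the packaged reference table
(`inst/extdata/ms_reference_levels.csv`) is tested at that tolerance,
and all its pairs imply `f_A` between 0.249 and 0.253.

Calibration curves use weighted least squares with weights `1/x`
(`weighted_linear_fit()`, via `lm`), the standard choice when response
noise grows with concentration; the tests verify both exact-line
recovery and agreement with a numeric minimizer of the weighted
objective, and a Monte-Carlo check that the weighting lowers slope
variance when noise SD grows like √x.

## Polysome quantification

The pipeline (`translation_ratio()`) follows the trace-geometry
conventions of gradient profiling:

1. **Normalization** subtracts the minimum absorbance between the 40S
   and 60S apexes from the whole trace. We read "normalized according to
   the lowest point" as subtraction, not division — subtraction makes
   empty-region areas ≈ 0, which is what a baseline correction should
   do; a division variant would change the ratio's meaning.
2. **Boundaries** sit at the argmin between adjacent apexes (leftmost on
   ties, deterministically). No rule exists for the trailing edge of the
   merged 80S&disome peak, so we search a symmetric span mirroring the
   60S→apex distance; this is a documented package choice, exposed via
   the landmark geometry rather than asserted as the original authors'.
3. The **polysome region** starts at that trailing boundary and spans
   `factor ×` the 60S→80S&disome apex distance, `factor = 1.42` by
   default. The factor is an exposed parameter; its anchoring (start
   point, apex-to-apex distance) is our interpretation of a
   "distance fixed proportionate to" rule and is configurable.
4. **Areas** use the composite trapezoid rule with linear interpolation
   at interval endpoints, which makes `auc()` exactly additive over
   abutting intervals (asserted to 1e-9).

Monotone traces with no valley between the stated apexes are rejected as
landmark/trace inconsistencies rather than producing arbitrary
boundaries. Replicate ratios are compared with an unpaired two-tailed
Student's t-test (equal variance; whether Welch was originally used is
unstated, so equal-variance is the default and Welch a flag).

## What the generator emulates — and what it does not

`simulate_two_condition()` and its components emulate the study design
the analyses assume: a 1650-nt uniform-composition transcript, Bernoulli
inosine placement per molecule with template weights
`{G: 1, C: 0.6, A: 0.35, U: 0.25}` (an invented strictly ordered vector
encoding the qualitative G>C>A>U hierarchy; any positive ordered vector
is accepted), per-base probabilities normalized against the transcript
composition so the composition-weighted mean equals the configured
overall rate exactly, and two readout models:

- `direct_rna`: 3% background miscall (uniform over the three other
  bases), and at inosine positions an 85% miscall probability with an
  alt-call distribution `{G: 0.5, C: 0.25, A: 0.15, U: 0.10}`
  (renormalized to exclude the template base). These inosine-channel
  numbers are placeholders for testing: no quantitative pore emission
  model for inosine is available, so only qualitative conclusions
  (enrichment direction, which base degrades most) should be read off
  simulations.
- `short_read`: inosine is read as G with probability 1, plus a small
  (default 0.001) background error.

The generator deliberately collapses molecules at the pileup stage: per
position, incidence is a fraction and read calls are drawn i.i.d. Read
length distributions, along-molecule correlation, alignment artifacts,
basecaller Q-score behaviour and polyadenylation effects are *not*
modelled — the downstream statistics are positionwise, so none of these
affect what the tests can legitimately claim. Passing tests demonstrate
the statistics are computed correctly and respond to misincorporation
in the configured direction; they do not validate the error model of
any real instrument.

All generators take explicit seeds and are byte-reproducible; compound
simulations derive component seeds from one master seed by fixed small
offsets.

## Numerical and scale choices

Test and simulation sizes are chosen to make sampling-based assertions
sharp while keeping the suite quick: oracle-equivalence tables use ≤ 50
positions (exact agreement required); parameter recovery uses depth
10⁴ over a 300-nt transcript across 5 seeds with a 3-standard-error
band; the two-condition enrichment check uses the full 1650-nt scale at
500× depth with a one-sided binomial test at p < 0.01; window-scan and
boundary fuzzing use 1000 random cases each against brute-force scans;
the weighted-fit/optimizer comparison uses 100 random problems at 1e-6.
Statistical tolerances are stated as multiples of analytic standard
errors rather than free constants wherever a sampling distribution is
known.

## Known limitations

- The short-read arm operates on supplied per-gene transcript
  references; there is no gene-model (GTF) handling or genome-wide
  variant calling.
- VCF handling is deliberately minimal (CHROM/POS/REF/ALT/QUAL;
  multi-allelic splitting; missing QUAL → 0 with a flag so a Q ≥ 20
  filter conservatively drops it). INFO/FORMAT are ignored.
- Per-position statistics impose no depth filter at the reader; depth
  gating is a downstream, explicit step (`find_window()`).
- The direct-RNA inosine alt-call distribution is not calibrated to any
  instrument; treat simulated accuracies as qualitative.
- Landmark apexes for polysome traces are user-supplied; there is no
  automatic landmark-free peak calling.
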