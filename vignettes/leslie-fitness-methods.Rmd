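---
title: "Leslie-matrix fitness from vial assays: models, choices and limits"
author: "flyfitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leslie-matrix fitness from vial assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyfitness)
```

This vignette is the package's own account of its science: the models it
fits, the conventions and tunable parameters behind them, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one defensible option existed.

## From counts to vital rates

The unit of observation is a vial of monoassociated female flies followed
through 8 twice-weekly egg-laying measures over 4 weeks. Each measure
provides a pupae count from an 18-hour laying window and the interval's
mortality bookkeeping. Two record-level rules convert these to per-class
vital rates.

**Fecundity.** The window count is normalised to the females alive at the
start of the window and extrapolated linearly from the window to the full
3- or 4-day class: `f = (pupae/females) × (24·class_days)/window_hours`.
The linear-rate extrapolation treats the 18-h laying rate as representative
of the whole class; `extrapolation = "raw"` is available for analyses that
prefer the unscaled per-female window count, since the raw-count reading of
the protocol cannot be excluded. The rate convention is the default because
the per-day fecundity framing of the assay (offspring per female per day)
is a rate throughout.

**Survival.** Flies lost during transfers are censored, and the default
treats the loss as non-informative: `s = (n − deaths − lost)/(n − lost)`,
removing lost flies from numerator and denominator alike. The alternative
(`censoring = "deaths"`) counts losses as deaths and gives a conservative
lower bound on `s`. With per-transfer loss rates near 1% the two differ
negligibly; the choice matters only for vials with heavy handling losses.

**Contamination.** A vial is dropped from *all* analyses when its weekly F1
monitoring shows ≥ 200 CFU per fly of an unexpected colony morphology in
two consecutive weeks; both the threshold and the run length are arguments,
and `threshold = Inf` disables the filter.

## The Leslie matrix and its boundary conventions

Fecundities go across the first row, survival fractions on the
subdiagonal. The wording "across the diagonal" that sometimes describes
this construction is implemented as the *subdiagonal*: a true-diagonal
placement would let a class persist in place, which is not an age-structured
model — after one class length, a fly is in the next age class or dead.

Three boundary conventions frame the measured classes:

1. a pre-adult class with `f = 0` and `s = 1` (complete egg-to-adult
   survival assumed, so the female count at the end back-computes the egg
   input);
2. one class per measured interval;
3. a terminal class with `f = 0`, so the matrix does not extrapolate
   never-ending low-level reproduction past the experiment.

The third convention is exactly λ-neutral: a trailing `f = 0` class adds a
zero eigenvalue and leaves the dominant root untouched. The test suite
asserts this at 1e-12 (measured drift is ~1e-14). After a cohort goes
extinct, remaining classes keep `f = 0, s = 0` instead of being dropped, so
matrix dimensions stay uniform within an experiment; this too is λ-neutral.

## λ and its independent oracle

Fitness is the dominant eigenvalue, computed by `eigen()`; the
Perron–Frobenius theorem guarantees a real dominant root for a nonnegative
Leslie matrix, and the implementation enforces an imaginary residual below
1e-9 (double-precision eigensolvers on k ≤ 12 matrices sit orders of
magnitude below this). "First eigenvalue" is taken as largest-modulus, the
sorting convention of standard eigenroutines.

The same λ solves the Euler–Lotka equation `Σ l_x f_x λ^(−x) = 1`. The
package's `eulerLotkaLambda()` solves it by bracketed root-finding on the
strictly decreasing left-hand side (bracket grown/shrunk by doubling,
`uniroot` at ~1e-13 relative tolerance) and is used throughout the tests as
an algorithmically independent oracle; the two routes agree to better than
1e-8 relative on hundreds of random schedules. Schedules with no reachable
reproduction (`l_x f_x = 0` for all x) have λ = 0 by convention, matching
the eigenvalue of the all-zero-top-row matrix.

## The perturbation engine

`scaleClass()` multiplies exactly one entry — one class's fecundity, or one
transition's survival — by a factor, leaving everything else bit-identical,
and the factor grid spans reductions by 2 up to 100,000. Indexing is
explicit to avoid an off-by-one trap: survival index *i* scales `s_i`, the
transition *out of* class *i*, so index 1 is the assumed pre-adult
transition and index 2 the first adult (first reproductive) transition.
`permutationGrid()` defaults to class 2, the first reproductive class, the
age class whose perturbation dominates fitness; the fitness-reversal
analysis uses class 1, where a survival collapse rescales every
reproductive term at once. With λ < 1, late reproduction (larger x in
`λ^(−x)`) is discounted *less*, which is why a deep uniform survival
reduction favours late-reproducing (LAB-like) treatments and reverses the
observed AAB-like advantage — the central context-dependence result the
engine reproduces.

Two structural properties follow from the model and are asserted as
invariants: λ responds monotonically to any single vital rate, and a
survival reduction at a class is never outweighed by an equal fecundity
reduction at the same class (the survival entry gates all later classes,
the fecundity entry only its own).

## Treatment statistics

Kruskal–Wallis (base R's tie-corrected implementation) gates a hand-rolled
Dunn post hoc — mean mid-ranks standardised by the tie-corrected pooled
variance, two-sided normal p — with Benjamini–Hochberg adjustment within
each family of pairwise comparisons (one family per analysis). No Dunn
implementation exists among the package's dependencies, so the z statistic
is implemented here and verified against the algebraic identity
`z² = H` for two groups and an independently coded mean-rank computation.
When all observations are identical the tie correction degenerates
(0/0); the package defines `H = 0, p = 1` for that case. Life-span
comparisons use `survival::survdiff` pairwise with BH adjustment. Letter
displays come from the insert-and-absorb algorithm, with letters assigned
in lexicographic group order for deterministic output; the defining law —
two groups share a letter iff not significantly different — is verified
exhaustively over all significance patterns for up to 5 groups. α = 0.05
throughout, configurable. A two-group Wilcoxon wrapper covers the
two-strain contrasts. Two textbook claims were *not* adopted as tests
because they are false in general: BH adjustment is not idempotent (tied
leading values rise on re-adjustment), and a log-rank statistic is not
invariant to appending censored records after the last event time (they
still join earlier risk sets).

## Metagenome-wide association

Ortholog groups sharing an identical strain presence/absence pattern form
one phylogenetic distribution group; only the pattern, not the OG count,
carries information for association. Each testable PDG (pattern with both
present and absent strains after exclusions) is fit with
`λ ~ presence + (1 | experiment)` by REML (`lme4`), Wald p from the normal
reference; Satterthwaite degrees of freedom are available through
`lmerTest` for small-sample caution. The random intercept is the
time-staggered *experiment*, not the vial — vials are the observations.
Bonferroni correction uses the number of testable PDGs. The pathogen-like
strain is excluded by default (as an argument, not hard-coded) because its
fitness values break the normality of the response, which
`shapiroCheck()` logs but never gates on.

Table-style mean fitness (±) columns pool *per-vial* λ across strains
with/without the PDG, matching the per-vial response of the model; a
strain-mean mode is available since the reporting convention is ambiguous.

A caveat the null simulations make explicit: the per-PDG model treats vials
as independent given the experiment. If strains differ in mean fitness for
reasons unrelated to the tested pattern, that clustering is unmodelled and
the test is anti-conservative (no relatedness correction is applied, as in
the original analysis). The type-I-error band [0.03, 0.07] is therefore a
property of the exchangeable null — no strain-level heterogeneity — and the
null simulations set the strain-level standard deviation to zero, while the
recovery simulations keep it at its realistic default.

## The synthetic-data generator

The generator exists so that every stage is testable without the raw assay
data. Its defaults mirror the study design: 15 treatments × 3 staggered
experiments × 3 vials, 30–60 females per vial, 8 measures in alternating
3/4-day classes from day 10, 18-h windows, 1% per-transfer loss.

Each treatment is an archetype with a gamma-kernel daily fecundity curve
`m(t) = A (t/p)^g exp(g(1 − t/p))` — unimodal, mode at the peak day `p`,
peak rate `A` — and a piecewise-constant daily hazard. The archetype set
encodes the documented life-history trade-off: five AAB-like treatments
peak early (days 12.5–14) with high late-life hazard, six LAB-like
treatments peak late (days 18–21) with low hazard, four intermediates, one
pathogen-like treatment with low fecundity and high early mortality. Peak
amplitudes (≈0.8–1.3 offspring/female/day) were set so truth λ spans
≈1.5–2.45 with AAB-like ≈2.25–2.45 and LAB-like ≈1.86–2.03, the scale of
reported vial fitness values; peak days stay inside the reported 12.5–21 d
range. These values were fixed from that calibration and are not adjusted
per analysis.

Counts are negative binomial (dispersion 8 by default) rather than Poisson
— egg counts are overdispersed, and the extra noise keeps the rank tests
non-degenerate — and deaths are binomial with `1 − (1 − h)^days`. The
expected schedule (`expectedSchedule()`) gives an analytic truth λ via
Euler–Lotka, against which the per-vial λ distribution is verified to
centre (median within 5%, MAD below 10%).

What the generator does **not** emulate: males (discarded in the assay and
absent from the schema), egg-to-adult viability (folded into the s = 1
boundary assumption), within-vial density effects, time trends across the
three staggered experiments beyond a random intercept, and any mechanistic
microbe–host interaction. Passing tests therefore demonstrate the
*pipeline's* correctness and the qualitative reproducibility of the
fitness-reversal and trait-asymmetry phenomena under the assay's design —
not distributional fidelity to any particular real dataset.

## Problem sizes and determinism

The validation workloads are sized for minutes, not hours: 200 random
schedules for the oracle agreement, the full 2 × (9 or 10) × 8
trait/class/factor grid over one simulated study (≈20,000 monotonicity
checks), 2000 Kruskal–Wallis null simulations, exhaustive letter-display
checks to 5 groups, and 100 recovery plus 200 null MGWA simulations
(≈9,000 mixed-model fits). Every stochastic step derives from an explicit
seed; `runPipeline()` reruns byte-identically from the same configuration,
and `scripts/acceptance.R` threads its `--seed` into every simulation.

## Known limitations

- λ carries no uncertainty: no confidence intervals, no stochastic
  projection, no Lefkovitch (stage-structured) generalisation.
- Perturbations act on one class and one trait at a time; no analytic
  sensitivity/elasticity calculus is provided (numeric perturbation covers
  the use case).
- The MGWA ignores strain relatedness; see the caveat above.
- The interchange format is CSV-only by design (vials, intervals,
  contamination, OG matrix, outputs); no binary formats are read or
  written except the JSON provenance/truth records.
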