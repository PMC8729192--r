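---
title: "Models and methods behind streamseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind streamseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamseg)
```

streamseg implements, end to end, a two-task battery for auditory
stream segregation in children — temporal fine structure (TFS)
sensitivity via harmonic/inharmonic complex-tone discrimination, and
concurrent vowel identification (CVI) as a function of F0 difference —
together with its statistical analysis and a simulated-listener layer
that makes every downstream stage testable without human data. This
vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the simulations do and do
not establish about real listeners.

## TFS stimuli

A harmonic complex H sums 18 equal-amplitude partials at k·F0
(F0 = 100 Hz) with random phases; the inharmonic complex I shifts every
partial up by the same Δf, which destroys periodicity while leaving
component spacing — and therefore the cochlear excitation pattern —
essentially unchanged. Discriminating H from I then requires
sensitivity to the temporal fine structure of the waveform. Both tones
pass the *identical* 5th-order Butterworth band-pass with edges fixed
at 9·F0 and 13·F0 (900/1300 Hz), never moving with Δf, so the only
spectral difference between H and I is the uniform shift. A pink-noise
floor (PSD ∝ 1/f, 50–10000 Hz) masks combination tones.

Parameters the protocol fixes: F0 = 100 Hz, sampling rate 44100 Hz,
harmonic band 9–13, filter order 5. Parameters the protocol leaves
open, with our defaults:

* **Tone duration 200 ms, ramps 20 ms** — typical of this family of
  tasks; keeps a four-tone interval under a second.
* **18 partials before filtering** — leaves stop-bands on both sides
  of the passband so the filter's work is observable.
* **Zero-phase filtering** (`filtfilt`, forward–backward). A causal
  single pass imposes frequency-dependent group delay; because H and I
  differ slightly in component frequencies, that delay pattern could
  itself become a cue. Forward–backward filtering removes it at the
  cost of doubling the effective order; `zero_phase = FALSE` restores
  a single pass.
* **Pink-noise level**: spectrum level at the band centre set 15 dB
  below the per-component level (`noise_db`), a level that masks
  distortion products without swamping the partials. The protocol
  states the noise's presence, not its level.
* **Noise gating**: the noise is gated with the trial rather than
  running continuously; which of the two a given lab used is rarely
  reported, and the choice does not affect any score-level quantity
  here.
* Trials use a 100 ms inter-stimulus interval within an interval and a
  500 ms gap between intervals; the two-interval trial therefore lasts
  2·(4·0.2 + 3·0.1) + 0.5 = 2.7 s.

Digital full-scale normalization stands in for presentation level:
nothing here models dB SPL, headphone response or calibration.

## The adaptive procedure

The 2-down/1-up transformed up-down rule lowers Δf one step (2 Hz)
after two consecutive correct responses and raises it one step after
any error, starting at Δf = 50 Hz with a ceiling at 50 Hz and a floor
at 2 Hz. Its equilibrium is the 70.7%-correct point: a down-step
requires two corrects, so the level where down- and up-rates balance
satisfies p² = 1 − p², i.e. p = √0.5.

The track terminates after 8 reversals; the threshold averages the
midpoints of the three non-overlapping consecutive pairs among the
last six reversal values — numerically equal to the plain mean of
those six (a `reversal_estimator = "mean"` switch makes the
equivalence explicit). If the track demands Δf above the ceiling on
three occasions (`ceiling_exceedances`, configurable — the protocol
says only that Δf "exceeded" the ceiling), the adaptive phase aborts
and a 40-trial constant-stimuli block at Δf = 50 Hz yields a
percent-correct score instead. Because, in the study population, most
children's tracks exceeded the ceiling, the group-level quantity
carried through the analysis is this percent-correct score, for every
child: when a simulated track converges instead, the same 40-trial
probe is run at the ceiling so the cohort column is one homogeneous
measure.

Two numerical properties worth knowing:

* **Transient bias.** Starting at 50 Hz, well above a typical
  threshold, the first reversals happen on the way down; an
  eight-reversal track retains a positive bias of roughly one to two
  steps in its estimate. The engine itself converges: with 20
  reversals the last-six estimator sits within 0.3 Hz of the
  theoretical 70.7% point for a cumulative-Gaussian observer (the
  acceptance suite measures exactly this). Short-track bias is a
  property of the protocol, not a defect of the implementation, and
  it cancels in group comparisons because both groups run the same
  protocol.
* **Non-termination guard.** An observer that never errs produces no
  reversals; a hard cap (`max_trials = 200`) flags such runs invalid
  rather than looping.

A run's full trial log is kept, and `replay_staircase()` re-derives
the outcome from the log alone — simulated sessions are exactly
reproducible and auditable.

## Vowel synthesis and pairing

The five steady-state vowels are produced by a cascade (serial)
formant synthesizer in the Klatt tradition: a glottal impulse train at
F0, a −6 dB/octave spectral tilt approximating the glottal source, and
four second-order digital resonators at the formant centres and
bandwidths, then a 20 ms raised-cosine gate. Steady-state vowels need
no aspiration or frication branches. The protocol fixes F0 = 200 Hz,
duration 270 ms, rate 44100 Hz, and the semitone shifts {1, 2, 4}
(one semitone = a 2^(1/12) frequency ratio, so +4 st gives
200·2^(1/3) ≈ 251.98 Hz); it does not parameterize the formants. The
package ships standard steady-state F1–F4 values in the Peterson &
Barney tradition (e.g. /a/: 750, 1200, 2500, 3400 Hz), overridable per
vowel through `vowel_spec(formants = ...)`.

Token enumeration yields 5 identities × 4 F0 conditions = 20 tokens;
pairing takes all C(5,2) = 10 unordered identity pairs at each F0
difference (40 pairs), one member at the base F0 and the other
shifted — the protocol never puts the same identity twice in a pair,
and only base-vs-shifted pairs are generated (pairing two shifted
members, which could produce the same nominal difference at higher
absolute F0s, is not described and not done). Which identity takes the
shifted F0 alternates deterministically across pairs. Members are
mixed at equal RMS (0 dB member-to-member), the protocol being silent
on relative level, then peak-normalized.

## The CVI task and its scoring

Every pair is presented 20 times in a seeded shuffle; a response is an
unordered pair of two distinct identities from the five-vowel closed
set (the response box offers exactly those five; click order is
ignored). *Double-correct* means the responded set equals the
presented set; *single-correct* means at least one match — so
double-correct implies single-correct, an invariant the scoring
enforces by construction. Condition scores are plain percentages over
the 10 pairs × 20 presentations = 200 trials per F0 condition. No
feedback and no chance correction are applied, matching the protocol;
single-correct scores are the analysis quantity because double-correct
performance saturates near floor in this population.

## Simulated listeners

* **TFS observer**: P(correct | Δf) = γ + (1 − γ − λ)·Φ((Δf − μ)/σ)
  with guess rate γ = 0.5 (2IAFC), lapse λ ≤ 0.05, midpoint μ and
  slope σ in Hz. Monotone by construction.
* **Vowel observer**: the single-correct probability at condition step
  s (s = 0..3 for 0, 1, 2, 4 semitones) is
  base + benefit·s − deficit + child offset, clipped to [0, 1];
  conditional on a single identification, both vowels are identified
  with probability `p_double_given_single`, which keeps the
  double ≤ single implication exact at event level. Responses are
  generated as actual vowel pairs (wrong answers drawn from the three
  unpresented identities) so the scorer is exercised for real.

A cohort draws per-child μ (TFS) and offsets (CVI) from group-level
normal distributions — the study gives no individual-difference model,
so normal heterogeneity is the minimal assumption. Group structure is
additive: an RD deficit shifts both tasks' parameters without
interacting with the F0 condition, mirroring the study's null
interaction.

Default cohort parameters (all overridable in `cohort_params()`):
TD μ = 50 Hz, RD μ = 75 Hz, between-child SD 12 Hz, σ = 20 Hz,
λ = 0.02; CVI base 0.85, benefit 0.0075/step, RD deficit 0.095,
offset SD 0.08. These were chosen so the simulated study conditions
reproduce the qualitative pattern of the real cohort — most adaptive
tracks exceed the ceiling, TD above RD on both tasks with a
between-group *t* around −4.5 and a group F in the low teens, a modest
but detectable F0-difference effect, and an interaction F near 1 —
without hard-coding any published value as an assertion target.

For cohort-scale simulation the CVI scores are drawn binomially at the
(child × condition) probability over the full 200-presentation
schedule; this is distributionally identical to presentation-level
simulation (a test verifies the equivalence through
`simulate_cvi_session()`) and makes thousand-cohort calibration runs
cheap. TFS scores always come from a full staircase run per child.

**What the simulations do not show.** The observer models are
phenomenological: they reproduce the *statistical structure* of the
data (psychometric monotonicity, binomial trial noise, additive group
effects, between-child heterogeneity), not the physiology behind it —
no phase-locking model, no development or age term, no
attention/lapse dynamics beyond a constant rate, and no
vowel-confusion structure (errors are uniform over unpresented
identities, whereas real confusions are biased by formant proximity).
A passing calibration therefore validates the pipeline's inferential
machinery, not any claim about children.

## The statistical layer

The analysis plan applied to any cohort table (simulated or loaded):

* Shapiro–Wilk normality of TFS scores per group (`stats::shapiro.test`).
* Pooled-variance Student *t* on TFS percent-correct. Pooled, not
  Welch, because the design's df = n₁ + n₂ − 2 = 28 identifies the
  pooled test; Welch sits behind `pooled = FALSE`. The sign convention
  is RD − TD, so a worse RD group gives negative *t*.
* A mixed between (group) × within (F0 condition) repeated-measures
  ANOVA, authored as a direct sums-of-squares partition:
  SS_total = SS_group + SS_subjects(group) + SS_condition +
  SS_interaction + SS_error, with F_group on MS_subjects(group) and
  the within effects on MS_error. For a complete 15 + 15 × 4 table the
  df are structurally (1, 28) and (3, 84). Degrees of freedom are
  reported sphericity-assumed (uncorrected), matching the reporting
  convention of the design; the Greenhouse–Geisser epsilon is computed
  from the pooled within-group covariance (double-centred matrix
  formula) and epsilon-corrected p values are reported alongside.
  `stats::aov` with an `Error(subject)` stratum is the independent
  oracle in the test suite — the two routes agree to 10⁻¹⁰ relative on
  random fixtures.
* Per-condition pooled *t* tests with Bonferroni adjustment
  (min(1, 4p) via `p.adjust`); both raw and adjusted p are emitted,
  since pairwise reporting conventions differ on which is quoted.

Degenerate inputs are surfaced, not papered over: constant tables make
the ANOVA report `degenerate = TRUE` with NA F values; constant groups
make the pooled *t* and Shapiro–Wilk error out.

## Calibration and problem sizes

The acceptance suite measures, among others: type-I error of the group
*t* and the interaction F over 1000 null-configured cohorts (accepted
at 0.05 ± 0.02); detection of a configured 2-pooled-SD TFS separation
over 200 cohorts (≥ 95%, with the realized Cohen's d verified ≈ 2);
staircase convergence over hundreds of runs; and the 70.7% point on
20-reversal tracks. These sizes put the whole suite at a couple of
minutes on a single core while keeping Monte-Carlo error well inside
each acceptance band. The 2-SD configuration
(`tfs_mu_td = 45, tfs_mu_rd = 73, tfs_mu_sd = 10`) was calibrated once
against the realized pooled SD of the simulated scores and then
frozen.

## Known limitations

* The deposited per-child score table of the original cohort is not
  bundled; `load_cohort_csv()` accepts it (or any table in its
  schema) via a documented column mapping, and the published
  statistics can then be recomputed with `analyze_cohort()`.
* Audio I/O is 16-bit PCM WAV only, sufficient for stimulus export.
* The RM-ANOVA supports the design it was built for: one between
  factor, one within factor, balanced and complete. Unbalanced groups
  or missing cells are rejected rather than approximated.
* Staircase thresholds in Hz and fallback percent-correct are kept as
  distinct outcome types; mixing them in one column is deliberately
  impossible, which is why the cohort measure is the percent-correct
  probe for every child.
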