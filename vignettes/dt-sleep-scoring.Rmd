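---
title: "Scoring DT sleep and cataplexy in mouse EEG/EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DT sleep and cataplexy in mouse EEG/EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsleep)
```

## The scoring problem

Narcoleptic mouse models generated by ablating orexin neurons show cataplexy:
episodes of muscle atonia with a REM-like, theta-dominant EEG that erupt out
of sustained wakefulness. When melanin-concentrating-hormone (MCH) neurons
are ablated together with orexin neurons, a further state appears: brief
(~15 s) behavioral arrests out of wakefulness in which the EEG carries *both*
high delta and high theta power while the EMG is atonic, terminated by an
abrupt return to wakefulness. Because of that joint delta/theta signature
this state is called *DT sleep*. Its spectral profile closely resembles the
final seconds of NREM sleep before a REM transition, which is why the package
also extracts NREM-to-REM transition windows for comparison.

`dtsleep` implements the complete measurement chain for two-channel mouse
polysomnography (EEG + EMG, 128 Hz, 4-s epochs): filtering, epoch spectral
features, a five-state classifier (`W`, `NR`, `R`, `C`, `D`), and
sleep-architecture statistics. Because no public recordings accompany the
phenotype description, the package ships a synthetic-recording generator
whose ground truth makes every stage testable.

## Epoch features

Signals are band-pass filtered with zero-phase 4th-order Butterworth filters
(forward-backward), EEG at 1.5–30 Hz and EMG at 15–300 Hz. At a 128 Hz
sampling rate the EMG band is capped at 0.98 of Nyquist (15–62.7 Hz): the
300 Hz figure describes the analog front end and cannot survive digitization;
the effective band is recorded in the run log. Zero-phase filtering keeps EEG
and EMG epoch boundaries aligned. Filtering is applied digitally; spectral
content below 1.5 Hz is therefore attenuated, which slightly reduces measured
power in the lowest delta bin for every state alike.

Each 4-s epoch (anchored at sample 0; a trailing remainder is dropped and
logged) yields:

* a Hann-windowed FFT periodogram, normalized so the one-sided bin sum equals
  the windowed signal's mean square; the native 0.25-Hz bins are summed into
  1-Hz bins centered on integer frequencies, conserving total power;
* band powers over delta = bins 1–5, theta = 6–10, alpha = 11–15,
  beta = 16–30 Hz (half-open `[low, high)` edges on bin centers; delta/theta
  follow the 1-Hz-resolution rodent convention, alpha/beta are the
  conventional continuation and are overridable);
* band fractions (each band over the four-band sum, summing to 1), and the
  `theta_fraction` = theta power / total 1–30 Hz power. The "over 50% theta"
  REM rule never states its denominator explicitly; total power is the
  default here and the denominator range is a parameter (`total_range`).
* the EMG integral: mean rectified EMG × 4 s (µV·s), the muscle-tone proxy.

One epoch is the atomic unit: there is no sub-epoch averaging, so per-epoch
band powers have roughly chi-square sampling noise with ~35% relative SD.
That noise floor drives several design choices below.

## The classifier

Thresholds are estimated per recording (`estimate_references`, ≥ 500 epochs):

* two-class 1-D k-means on log EMG integrals, deterministically initialized
  at the 25th/75th percentiles; the **wake threshold** is the midpoint of the
  cluster centers (geometric midpoint on the raw scale) and the **atonia
  threshold** the 90th percentile of the low cluster. If the cluster centers
  differ by less than 4-fold the distribution is declared unimodal (no
  sleep/wake contrast) and estimation fails, advising manual thresholds.
* provisional NREM epochs are low-EMG, delta-dominant; their **median** delta
  power is the NREM delta reference (median rather than mean: robust to
  misclassified provisional epochs). A REM theta reference is the median
  theta power of low-EMG, theta-dominant epochs.

Base rules per epoch: wake if the EMG integral is at or above the wake
threshold (EMG wins regardless of spectrum); otherwise REM if
`theta_fraction > 0.5`; otherwise NREM.

Contextual detectors then relabel maximal runs:

* **Cataplexy**: a run of non-wake, atonic, theta-dominant epochs lasting at
  least 3 epochs (12 s — the smallest multiple of the 4-s grid exceeding the
  10-s rule), immediately preceded by at least 10 consecutive wake epochs
  (40 s).
* **DT sleep**: a run of non-wake, non-cataplexy, atonic epochs whose delta
  power is at least `dt_delta_ratio` (default 0.6, the permissive end of the
  published 60–80% range; configurable) of the NREM delta reference and whose
  theta power is at least 0.6 of the REM theta reference, immediately
  preceded by 10 wake epochs **and** followed by wake. A qualifying run cut
  off by the end of the recording has no observable return to wakefulness and
  is conservatively left unlabeled (flagged in the log). "Behavioral arrest"
  is operationalized purely as EMG atonia; video is out of scope.

Cataplexy is detected before DT sleep and takes precedence when a run
satisfies both: the precedence is not specified anywhere, and cataplexy has
the stricter theta-dominance requirement and is the primary phenotype. The
10 antecedent epochs must be strictly wake; DT epochs do not count toward the
wake run of a subsequent episode. No smoothing or majority filter is applied:
the published workflow used human visual correction, which is not
reproducible, so the automatic output is left untouched.

## The synthetic generator

`simulate_hypnogram` draws a semi-Markov state sequence: per-state dwell
times are gamma distributed (shape 2: positive and right-skewed without
committing to an unknown shape), rounded to whole epochs, truncated below at
1 epoch (3 epochs for cataplexy so every generated bout satisfies the >10 s
rule). The gamma mean is calibrated numerically so the rounded, truncated
dwell has exactly the configured mean. Transitions: REM is entered only from
NREM; cataplexy and DT sleep only from wake bouts that have lasted at least
10 epochs; DT sleep always exits to wake. The antecedent-wake and
termination invariants therefore hold by construction, and `audit_structure`
asserts them on every generated (and scored) hypnogram. A trailing C/D bout
truncated by the recording end is relabeled wake. One RNG stream per
recording is split deterministically between hypnogram and signal synthesis,
so changing signal noise never perturbs the state sequence.

Transition weights are solved in closed form from target bout counts by a
renewal argument: given per-12-h bout counts `n_s` and mean dwells `d_s` for
the non-wake states, wake fills the remaining time, the number of wake bouts
is `n_NR + n_C + n_D`, and the entry probabilities into C and D from eligible
wake bouts are scaled by the probability that a wake dwell reaches 10 epochs.

`synthesize_signals` builds EEG as a sum of four band-limited Gaussian noise
components (frequency-domain synthesis — an ideal band-pass of white noise),
each scaled per sample by the current state's band amplitude. Each component
spans the exact frequency support of its band's integer-centered analysis
bins, so a band's power lands in its own bins rather than a neighbor's. EMG
is white Gaussian noise whose rectified-mean envelope follows the state's
tone with epoch-level lognormal modulation (CV 0.2 for wake, 0.3 for sleep
states). State changes are smoothed with a 0.5-s raised-cosine crossfade
straddling the boundary — long enough to remove discontinuities, short
enough that a 4-s epoch keeps ≥ 94% own-state content; a full-epoch
crossfade would contaminate the single-epoch margins of 3–4-epoch DT bouts
with wake-level EMG and systematically clip the first epoch off every scored
DT bout. The infrared locomotion channel of the original acquisition setup is
not simulated (hardware-specific, and redundant: wake is separable on EMG
alone); circadian drift within a phase and electrode artifacts are likewise
out of scope.

### Presets and their provenance

`preset_config` encodes three study conditions at the 4-week ablation stage.
Published per-phase values (group means) fix most targets:

| condition | phase | NR total | R total | C bouts × mean | D bouts × mean |
|---|---|---|---|---|---|
| intact | dark | 220 min | 30 min | — | — |
| intact | light | 390 min | 55 min | — | — |
| OX_ablated | dark | 258.3 min | 25.6 min | 14.8 × 53.3 s | — |
| OX_ablated | light | 389.8 min | 46.3 min | 8.3 × 50.0 s | — |
| OXMC_ablated | dark | 90.5 min | 2.7 min | 16.9 × 113.0 s | 98.3 × 14.4 s |
| OXMC_ablated | light | 340.1 min | 20.8 min | 15.4 × 96.3 s | 40 × 14.4 s |

Wake is the per-phase remainder, which makes phase totals conserve exactly.
Values not published anywhere were fixed once at field-realistic levels and
are not fitted: NREM mean bout durations (60 s dark / 90 s light in the
ablated conditions, longer in intact animals), REM mean bout duration
(60–70 s), intact-condition totals (typical C57BL/6 architecture), and the
light-phase DT bout count (40 — the light-phase DT duration is taken equal
to the dark-phase value, consistent with the reported ~15 s plateau in both
phases, while its count is reported only as "progressively increasing" and is
left as an explicit choice).

Per-state signal profiles (EEG band amplitudes in µV; EMG tone):

| state | delta | theta | alpha | beta | EMG tone |
|---|---|---|---|---|---|
| W | 15 | 15 | 12 | 12 | 25 µV |
| NR | 60 | 18 | 9 | 6 | 2.5 µV |
| R / C | 15 | 55 | 9 | 6 | 1 µV |
| D | 110 | 70 | 9 | 6 | 1 µV |

These encode the qualitative signatures — low-amplitude mixed EEG with high
tone in wake; delta-dominant NREM with residual tone; low-amplitude
theta-dominant REM and cataplexy with atonia; DT sleep with both delta and
theta elevated (its delta the largest single-state power, consistent with the
relative-power normalization peaking in DT) and atonia. The separations are
deliberately calibrated to ≥ 3 standard deviations of single-epoch
periodogram noise relative to every classifier criterion ("clean" recordings):
smaller margins make single-epoch chi-square flickers break contextual runs,
which is a property of 4-s periodograms rather than of the state machine
under test. Residual heavy-tail flickers still cost roughly 1–2% of DT bouts
per recording, a known and accepted imperfection of the clean-signal regime.
What passing tests on these recordings do **not** show: robustness to real
artifacts (movement, electrode noise), to drifting EMG baselines, or to
states whose spectra overlap more than the configured margins — real
recordings are scored with the same rules but deserve visual review.

## Architecture statistics

Bouts are maximal same-label runs; they partition the hypnogram. Phase
totals are epoch-accurate (each epoch contributes to the phase its clock time
falls in), while bout counts and mean bout durations assign a bout to the
phase of its start epoch — both conventions are documented because a bout can
span the light/dark boundary; they coincide otherwise. Hourly summaries
split totals at hour boundaries but count a boundary-spanning bout once, in
its start hour. Fold differences are reported as second argument over first
(ablation-comparison convention) at full precision, rounded to two decimals
for report output. NREM-to-REM transitions are the last three NREM epochs
before a REM bout; shorter NREM runs are skipped and counted. Group
comparisons use the classical pooled-variance t-test, the paired t-test, or
one-way ANOVA with Bonferroni-adjusted pairwise post hoc tests (Bonferroni
rather than Holm, matching the original analysis style); the DT-vs-transition
band comparison reports per-band paired t-tests with Bonferroni adjustment
across the four bands.

## Numerical choices and degenerate inputs

* Epoch grid: 0-based indices, half-open sample windows `[kL, (k+1)L)`,
  clock times as seconds from midnight.
* All-zero epochs yield zero PSD and *missing* (not zero) band fractions.
* Relative state spectra divide all states jointly by the single greatest
  bin value (global max exactly 100); states with zero epochs are dropped
  with a message.
* Paired tests with identically zero differences return t = 0, p = 1 rather
  than erroring; all-constant group comparisons with differing means error.
* `fold_difference` refuses zero denominators.
* The EDF writer quantizes to 16 bits over a symmetric per-channel range
  covering the data; round-trip error is below one quantization step.

## Problem sizes used in the shipped checks

The validation suite simulates 12-h recordings for the parameter-recovery
and fidelity checks (ten seeds for the DT duration/count recovery), 50 ×
10,000-epoch hypnograms for the stationary-occupancy comparison against the
analytic embedded-chain solution, and one hundred 6-recording batches of
half-hour recordings for the null calibration of the DT-vs-transition
comparison (under an exactly shared spectral profile, fewer than 10% of
batches may declare any band different at adjusted p < 0.05). These sizes
were chosen so each check's Monte-Carlo error is small relative to the
tolerance it asserts.

## Known limitations

* The classifier has no artifact rejection beyond non-finite checks and no
  multitaper/Welch averaging; it presumes the 4-s epoch convention.
* "Behavioral arrest" is EMG-only; episodes with preserved posture but quiet
  EMG would be indistinguishable from DT sleep without video.
* Human visual correction of automatic scores — part of the original
  workflow — is out of scope, as is sleep-onset-REM labeling, which has no
  operational definition in the source methods.
* The generator models neither circadian drift within a phase nor
  autocorrelated (1/f) background EEG; band powers are stationary within a
  state.
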