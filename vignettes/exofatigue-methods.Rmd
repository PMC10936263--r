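---
title: "EMG-based fatigue risk assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-based fatigue risk assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exofatigue)
```

## Scope and model

`exofatigue` estimates localized muscle fatigue risk from multi-channel
surface EMG recorded during cyclic industrial work, and compares paired
with/without-exoskeleton conditions at the level of the job process. The
underlying risk model treats a muscle's exposure as two numbers per
session: how hard it works when it works (mean active amplitude, in
%MVC) and how much of the time it works (duty cycle). An
occupational-hygiene threshold limit value (TLV) maps the duty cycle to
the highest normalized effort sustainable without localized fatigue; the
fatigue risk value FRV = MAA − TLV(DC) is the signed exceedance of that
limit.

## Signal conditioning

Each raw channel passes through four stages with these defaults:

| stage | parameter | default | why |
|---|---|---|---|
| spike removal | threshold multiplier `k` | 25 | contact artifacts are far outside physiological range |
| | isolation ratio / halo | 3 / ±3 samples | see below |
| band-pass | edges, effective order | 20–450 Hz, 4 | standard surface-EMG band; removes motion artifact and out-of-band noise |
| rectify + low-pass | envelope cutoff, order | 10 Hz, 4 | linear envelope tracking activation |
| normalization | MVIC window | 1 s sliding, 1-sample step | highest sustained maximal effort |
| interval series | interval | 1.0 s, trailing partial discarded | fixed-duration consecutive intervals |

"Fourth-order zero-lag Butterworth" is implemented as a half-order
design applied forward and backward (`signal::filtfilt`), so the stated
order is the *effective* magnitude order of the cascade and the phase
lag is identically zero. The alternative reading (a fourth-order design
applied twice, eighth-order effective) is available by passing
`order = 8`.

**Spike removal.** Manual artifact editing is not reproducible, so the
package uses an automated surrogate: a sample is a spike when (a) its
absolute value exceeds `k` times the robust scale of the rectified
signal (MAD scaled to a normal-sigma equivalent) *and* (b) it exceeds
three times every neighbor within ±3 samples. The isolation criterion
matters for bursty task signals: with a 2 %MVC resting baseline and
bursts at 40 %MVC, the signal-wide robust scale is dominated by the
baseline and a pure amplitude rule at `k = 25` would clip genuine burst
peaks (band-limited EMG is strongly correlated sample-to-sample, so real
peaks have large neighbors, while single-sample contact artifacts do
not). With both criteria the rule removes injected artifacts exactly and
leaves clean and bursty signals untouched in the validation suite.
Flagged samples are bridged by linear interpolation rather than excised,
preserving the time base that the duty cycle depends on.

**Envelope clamp.** A zero-phase low-pass can undershoot slightly below
zero after sharp onsets; envelopes are clamped at zero because an
amplitude is non-negative by definition.

**Filter transients.** The first and last 1-s intervals of each series
are flagged (`edge`) but kept, so "total work time" is the full
recording; recovery tests exclude the flagged intervals when comparing
against analytic ground truth.

## The TLV curve

The TLV for localized fatigue is cited in the ergonomics literature as a
decreasing duty-cycle curve but its published functional form is
edition-dependent. The package therefore ships a configurable decreasing
power-law family

$$\mathrm{TLV}(DC) = 20 \cdot \left(\frac{DC}{0.5}\right)^{-0.5}\ \%MVC,$$

calibrated so that TLV at a 50% duty cycle is exactly 20 %MVC — the
anchor implied by the meaningful-change guideline that a 2 %MVC
amplitude reduction is at least a 10% reduction relative to the TLV at
50% duty cycle. The exponent 0.5 was chosen once as a field-plausible
decay (TLV ≈ 45 %MVC at 10% duty, ≈ 14 %MVC at continuous work) and is
a config field, as are the anchor, the duty-cycle floor (0.02, below
which the curve is evaluated at the floor so it stays bounded) and the
cap (100 %MVC). Two boundary rules: a duty cycle of exactly zero returns
the cap and an undefined (NA) fatigue risk value — no finite limit or
risk applies to a muscle that is never active; an FRV of exactly zero
counts as at-or-below the TLV in the benefit categories, because only
positive FRVs indicate effort above the limit.

## Bilateral reduction

Arm and shoulder muscles retain the higher of the two sides. The
reduction takes the per-metric maximum of mean active amplitude and duty
cycle, re-evaluates the TLV at the retained duty cycle, and recomputes
the FRV from the retained amplitude and TLV. This keeps two properties
simultaneously: the reduced record is never below either side on any
metric, and the identity FRV = MAA − TLV holds exactly on every reported
row (taking independent maxima of MAA and FRV could mix sides and break
the identity). The lumbar erector spinae is treated as one bilateral
postural muscle: its left/right normalized series are averaged
elementwise *before* metrics are computed, which genuinely differs from
averaging metrics (alternating unilateral activity yields a full duty
cycle on the averaged series).

## Statistics

Normality is assessed on the paired differences — the quantity the tests
act on — with the Lilliefors-corrected Kolmogorov–Smirnov test
(`nortest::lillie.test`; the naive KS test with estimated parameters is
anticonservative). The gate requires at least 5 pairs, the validity
floor of the small-sample correction. Normal differences get a paired
t-test; otherwise an exact Wilcoxon signed-rank test: zero differences
are dropped, ties share midranks, and for n ≤ 15 the two-sided p-value
is computed from the full distribution of the rank sum over all 2^n
sign assignments (dynamic programming over doubled ranks, so midranks
enumerate exactly); beyond that a normal approximation with tie and
continuity corrections is used. Effect sizes default to the paired d_z
(|mean| / SD of differences; a pooled-SD variant is available via
`pooled = TRUE`), labelled at the conventional 0.20/0.50/0.80
cut-points, with the signed mean difference carrying the direction.
No multiple-testing correction is applied across muscles or metrics;
each comparison is reported at α = 0.05.

## The synthetic generator

The generator exists because raw field EMG from such studies is rarely
shareable. It emulates:

- **MVIC trials**: 5 s, a 2-s linear ramp to maximum then a 3-s maximal
  plateau; the plateau modulation level *defines* the 100 %MVC scale.
- **Task sessions**: per-cycle piecewise-constant %MVC profiles (one
  activation burst per muscle, plateau over a resting baseline) with
  100-ms cosine transition ramps, modulating independent band-limited
  (20–450 Hz) unit-RMS Gaussian carriers; occasional isolated
  single-sample spikes at 30× channel RMS.
- **Cohorts**: 16 processes by default, three quarters performed by two
  team members and the rest by one; the exoskeleton effect on a muscle's
  plateau is drawn per process (mean −5 %MVC, between-process SD 5) plus
  a within-process member component (SD 2).

Because session and MVIC signals share the carrier model and pass the
identical envelope chain, the proportionality constant between
modulation depth and envelope level cancels under normalization, making
the ground truth linear in the profile: the true duty cycle and mean
active amplitude follow in closed form from the profile, threshold and
cosine-ramp geometry (`session_ground_truth()`). The defaults mirror the
emulated study's conditions: 1,926 Hz sampling, roughly 70-s cycles
repeated for about 10 minutes, an anterior-deltoid plateau of 40 %MVC
over 30% of the cycle.

What the generator does *not* emulate: motor-unit physiology,
fatigue-induced spectral drift, posture-dependent amplitude changes
within a burst, or correlated noise across channels. Passing recovery
tests therefore shows the analysis chain is correct and calibrated for
amplitude-modulated signals, not that it is robust to every property of
real field EMG.

## Problem sizes used in validation

The validation suite runs at desk scale by choice: recovery tests use
60-s single-muscle sessions (10-s cycles × 6) over 20 seeds, where
recovered duty cycles sit within ±0.01 of truth and amplitudes within
about −6% (a small negative bias from the max-window MVIC reference and
interval-boundary ramps, well inside the ±10% recovery band).
Operating-characteristic checks of the comparison stage (type-I error
over 2,000 replicates, power over 500 at n = 16 with a −5 %MVC effect
and 5 %MVC between-process SD) draw paired differences directly at the
metrics level — a reduced-scale surrogate that isolates the statistical
stage from the (already separately validated) signal stage. End-to-end
determinism is checked on a 6-process cohort with 12-s sessions.

## Known limitations

- The TLV curve's exponent is a calibrated stand-in for the cited
  guideline equation; only the 20 %MVC anchor at 50% duty cycle is
  constrained. Conclusions that depend on the curve's shape far from the
  anchor should be made with the coefficients configured to the
  guideline edition in use.
- TLV curves of this family were designed for upper-limb fatigue;
  applying them to back muscles is a convention, not a validated model.
- The normality gate and the exact Wilcoxon are sound at n ≥ 5, but the
  benefit categorization is purely descriptive — no uncertainty is
  attached to a process's category.
- "Total work time" is the full recording duration; non-work gaps are
  not detected or excluded.
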