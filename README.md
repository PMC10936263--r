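# exofatigue

Surface-EMG fatigue risk assessment for occupational exoskeleton
evaluation.

Arm-support exoskeletons are deployed on assembly lines to relieve the
shoulder musculature during repetitive overhead work. Whether they
actually reduce localized muscle fatigue risk is an empirical question
answered with surface electromyography (EMG): record the working muscles
with and without the exoskeleton, normalize amplitudes to maximal
contractions, and compare the resulting fatigue risk estimates across
job processes. `exofatigue` implements that full pipeline for
ergonomists and biomechanists, plus a seeded synthetic EMG generator
with analytically known ground truth so every stage can be validated end
to end.

## The method

For each muscle channel (anterior deltoid, biceps brachii, upper
trapezius, lumbar erector spinae; left and right):

1. **Conditioning** — nonphysiological contact spikes are removed
   (robust amplitude threshold + isolation criterion, linear
   interpolation), the signal is band-pass filtered 20–450 Hz with a
   fourth-order zero-lag Butterworth filter, rectified, and low-pass
   filtered at 10 Hz into a linear envelope.
2. **Normalization** — the envelope of a 5-s maximum voluntary isometric
   contraction (MVIC) trial is scanned with a sliding 1-s window; the
   highest windowed mean is the 100 %MVC reference. Working envelopes
   are averaged over consecutive 1-s intervals and expressed in %MVC.
3. **Fatigue metrics** — an interval is *active* when its amplitude
   exceeds 5 %MVC. The duty cycle DC is the active fraction of total
   work time; the mean active amplitude (MAA) averages active intervals.
   The threshold limit value for localized muscle fatigue is a
   decreasing function of duty cycle, here a calibrated power law

   TLV(DC) = 20 · (DC / 0.5)^(−0.5)  %MVC  (capped at 100 %MVC),

   anchored so TLV(0.5) = 20 %MVC. The **fatigue risk value**
   FRV = MAA − TLV(DC) is positive when the muscle works above its
   fatigue limit.
4. **Bilateral reduction** — shoulder/arm muscles retain the higher of
   the two sides; the lumbar erector spinae series are averaged across
   sides first.
5. **Cohort comparison** — member-level metrics are collapsed to
   process-level means, paired with/without-exoskeleton differences are
   gated through a Lilliefors (Kolmogorov–Smirnov) normality check and
   tested with a paired t-test or an exact Wilcoxon signed-rank test
   (α = 0.05), with Cohen's d_z and 95% confidence intervals. Each
   process is assigned a benefit category from its FRV pair (meaningful
   change ≥ 2 %MVC): (1) reduced but still above TLV, (2) reduced from
   above to below TLV, (3) reduced while already below TLV, (4) minimal
   change or increase. Optional posture sheets (percent time at shoulder
   elevation ≥60°/90°/135°) and −1…+1 visual-analog-scale usability
   surveys are aggregated alongside.

## Worked example

A reduced-scale synthetic cohort (6 processes, 12-s sessions, anterior
deltoid only, a −5 %MVC exoskeleton effect on the plateau amplitude):

```r
library(exofatigue)
cfg <- run_config(
  paths = list(data_dir = "cohort", output_dir = "results"),
  simulate = list(n_processes = 6, cycle_time_s = 6, n_cycles = 2,
                  muscles = "anterior_deltoid"),
  seed = 123L
)
cmd_simulate(cfg)   # writes signal CSVs, MVIC trials, manifest, truth table
metrics <- cmd_process(cfg)
res <- cmd_compare(cfg)
res$comparison[, c("variable", "n", "delta", "test", "p", "d", "d_label")]
#>                       variable n    delta     test          p        d d_label
#> 1 anterior_deltoid.maa_pct_mvc 6 -3.42317 paired_t 0.03881455 1.135708   large
#> 2 anterior_deltoid.frv_pct_mvc 6 -3.42317 paired_t 0.03881455 1.135708   large
table(res$categories$category)
#> 1 2 3 4
#> 2 1 1 2
```

Reading: across the six processes the mean active anterior-deltoid
amplitude dropped by 3.4 %MVC with the exoskeleton (paired t-test,
p = 0.039, large effect), and the fatigue risk value dropped by the same
amount; two processes stayed above the TLV despite a meaningful
reduction (category 1), one crossed from above to below the TLV
(category 2), and two showed no meaningful change (category 4). The
same functions run on real recordings by pointing `data_dir` at a
directory with a `manifest.yaml`, signal CSVs (`time_s` +
`<muscle>_<side>` columns) and MVIC trials.

A command-line front end wrapping the same three stages is installed at
`system.file("cli", "exofatigue.R", package = "exofatigue")`:

```sh
Rscript exofatigue.R simulate --config cfg.yaml --seed 1
```

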