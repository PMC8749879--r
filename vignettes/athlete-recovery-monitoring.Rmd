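---
title: "Monitoring fatigue and recovery from wearable-sensor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring fatigue and recovery from wearable-sensor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebound)
```

## The monitoring problem

When a squad of team-sport athletes returns to training after a prolonged
rest, coaching staff want to know three things: how much a standardized
fatiguing session costs each athlete, in which week that cost peaks, and
when it has faded — i.e. when the athlete has recovered. `rebound`
implements an instrumented answer built on three measurement streams per
session:

* a **shuttle-run fatigue protocol** monitored by a wrist device (heart
  rate every 5 s, GNSS position),
* a **Wingate test** (30 s of all-out cycling on an ergometer) before and
  after the protocol, giving mean and peak anaerobic power,
* a **Bosco test** (30 s of repeated maximal vertical jumps) recorded by a
  single foot-mounted accelerometer, giving the ballistic profile.

The pre-effort trial of each session is the athlete's own baseline for
that day; the post/pre contrast isolates the effect of the protocol from
day-to-day and athlete-to-athlete variation.

## From specific force to ballistic parameters

An accelerometer measures specific force: ≈1 g when the athlete stands,
≈0 g in free fall, and a large pulse while the foot loads the ground.
`detect_jump_events()` exploits this contrast directly:

* a **flight** is a maximal run of samples below `flight_threshold_g`
  (default 0.3 g — halfway between the 0 g flight level and the 1 g
  standing level, robust to sensor noise of a few hundredths of g)
  lasting at least `min_flight_s` (default 80 ms);
* a **contact** is the interval between consecutive flights; flights
  separated by less than `min_contact_s` (default 50 ms) are merged, since
  no real contact is that short;
* the **first contact** has no preceding flight; its start is the end of
  the last sustained (≥ 50 ms) quiet-standing run before the first
  takeoff, with "quiet" meaning a deviation from baseline below three
  times the noise level estimated from the initial standing segment. The
  sustained-run requirement matters: the contact pulse returns smoothly
  towards 1 g just before takeoff, and a single sub-threshold sample there
  must not be mistaken for standing.

From the aggregate contact time $T_c$ and flight time $T_f$ of a trial and
the body mass $m$, the four parameter groups are

$$h_{max} = \frac{g T_f^2}{8}, \qquad
  RSI = \frac{h_{max}}{T_c},$$

$$P = \frac{m g^2}{T_c}\left(\frac{T_f^2}{4}
      + \frac{T_c\,|T_c+T_f|}{\pi} - \frac{T_c^2}{4}\right), \qquad
  K = \frac{m \pi (T_f + T_c)}
        {T_c^2\left(\frac{T_f+T_c}{\pi} - \frac{T_c}{4}\right)},$$

with $g = 9.81\ \mathrm{m/s^2}$. $h_{max}$ is the flight-time estimate of
jump height (projectile kinematics), $P$ the mean power exerted during
contact, and $K$ the stiffness of the leg modeled as a linear spring over
the contact phase. The stiffness denominator is positive for every
physically possible pair of positive durations; the implementation still
guards it defensively.

**Trial aggregation.** A 30-s trial yields 20–40 jumps. Events with
implausible durations ($T_c \notin [0.10, 1.00]$ s,
$T_f \notin [0.20, 0.90]$ s) are discarded as artifacts. The valid
durations are averaged and the four derived parameters computed *from the
aggregated pair*, not averaged per jump. This choice keeps the reported
aggregate internally consistent ($h_{max} = g T_f^2/8$ holds exactly for
the output) at the price of a small Jensen-gap difference from the mean of
per-jump values; it is a convention, not a claim about how any particular
study aggregated its trials.

## Session metrics

* **Mean heart rate**: arithmetic mean of the 5-s estimates over the whole
  workout. Wrist devices drop estimates they deem implausible at high
  intensity; dropped samples are simply omitted from the mean, with no
  interpolation.
* **Covered distance**: haversine sum over successive GNSS points on a
  sphere of radius 6,371 km — accurate to well below 0.1% at shuttle-run
  scale. An optional speed gate (12 m/s) can drop GNSS spikes; it is off
  by default.
* **Wingate powers**: the mean is the time-average of the trace; the peak
  is the maximum of a centred 1-s rolling mean, because instantaneous
  maxima are dominated by pedal-stroke and sensor noise and anaerobic peak
  power is conventionally reported over a short window. The window width
  is configurable since ergometers differ in what they report.

## The statistical battery

Eight athletes per cell put the analysis firmly in exact-test territory.

* **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): differences are
  `pre − post`; zeros are dropped (recorded in the result's notes),
  absolute differences mid-ranked. For $n \le$ `exact_max_n` (default 12)
  the two-sided p-value is $P(|W - \mu| \ge |w_{obs} - \mu|)$ over all
  $2^n$ sign assignments, computed by convolution on doubled ranks so that
  tied mid-ranks stay exact (the enumeration is then conditional on the
  observed tie pattern). This choice — rather than falling back to the
  normal approximation whenever ties occur — keeps the test exact in the
  regime where ties are most damaging, and is what makes the smallest
  achievable two-sided p at $n = 8$ exactly $2/256 = 0.0078$. Above
  `exact_max_n`, a tie-corrected normal approximation without continuity
  correction is used.
* **Friedman test** (`friedman_rank_test()`): mid-ranks within each
  athlete, tie-corrected statistic referred to $\chi^2_{k-1}$. The
  chi-square reference is slightly conservative at $n = 8$, $k = 4$; the
  package's own calibration (1000 simulated null cohorts) puts the
  empirical type-I rate near 0.04 at a nominal 0.05.
* **Bonferroni post hoc** (`bonferroni_posthoc()`): all $k(k-1)/2$
  pairwise signed-rank tests with p-values multiplied by the number of
  comparisons, clipped at 1. Identical columns are reported as $p = 1$
  (no evidence of difference) rather than an error. A Friedman mean-rank
  critical-difference variant is available via
  `analysis_config(posthoc = "rank_cd")`; the pairwise form is the default
  because it stays consistent with the per-week signed-rank framing.
* **Cliff's delta**: normalized excess of concordant pairs, in $[-1, 1]$;
  reported alongside each pre/post p-value because at $n = 8$ the p-value
  saturates (many configurations reach 2/256) while the effect size still
  discriminates.
* **Dispersion**: coefficient of quartile variation
  $100 (Q_3 - Q_1)/(Q_3 + Q_1)$ and median/IQR, all under one fixed
  quartile convention — linear interpolation of order statistics at
  position $(n-1)p + 1$ (R's type 7). The convention is configurable but
  must be fixed for CQV values to be comparable across reports.
* **Normality check**: one-sample KS statistic against the normal with
  *estimated* mean and sd. Because parameters are fitted, the naive KS
  p-value would be anticonservative; the p is instead calibrated by
  seeded Monte Carlo (the Lilliefors construction, 10,000 replicates by
  default). Whether to use fitted or fixed reference parameters was an
  open choice; fitted parameters are the defensible default since no
  external reference distribution exists for these measures.

## The study pipeline

Sessions are grouped by week; weeks with more than one acquisition
contribute the mean of their sessions. Heart rate and covered distance are
analysed on raw weekly values; power and Bosco parameters on their
**normalized variations** $100 (post - pre)/pre$, which removes
inter-subject scale before athletes are pooled. This raw-vs-normalized
mapping is hard-coded with a config override (`quantity = "raw"` or
`"nv"`).

`detect_phases()` formalizes the downfall/recovery reading of a weekly
trajectory: the nadir is the worst weekly median (minimum for
larger-is-better parameters; maximum for heart rate and contact time,
which improve downwards — see `parameter_orientation()`), ties break
toward the earlier week, and weeks after the nadir are labelled
"recovery". `build_report()` runs the full battery for all ten monitored
parameters and writes deterministic CSV tables, optional SVG boxplots and
a run-metadata JSON (seed, configuration hash).

Missing pre- or post-effort trials exclude a session from the pre/post
analysis of that parameter only. Week indices are 1-based everywhere.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` generates the full study design: 8 athletes
(anthropometrics drawn around 72.4 ± 8.3 kg, 180.8 ± 6.3 cm, 24 ± 3.3 y),
4 weeks with session counts (2, 2, 1, 1), pre/post trials each session,
and two equal training subgroups.

The key defaults, and why:

* **Fatigue trajectories.** Post/pre multiplicative effects per week:
  Wingate (0.90, 0.80, 0.92, 0.94), Bosco flight time
  (0.93, 0.87, 0.95, 0.995). Both bottom out in week 2 — the nadir — and
  recover strictly afterwards; the Wingate deficit persists at week 4
  while the ballistic deficit essentially vanishes, so pre/post
  significance is lost there. Magnitudes correspond to median power losses
  of roughly −10/−20/−8/−6% across the weeks, the size of effect such
  campaigns report. Fatigue lengthens contacts and shortens flights:
  $T_f$ scales by the effect, $T_c$ by its inverse, and the four derived
  parameters respond consistently.
* **Subgroups.** Athletes who had trained less ("<45min") carry a +6 bpm
  heart-rate offset and a fatigue-*deficit* multiplier of 1.4:
  $\mathrm{effect}' = 1 - (1 - \mathrm{effect}) \times 1.4$. Scaling the
  deficit rather than the ratio makes the subgroup gap large when fatigue
  is deep and negligible once the cohort has recovered, which is how
  susceptibility behaves.
* **Noise.** Multiplicative Gaussian noise with CV 0.04 on scalar
  performance values (typical test–retest variability for jump and power
  measures), between-athlete CVs of 0.15 for power and 0.06 for jump
  durations, 4 bpm between-athlete HR spread. `noise_cv = 0` switches the
  generator into a fully deterministic mode (including between-athlete
  spread) in which weekly aggregates equal the configured truth to
  machine precision — the basis of the end-to-end validation tests.
* **Traces.** Jump traces place phase boundaries on the sample grid by
  cumulative rounding (each phase within one sample of its
  specification) and return the exact boundary indices as ground truth;
  contacts are half-sine pulses from 1 g up to a 2.5 g peak, flights are
  exactly 0 g. HR series are centred so their mean is exactly the
  configured value when noiseless. GNSS tracks realize the prescribed
  shuttle geometry (5 phases of two- or three-way 25-m shuttles in
  10 s work / 10 s rest cycles, 2-min inter-phase rests) with points at
  the turn instants, so the haversine path length equals the prescribed
  distance; the protocol source states 5-min first and last phases but
  not the middle ones, so the middle phases default to 5 min as well
  (configurable), giving a prescribed total of 4875 m — a package
  default, not a protocol fact. Wingate traces are a rise-and-decay
  profile affinely scaled to hit the drawn mean and windowed peak
  exactly.

The generator does **not** emulate: musculoskeletal dynamics (the contact
pulse is a shape, not a force solution), GNSS error structure (multipath,
drift — only white jitter), photoplethysmography artifacts, or per-jump
fatigue drift within a trial. Passing tests therefore demonstrate that the
pipeline recovers what the sensors would ideally encode; they do not
certify robustness to every real-world artifact.

## Problem sizes and numerical choices

The validation suite uses 100-trial detector round-trips at 100 and
1000 Hz, 500-case oracle comparisons for the exact tests, 1000 simulated
null cohorts for the Friedman type-I calibration and 200 cohorts for
nadir recovery — sizes at which all Monte-Carlo margins are comfortable
and the whole suite runs in a few minutes on one core. Quartiles use one
fixed interpolation rule (above); the detector's thresholds are stated in
physical units and configurable; all random draws flow from explicit
seeds, and internal seeded routines save and restore the caller's RNG
state.

## Known limitations

* The exact signed-rank floor of 2/256 means per-week pre/post p-values
  saturate at $n = 8$; effect sizes carry the discrimination.
* The first-contact duration depends on an onset heuristic; under heavy
  noise its error grows faster than that of flight-delimited contacts.
* Subgroup contrasts are descriptive only — with four athletes per group
  no inferential claim would be honest.
* The normalized-variation convention divides by the pre-effort value;
  parameters that can legitimately approach zero would need a different
  normalization (none of the ten monitored ones does).
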