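---
title: "Methods: gait segmentation from plantar-pressure insoles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait segmentation from plantar-pressure insoles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitseg)
```

## The problem

A pair of sensorized insoles measures plantar pressure at eight anatomical
sites per foot (heel, lateral midfoot, three metatarsal heads, hallux, two
toes), nominally at 100 Hz. From those sixteen channels alone, `gaitseg`
segments the gait cycle into its stance and swing phases, splits stance
into its four ordered subphases — initial contact (ICP), forefoot contact
(FFCP), flat foot (FFP), and forefoot push-off (FFPOP) — and reports six
spatiotemporal indices: CoP mean velocity, mean double-support time,
cadence, and the stance / swing / double-support percentages of the gait
cycle. In healthy adults the stance phase occupies roughly 60% of the
cycle and swing the remaining 40%; that split is the package's headline
recovery check.

## Event detection

Heel strike (initial contact, IC) and toe off (TO) bound the stance phase.
Both are detected with an *adaptive half-range threshold*: at every sample
the threshold is the midpoint of the rolling maximum and minimum of the
signal over a centered window (`detector_params()$window`, default 1.5 s,
truncated at the recording edges). An IC is the first sample at which the
heel signal reaches or exceeds its threshold after having been below it; a
TO is the first sample at which the hallux signal drops below its
threshold after having been at or above it.

Three tunables surround the rule, none of which changes the rule itself:

* `window` (s, default 1.5): must span at least one gait cycle so that the
  rolling extrema see both a loaded and an unloaded state; it should stay
  short enough to track slow drift. At a typical 1.05 s cycle, 1.5 s covers
  about one and a half cycles.
* `refractory` (s, default 0.3): minimum spacing between same-type events,
  absorbing crossing chatter when noise rides on a slow signal. 0.3 s is
  well below any physiological step interval.
* `min_amplitude` (kPa, default 20): the detector is disarmed wherever the
  rolling max–min range is smaller, so quiet standing (a flat, noisy
  signal whose threshold hugs the noise) produces no events.

Event times are reported at the crossing sample, with no sub-sample
interpolation: at 100 Hz the granularity is 10 ms, which matches the
hardware class this method targets. Whether the window is centered or
causal is not dictated by the method; the centered choice is symmetric
around the event and is the package default.

## Center of pressure

Per sample, the CoP is the pressure-weighted mean of the sensor positions,

$$CoP_x = \frac{\sum_i X_i P_i}{\sum_i P_i}, \qquad
  CoP_y = \frac{\sum_i Y_i P_i}{\sum_i P_i},$$

with $X_i, Y_i$ the medial–lateral and anteroposterior sensor coordinates
(mm) and $P_i$ the pressures. During swing $\sum_i P_i \to 0$ and the
ratio is meaningless, so samples whose total pressure falls below
`contact_floor` (default 10 kPa) are *masked*, never zero-filled. Note
that the floor is compared against the **sum over eight sensors**: with
additive sensor noise of standard deviation $\sigma$, the expected summed
magnitude during swing is about $8\sigma/\sqrt{2\pi}$ (≈16 kPa at
$\sigma = 5$), so users analyzing noisy recordings should either raise the
floor or rely on the stance-restricted aggregation described below, which
is what the pipeline does.

Instantaneous velocity is the first difference scaled by the sampling
rate, $Vel(T) = (CoP(T) - CoP(T-1)) \cdot f_s$; at the nominal 100 Hz this
is a division by 0.01 s, and the package generalizes that divisor to
$1/f_s$ so recordings at other rates are handled identically. Velocity is
undefined at the first valid sample of every contact episode and wherever
either sample of the pair is invalid.

The scalar "CoP mean velocity" index aggregates the two axes as the mean
Euclidean speed $\sqrt{Vel_x^2 + Vel_y^2}$ (reported in cm/s), computed
over stance samples (one mean per stance, then mean ± SD across stances).
How the two axes should be collapsed into the reported scalar — and
whether it should be computed per foot or over both feet combined — is not
uniquely determined by the method; the package computes it per foot,
reports axis-wise means as attributes of `mean_cop_speed()`, and keeps the
choice documented here rather than asserting it as canonical.

## Stance subsegmentation

Within a stance the anteroposterior CoP travels rearfoot → lateral
midfoot → metatarsal heads → hallux. The four subphases are obtained by
partitioning the foot's anteroposterior axis into four zones and labeling
every stance sample with the zone containing its $CoP_y$. The package
defaults place the three cuts at fractions 0.25, 0.45 and 0.70 of foot
length (65, 117 and 182 mm for the EU 41 / 260 mm default): the cut
positions themselves are not published for this method, so these defaults
were chosen to fall between the heel, midfoot, metatarsal-head and toe
sensor bands of the default layout, and are fully configurable
(`zone_boundaries()`).

Two policies resolve ambiguities the zone rule alone leaves open:

* **Monotone forward-carry.** The subphases are strictly ordered events,
  so a sample may never be labeled an earlier subphase than any preceding
  sample of the same stance. The label is the furthest zone reached so
  far; CoP jitter across a cut cannot revert it.
* **Half-open zones** `[low, high)`: a CoP exactly on a cut belongs to the
  later zone.

Stance samples without a valid CoP (typically the first contact sample,
before total pressure clears the floor) inherit the first observed zone of
that stance; a stance with no valid CoP at all is skipped with a warning.
Subphase intervals are delimited by the stance bounds and the transition
sample times, so their durations always sum exactly to the stance
duration.

The zone → subphase mapping is rear-to-front ICP → FFCP → FFP → FFPOP,
i.e. the subphases in their stated order. There is a genuine tension here:
descriptively, FFCP is the arrival of the metatarsal heads and FFP the
flat-foot period, while the CoP passes through the *midfoot* zone before
the metatarsal zone. A position-based rule cannot distinguish "midfoot
loaded on the way to the forefoot" from "foot flat"; the package keeps the
ordered mapping (which preserves the event order) and leaves the cuts
configurable rather than guessing a different mapping as ground truth.

## Gait cycles and indices

A gait cycle runs IC → next IC of the same foot. Stance duration is the
paired IC–TO interval clipped to the cycle; swing is the remainder, so
stance% + swing% = 100 per cycle by construction. Double support is the
intersection of the two feet's stance trains (a two-pointer sweep over the
sorted intervals); a cycle's double-support percentage counts *all*
overlap episodes inside the cycle — two per cycle in normal gait — divided
by the cycle duration. That normalization is a documented package choice:
it is consistent with double-support percentages in the 20–40% range
reported for instrumented-insole studies, but other normalizations (single
episode, per half-cycle) exist in the literature.

Cadence is $steps / time \cdot 60$ with a step = one initial contact of
either foot. The analysis window runs from the first detected IC to the
last detected event, because walking trials typically begin and end with
quiet standing that should not dilute the rate; `full_window = TRUE`
switches to the whole recording. Since counting both feet doubles the
single-foot (stride) rate, `analyze_gait()` also reports
`stride_cadence_cycles_min` for comparison with stride-based conventions.
The summary's cadence SD is that of the per-cycle instantaneous cadence
(2 steps per cycle duration); the method itself defines only the overall
mean.

## The synthetic gait generator

There is no public recording corpus for this sensor class, so the package
ships a generator (`gait_profile()`, `generate_gait()`) that produces
annotated two-foot recordings with the statistical structure the pipeline
assumes:

* strictly periodic cycles (default 1.05 s) with stance_fraction 0.60 —
  the healthy-adult split the method is expected to recover;
* per-sensor smooth unimodal pulses inside activation windows expressed as
  fractions of stance, following the heel → midfoot → metatarsals →
  hallux/toes progression; peak pressures (250–900 kPa) lie inside the
  0–1200 kPa range over which capacitive insole sensors of this class are
  characterized;
* feet in anti-phase (offset 0.5 cycles), giving the two double-support
  episodes per cycle of normal gait;
* additive Gaussian sensor noise (default σ = 5 kPa) truncated at 0 kPa,
  applied after the noiseless waveform — ground-truth event times are
  stored, not re-detected, so noise never moves the truth.

The pulse shape is a generalized raised cosine (half-cosine attack,
plateau, half-cosine release — a Tukey window; the symmetric Hann shape is
the special case attack = release = half the window). The asymmetry is
deliberate: the heel onset (attack 0.008 of stance, ≈5 ms) is the physical
heel-strike transient and pins the heel's half-range threshold crossing to
within one sample of the true IC even when the true event falls between
samples; every sensor loaded until toe off shares one sharp release
(0.02 of stance) ending exactly at TO, which pins the hallux crossing to
TO and keeps the late-stance CoP stationary. The default activation
windows were chosen once so that the noiseless CoP advances monotonically
through all four anteroposterior zones in every stance, as the real
heel-to-hallux CoP progression does.

The default stance subphase fractions (0.15/0.20/0.35/0.30 of stance for
ICP/FFCP/FFP/FFPOP) define the *ground-truth labels*; they are plausible
values chosen so all four zones are exercised, not published constants.

What the generator does **not** emulate: step-to-step timing variability,
asymmetry, speed changes, sensor drift or hysteresis, crosstalk,
heteroscedastic or impact noise, and pathological patterns. Passing the
recovery tests therefore shows the pipeline is correct under the model's
assumptions (periodic gait, clean heel/hallux loading), not that it is
robust to every real-world artifact.

## Numerical choices and degenerate inputs

* Time is seconds as doubles; sample $k$ of a recording is at
  $t_0 + k/f_s$.
* Rolling extrema use a centered window of $2\lfloor w f_s / 2 \rfloor +
  1$ samples, truncated (not padded) at the edges.
* Event pairing: each IC takes the first TO strictly after it and before
  the next IC; leading TOs and trailing ICs are dropped.
* The last IC of a foot starts no cycle (no next IC), so $n$ stances give
  $n - 1$ cycles per foot.
* Empty results are signalled, not silently zeroed: no events → empty
  vectors; fewer than 2 ICs → zero-row cycle table with a warning; no
  defined velocity samples → error.
* All randomness in the generator flows from the single `seed` in the
  profile; identical seeds give bit-identical recordings.

## Verification problem sizes

The shipped test-suite and the acceptance script exercise the chain at
sizes a laptop handles in seconds: the stance/swing recovery runs the full
pipeline on 20 seeded simulations of 30 cycles per foot at 5 kPa noise
(≈1160 analyzed cycles); event-time recovery uses one noiseless 10-cycle
run plus 50 seeded 8-cycle runs at 5 kPa; the CoP and double-support
implementations are checked against brute-force oracles on 1000 random
frames and 100 random interval-train pairs. With the default profile the
recovered split is ≈59.0% stance / 41.0% swing against the generator's
true 60/40 — the ~1 pp stance deficit is the expected one-sample detection
latency of the IC rule (the crossing sample is the first sample *after*
contact) and sits well inside the ±2 pp recovery tolerance.

## Known limitations

* Per-foot CoP only; the two feet are never combined into a whole-body
  CoP, so balance-style analyses are out of scope.
* The zone rule assumes a roughly monotone anteroposterior CoP during
  stance; shuffling gaits (CoP lingering at the rear) will compress the
  later subphases.
* No swing-phase subsegmentation (acceleration / midswing / deceleration):
  a pressure insole is silent during swing.
* The default layout's coordinates are anatomically plausible stand-ins,
  not measured positions of any particular hardware; users with a real
  insole should supply their own layout JSON.
* Absolute CoP-velocity magnitudes depend strongly on the layout geometry
  and the aggregation convention; compare them only within one convention.
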