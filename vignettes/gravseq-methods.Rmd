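---
title: "gravseq: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gravseq: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gravseq quantifies how gravito-inertial acceleration and vibration relate to
nanopore sequencing behaviour during parabolic flight. It covers the whole
chain from raw triaxial accelerometer samples and event-aligned base tables
to the statistical battery, plus synthetic generators for both data streams
so the pipeline is testable end to end without flight data. This vignette
records the models, the tunable parameters, and the design decisions that
were genuinely open.

## Vibration processing

**Magnitude.** The three accelerometer axes are collapsed to
$g = \sqrt{g_x^2 + g_y^2 + g_z^2}$ (Earth-g units), which is invariant to
how the logger was mounted. All downstream work uses this magnitude.

**High-pass filter.** Vibration is isolated from the quasi-static g level
with an IIR high-pass specified in the frequency domain: stopband edge 5 Hz
with at least 60 dB attenuation, passband edge 10 Hz with at most 1 dB
ripple ("unity ripple" is read as 1 dB), at a 5 kHz sample rate. The family
is the minimum-order elliptic design, the family a specs-driven design tool
selects for such constraints; the minimum order is computed from the
standard elliptic-integral order formula on the bilinear-prewarped lowpass
prototype (the installed design helper returns NaN at these extreme
normalized edges, so the order formula is evaluated directly) and the
resulting design is verified against the spec at the band edges. For the
default spec the order is 5 and the realized single-pass attenuation at
5 Hz is 60.004 dB.

The filter is applied in transfer-function form rather than second-order
sections. That choice was checked, not assumed: at order 5 the pole moduli
stay at or below 0.9991 and a 60 s, 1 Hz unit tone leaves a residual below
$10^{-6}$ in the interior after forward-backward filtering — the
doubled-attenuation bound — so double precision is comfortably sufficient
and the extra SOS machinery buys nothing here.

**Zero-phase application.** Filtering runs forward and then backward, so the
effective magnitude response is $|H|^2$ (attenuations double in dB) and the
net phase shift is zero. Edges are handled with odd-reflection padding of
three filter orders and steady-state initial conditions, the standard
forward-backward practice. Two consequences are worth knowing: edge
transients persist for a few filter time constants (about a second here), so
properties such as reversal symmetry hold in the interior of a record rather
than at its ends; and a record must be longer than the padding to be
filterable at all.

**RMS binning and PSD.** RMS vibration is computed in 1 s bins aligned to
the accelerometer's elapsed-time origin, with a trailing partial bin
dropped. Power spectral densities use Welch's method with the common
defaults — 8 segments, 50% overlap, Hamming window, one-sided scaling — all
configurable. Each segment's mean is removed before windowing so the large
static offset (about 1 g) does not leak across the low-frequency bins. The
one-sided PSD integrates to the signal variance within windowing tolerance,
which the tests check against white noise.

## Flight segmentation

The segmentation vocabulary is four labels: *parabola* (reduced-g arc),
*hypergravity* (pull-up/pull-out), *transition* (the short connection
between them), and *other* (everything else). The published analyses cite a
prior procedure whose thresholds are not reproduced here, so the algorithm
is the package's own, with everything configurable:

* smooth the magnitude with a 1 s moving median (median, not mean, so
  vibration bursts do not drag the level);
* hypergravity = smoothed g ≥ 1.2 sustained ≥ 2 s;
* parabola = smoothed g within ±0.07 of the nearest target in
  {0, 0.166, 0.378} and below 0.5, sustained ≥ 5 s; the plateau's target is
  the nearest configured target of its median level, ties toward the lower
  g;
* transition = a gap that directly connects a hypergravity period to an
  adjacent parabola;
* other = the remainder. The output covers the record exactly, without
  overlap; a quiet trace yields a single *other* period.

These defaults reproduce the four-phase vocabulary and the named g levels;
they are not claimed to equal the prior study's unpublished thresholds.

## The synthetic flight

`make_flight()` builds the low-frequency profile from a flight plan —
by default four sets of 5, 6, 4 and 5 parabolas, the first set targeting
Mars g (0.378), Mars g, Lunar g (0.166), 0 g, 0 g, and every later parabola
0 g — as plateaus joined by 3 s cosine ramps, then adds vibration as a
seeded sinusoid-plus-noise mixture. Choices that were genuinely open:

* **Truth boundaries are analytic level crossings.** A construction that
  labels whole ramps as transitions cannot be recovered to within a second
  by any level-based detector: on a 3 s cosine ramp from 1.8 g toward 0 g,
  the 1.2 g crossing sits 1.18 s after the ramp starts. The generator
  therefore places its true period boundaries where the constructed profile
  crosses the defining levels — hypergravity is where the profile is at or
  above the hypergravity threshold, a parabola is where it is within the
  plateau tolerance of its target, and the ramp slivers between are the
  transitions. This is also the physically meaningful reading: the parabola
  *is* the interval during which the aircraft holds the target g. With this
  construction, segmentation recovers all labels and boundaries to about a
  tenth of a second on noisy traces.
* **Plateau durations scale with target g** (0 g: 20 s, Lunar: 30 s,
  Mars: 40 s, each jittered ±2 s), as flown in practice — lower target
  accelerations need shallower arcs. This also gives the duration spread
  that the coverage-versus-duration regression needs to be informative.
* **Residual acceleration in "0 g"** defaults to 0.04 g with 0.005 g
  jitter, the residual level reported for such flights.
* **Vibration** defaults to peaks near 120, 260, 495, 620 and 876 Hz
  (jittered ±2 Hz per seed so peaks never sit bin-exactly) over a broadband
  floor, scaled by 0.5 during parabolas — freefall is smoother than powered
  flight. Peak amplitudes are expressed as per-component RMS, so the
  expected filtered 1 s RMS has the closed form
  $\mathrm{scale}\times\sqrt{\sum r_i^2 + r_b^2}$, which the tests compare
  against measurement. The synthetic vibration rides on the z axis on top
  of the profile; the magnitude channel therefore carries profile plus
  vibration exactly, which is all the analysis consumes.

What the generator does **not** emulate: sensor noise floors and
non-unity frequency response, aerodynamic buffet nonstationarity within a
phase, attitude changes (the magnitude is orientation-free by
construction), or negative-g excursions. Passing tests say the pipeline
recovers what this model plants, not that the model is the aircraft.

## Sequencing metrics

**Representative read quality.** Per-base Phred scores $q$ are converted to
error probabilities $p = 10^{-q/10}$; the read's representative quality is
$q_{\bar p} = -10\log_{10}(\bar p)$ with $\bar p$ the mean per-base error
probability. Averaging on the probability scale makes the score sensitive
to the worst bases: $q_{\bar p}$ never exceeds the arithmetic mean of the
scores (Jensen), with equality only when all bases agree — a property the
tests exercise.

**Translocation time.** An event of $n$ raw-signal samples at rate $f_s$
lasted $1000\,n/f_s$ milliseconds; its inverse is the instantaneous
sequencing rate. The signal rate defaults to 4000 Hz, the standard MinION
rate, and is configurable: published summaries quoting a 7-sample median as
"1.8 ms" imply an effective rate near 3.9 kHz, whereas 7/4000 gives
1.75 ms. The package reports what it computes (1.75 ms at 4 kHz) and leaves
the rate a parameter rather than guessing a dataset-specific value.

**Coverage.** For each period, coverage is the count of aligned bases whose
timestamp falls in the period divided by the 48,502-base lambda genome
length — genome-fold units. Summed over disjoint periods this conserves the
total in-period base count.

**Timestamps and coordinates.** A base's timestamp is its read's start plus
the cumulative length of the preceding events over the signal rate (the
event's start). Genome coordinates are 0-based half-open throughout.

## Timeline integration

Reads and bases are shifted onto the accelerometer clock by a configured
offset and joined in 1 s bins: the bin's quality is the median $q_{\bar p}$
over reads *covering* the bin (interval overlap, point contact included)
and its noise is the median tombo-style `norm_std` over bases *within* the
bin (point membership) — the deliberate asymmetry matches how read-level
and base-level quantities live on the timeline. Additional conventions,
each deterministic and documented because the published text is silent:

* a bin's phase is the phase at its midpoint;
* points exactly on a shared boundary belong to the earlier interval, and
  an interval ending exactly at a period's end is still wholly within it
  (closed containment); reads not wholly inside one period are *spanning*;
* elapsed-time truncation keeps bins with elapsed time ≤ 4000 s inclusive;
* bins without reads or bases carry missing medians and are dropped
  listwise by the regressions.

## The statistical battery

**Stepwise regression.** `stepwise_lm()` reproduces the partial-F
entry/removal procedure: starting from the intercept-only model, add the
candidate (main effects, then pairwise interactions once both parents are
in) with the smallest partial-F p-value below 0.05, then remove any term
whose p-value exceeds 0.10, under the marginality constraint, until stable;
a visited-state guard rules out cycles. R's own `step()` is AIC-based, so
this procedure is implemented directly on `add1()`/`drop1()` F tests. It
reports adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-k-1)$. Quadratic terms are not
considered: "combined effects" is read as pairwise interactions.

One calibration fact matters when interpreting a null result: with three
candidate main effects each tested at 0.05, the chance that *some* term
enters a pure-noise regression is $1 - 0.95^3 \approx 14\%$ per run, and
correlation among candidates only partly reduces it. A no-term result in
roughly 85% of null runs is therefore the procedure working as specified,
not a defect; the tests check the per-candidate entry rate against its
nominal level.

**ANOVA and Tukey.** One-way ANOVA uses the classic between/within
decomposition (via `aov`), with perfect separation guarded to
$F = \infty,\ p = 0$. Pairwise comparisons use the Tukey-Kramer honestly
significant difference with the studentized-range distribution (R evaluates
its CDF by numerical integration), valid under unequal group sizes and
conservative at the family-wise 0.05 level; for two groups it collapses to
the pooled t-test via $q = t\sqrt{2}$, which the tests verify to $10^{-6}$.

**Kolmogorov-Smirnov.** The two-sample, two-sided statistic
$D = \sup_x |F_m(x) - G_n(x)|$ with the asymptotic p-value — appropriate
for the sample sizes this analysis deals in (about $10^5$ and up), where the
exact small-sample distribution is irrelevant. Translocation times are
discretized to whole samples, so ties are ubiquitous; the ECDF definition
of D handles them, and the test is checked against brute-force ECDF
enumeration.

**MAD outliers.** A value is flagged when its distance from the median
exceeds $k$ (default 3) scaled MADs, with the 1.4826 normality constant.
When the MAD is zero — over half the values identical — any value different
from the median is flagged, which is the limit of the rule as stated.

## Synthetic reads

`simulate_reads()` draws read starts as a Poisson process (default
3 reads/s, the throughput scale of one flow cell in such experiments),
aligned-segment lengths as lognormal (default median 1000 bases), and
per-base values from three families:

* dwell times: lognormal parameterized by median and mean
  ($\sigma^2 = 2\ln(\mathrm{mean}/\mathrm{median})$,
  $\mu = \ln(\mathrm{median})$), defaults 1.8 ms / 2.28 ms, discretized to
  whole samples at the signal rate — which reproduces the 7-sample median
  granularity. An inverse-Gaussian alternative was considered and dropped:
  the two are indistinguishable at the moments the analysis consumes, and
  the median/mean parameterization is the one the reported summaries pin
  down.
* Phred scores: rounded normal (default mean 9.5, SD 3, clipped to
  [0, 40]), which puts the representative read quality near 8.5;
* ionic-current noise: lognormal with mean 0.28.

Optional effects couple any of the three families to flight phase (additive
mean shifts), elapsed time, or RMS vibration (linear slopes) — the smallest
model that can plant, and let the battery recover, the relationships the
statistics are built to detect. Reads starting in the first 90 s are
flagged as multiplex-scan (mux) reads and excluded from statistics, as
start-up reads are in practice. The first 90 s emulate the pore-selection
scan; there is no channel-blockage or pore-death dynamics, no basecalling
error structure along a read, and no sequence-dependent dwell — so
agreement on synthetic data validates the computations, not nanopore
chemistry.

## Problem sizes

The test and analysis runs choose sizes that keep the whole suite fast
while leaving every mechanism exercised: long flight profiles are emulated
at 50-250 Hz accelerometer rates with sub-Nyquist vibration peaks (the
segmentation consumes only sub-10-Hz content, so nothing is lost), while
the full 5 kHz rate with the real 120-876 Hz peak set is used for the
spectral and filtering checks on shorter records; translocation-time
comparisons use $10^5$ bases per arm, where the planted 0.125 ms mean shift
is detected with $D \approx 0.025$ and recovered to within 0.02 ms. The
analysis scripts scale aligned-segment lengths down to ~150 bases at the
full 3 reads/s so stage outputs stay around a million bases.

## Known limitations

* The HDF5 (fast5-dialect) reader is not provided; the tabular event
  dialect is the supported interchange format. The schema carries the same
  per-base fields, so an external converter can bridge real fast5 output.
* The segmentation thresholds are this package's defaults, not the prior
  study's; on real traces they should be reviewed against a plotted
  magnitude before trusting phase-level statistics.
* Regression responses are 1 s bin medians; reads longer than a few seconds
  make neighbouring quality bins share reads, so serial correlation
  inflates the apparent significance of slowly varying predictors. The
  package reports what the procedure reports; drawing causal conclusions
  from those p-values on real data needs the same caution the original
  analyses needed.
* The asymptotic KS p-value is inaccurate below a few dozen observations
  per arm; the package targets large samples.
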