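# gravseq

Does vibration and altered gravity change how a nanopore sequencer behaves?
Parabolic flight delivers repeated bouts of hypergravity (~1.8 g), reduced
gravity (Mars 0.378 g, Lunar 0.166 g, 0 g), and strong aircraft vibration —
while a MinION sequences lambda phage DNA next to an accelerometer on a
common baseplate. **gravseq** is an R package plus analysis workflow that
implements the full evaluation chain for such an experiment, for
instrument-performance and astrobiology-instrumentation work:

* **Accelerometer processing** — orientation-independent magnitude
  `g = sqrt(gx² + gy² + gz²)`; minimum-order elliptic high-pass IIR
  (stopband 5 Hz @ 60 dB, passband 10 Hz @ 1 dB, 5 kHz) applied
  forward-backward for zero phase; Welch PSD; RMS vibration in 1 s bins.
* **Flight segmentation** — parabola / transition / hypergravity / other
  periods from the smoothed magnitude, with per-parabola target g, plus the
  period-table file format.
* **Sequencing metrics** — representative read quality
  `q_p̄ = −10·log10(mean(10^(−q/10)))` over per-base Phred scores `q`; base
  translocation time `1000·event_len/f_s` ms from event lengths in
  raw-signal samples; per-base ionic-current noise (`norm_std`); coverage =
  aligned bases per period / 48,502 (lambda genome).
* **Timeline integration** — clock offsets, whole-containment phase
  assignment, and the joint 1 s bin series (median `q_p̄`, median noise,
  RMS vibration, mean g, phase) with a 4000 s elapsed-time cut.
* **Statistics** — stepwise linear regression with pairwise interactions
  (partial-F entry p < 0.05 / removal p > 0.10, hierarchy enforced),
  one-way ANOVA with Tukey–Kramer HSD, two-sample Kolmogorov–Smirnov,
  adjusted R², and MAD-based outlier flags.
* **Synthetic generators** — parabolic-flight accelerometer traces
  (plateaus, cosine ramps, spectrally realistic vibration, ground-truth
  periods) and event-aligned nanopore read tables (Poisson read starts,
  lognormal dwell times discretized to signal samples, configurable
  phase/time/vibration couplings, mux flags) so every stage is testable
  without flight data.

## Worked example

Generate a two-parabola flight, segment it, sequence through it, and test
whether a planted dwell-time shift is detectable:

```r
library(gravseq)

vib <- vibration_model(peak_freqs = c(13, 20), peak_rms = c(0.02, 0.02),
                       broadband_rms = 0.02)
fl  <- make_flight(flight_plan(sets = 2, targets = c(0.378, 0)),
                   vib, seed = 3, sample_rate = 100)
seg <- segment_phases(vibration_magnitude(fl$trace), 100)
seg[seg$label == "parabola", ]
#>      start_s     end_s    label target_g
#> 4   65.58    105.11     parabola    0.378
#> 10 181.47    201.19     parabola    0.000

sr <- simulate_reads(read_model(read_rate = 1), phase_periods(0, 300, "other"),
                     300, seed = 2)
ev <- parse_event_table(sr$events)
c(q_pbar = mean(ev$reads$q_pbar), mean_ms = mean(ev$bases$trans_ms),
  median_ms = median(ev$bases$trans_ms))
#>    q_pbar   mean_ms median_ms
#>     8.467    2.2858    1.7500
```

The parabola periods land within ~0.1 s of the generator's truth with the
right targets; reads average `q_p̄` ≈ 8.5 and dwell ≈ 2.29 ms with a
7-sample (1.75 ms at 4 kHz) median, the regime such experiments report.

The full study-shaped workflow lives in `analysis/01_simulate_flight.R` …
`analysis/06_stats.R`; each stage prints what it found and writes its
tables under `results/`. A complete run prints, among other things:

```
segmented 121 periods (truth: 121)
all labels recovered; max boundary error 0.11 s
quality ~ time/vibration/g: mean_g (adj R2 = 0.444, n = 2315)
phase ANOVA on q_pbar: F = 991.49, p = 0; means: hypergravity 8.66, other 8.46, parabola 8.26
KS flight vs ground dwell: D = 0.0250, p = 0; medians 1.75/1.75 ms; dmean = 0.1211 ms
coverage ~ parabola duration: adj R2 = 0.819 over 20 parabolas
```

i.e. the battery recovers the planted structure: lower read quality at
lower g, a small but highly significant dwell-time shift between flight
and ground with identical medians, and parabola coverage largely explained
by parabola duration.

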