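#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped parabolic flight.
#
# Four sets of 5, 6, 4 and 5 parabolas; the first set targets Mars g, Mars g,
# Lunar g, 0 g, 0 g and all later parabolas target 0 g. The accelerometer is
# emulated at 100 Hz here (the downstream segmentation and RMS statistics
# only need sub-Nyquist vibration content; the full 5 kHz spectral model is
# exercised in the package tests), with vibration peaks placed below the
# 50 Hz Nyquist and freefall vibration scaled to half the powered-flight
# level. Writes the trace and the generator's true period table.

suppressMessages(library(gravseq))
dir.create("results", showWarnings = FALSE)

accel_rate <- 100
vib <- vibration_model(peak_freqs = c(13, 21, 35),
                       peak_rms = c(0.03, 0.025, 0.02),
                       broadband_rms = 0.02)
fl <- make_flight(flight_plan(), vib, seed = 101, sample_rate = accel_rate)

n <- length(fl$trace$gz)
data.table::fwrite(
  data.frame(t = (seq_len(n) - 1) / accel_rate,
             gx = fl$trace$gx, gy = fl$trace$gy, gz = fl$trace$gz),
  "results/accel_trace.csv")
write_periods(fl$periods, "results/periods_true.txt")

par <- fl$periods[fl$periods$label == "parabola", ]
cat(sprintf("flight: %.0f s total, %d parabolas (targets: %s ...)\n",
            fl$total_s, nrow(par),
            paste(par$target_g[1:5], collapse = ", ")))
cat(sprintf("parabola durations %.1f-%.1f s; wrote trace (%d samples) and truth periods\n",
            min(par$end_s - par$start_s), max(par$end_s - par$start_s), n))
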