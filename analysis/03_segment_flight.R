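#!/usr/bin/env Rscript
# Stage 3: flight-phase segmentation, checked against generator truth.
#
# Classifies the smoothed acceleration magnitude into parabola / transition /
# hypergravity / other and compares the recovered periods with the true
# construction intervals from stage 1.

suppressMessages(library(gravseq))

trace <- read_accel_csv("results/accel_trace.csv")
truth <- read_periods("results/periods_true.txt")
seg <- segment_phases(vibration_magnitude(trace), trace$sample_rate)
write_periods(seg, "results/periods.txt")

cat(sprintf("segmented %d periods (truth: %d)\n", nrow(seg), nrow(truth)))
if (nrow(seg) == nrow(truth) && all(seg$label == truth$label)) {
  cat(sprintf("all labels recovered; max boundary error %.2f s\n",
              max(abs(c(seg$start_s - truth$start_s,
                        seg$end_s - truth$end_s)))))
  par_t <- seg$target_g[seg$label == "parabola"]
  cat("recovered parabola targets (first set):",
      paste(par_t[1:5], collapse = ", "), "\n")
} else {
  cat("label sequences differ:\n")
  print(table(seg$label))
  print(table(truth$label))
}
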