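#!/usr/bin/env Rscript
# Stage 5: place reads and bases on the accelerometer timeline and build the
# joint 1 s bin series (median read quality, median ionic-current noise, RMS
# vibration, mean g, phase) that feeds every regression in stage 6.

suppressMessages(library(gravseq))

trace <- read_accel_csv("results/accel_trace.csv")
periods <- read_periods("results/periods.txt")
vibr <- process_vibration(trace)

ev <- parse_event_table("results/events_flight.tsv")
ev <- exclude_mux(ev)
ev <- apply_time_offset(ev, 0)  # generator and accelerometer share a clock

bins <- build_bins(ev$reads, ev$bases, vibr, periods)
bins <- truncate_elapsed(bins, 4000)
write.table(bins, "results/bins.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

lab <- assign_phase(ev$reads$start_s, ev$reads$start_s + ev$reads$duration_s,
                    periods)
cat(sprintf("%d non-mux reads; wholly within a phase: %d (%s)\n",
            nrow(ev$reads), sum(lab != "spanning"),
            paste(sprintf("%s %d", names(table(lab)), table(lab)),
                  collapse = ", ")))
cat(sprintf("bin series: %d bins (<= 4000 s), %d with reads, %d with bases\n",
            nrow(bins), sum(!is.na(bins$median_q_pbar)),
            sum(!is.na(bins$median_norm_std))))
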