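#!/usr/bin/env Rscript
# Stage 6: the statistical battery.
#
#  * stepwise regressions (partial-F entry/removal, pairwise interactions)
#    of binned median read quality and median ionic-current noise on elapsed
#    time, RMS vibration and g level;
#  * one-way ANOVA + Tukey-Kramer HSD of read quality by phase of flight
#    (transition excluded: too few reads);
#  * two-sample KS of ground vs flight base translocation times;
#  * per-parabola coverage regressed on parabola duration;
#  * MAD outlier screen on the binned noise medians.

suppressMessages(library(gravseq))

bins <- read.delim("results/bins.tsv")
periods <- read_periods("results/periods.txt")
evf <- exclude_mux(parse_event_table("results/events_flight.tsv"))
evg <- exclude_mux(parse_event_table("results/events_ground.tsv"))

report <- function(x, path) jsonlite::write_json(
  x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)

cand <- data.frame(elapsed_s = bins$elapsed_s, rms_g = bins$rms_g,
                   mean_g = bins$mean_g)
fit_q <- stepwise_lm(bins$median_q_pbar, cand)
fit_n <- stepwise_lm(bins$median_norm_std, cand)
cat(sprintf("quality ~ time/vibration/g: %s (adj R2 = %.3f, n = %d)\n",
            if (length(fit_q$selected_terms)) paste(fit_q$selected_terms, collapse = " + ")
            else "intercept only", fit_q$adj_r2, fit_q$n))
cat(sprintf("noise   ~ time/vibration/g: %s (adj R2 = %.3f, n = %d)\n",
            if (length(fit_n$selected_terms)) paste(fit_n$selected_terms, collapse = " + ")
            else "intercept only", fit_n$adj_r2, fit_n$n))
report(list(quality = fit_q[c("selected_terms", "coefficients",
                              "term_pvalues", "adj_r2", "n")],
            noise = fit_n[c("selected_terms", "coefficients",
                            "term_pvalues", "adj_r2", "n")]),
       "results/regressions.json")

# phase-of-flight ANOVA on read quality (transition excluded)
lab <- assign_phase(evf$reads$start_s,
                    evf$reads$start_s + evf$reads$duration_s, periods)
keep <- lab %in% c("parabola", "hypergravity", "other")
grp <- split(evf$reads$q_pbar[keep], lab[keep])
an <- anova_oneway(grp)
tk <- tukey_hsd(grp)
cat(sprintf("phase ANOVA on q_pbar: F = %.2f, p = %.3g; means: %s\n",
            an$F, an$p_value,
            paste(sprintf("%s %.2f", names(an$means), an$means),
                  collapse = ", ")))
report(list(F = an$F, p_value = an$p_value, means = as.list(an$means),
            tukey = tk), "results/anova_quality.json")

# ground vs flight translocation-time KS and mean difference
ks <- ks_two_sample(evf$bases$trans_ms, evg$bases$trans_ms)
dmean <- mean(evf$bases$trans_ms) - mean(evg$bases$trans_ms)
cat(sprintf("KS flight vs ground dwell: D = %.4f, p = %.3g; medians %.2f/%.2f ms; dmean = %.4f ms\n",
            ks$D, ks$p_value, median(evf$bases$trans_ms),
            median(evg$bases$trans_ms), dmean))
report(list(D = ks$D, p_value = ks$p_value, mean_diff_ms = dmean,
            median_flight_ms = median(evf$bases$trans_ms),
            median_ground_ms = median(evg$bases$trans_ms)),
       "results/ks.json")

# per-parabola coverage vs duration
par_rows <- periods[periods$label == "parabola", ]
covg <- phase_coverage(evf$bases, par_rows)
fit_c <- stepwise_lm(covg$coverage,
                     data.frame(duration_s = covg$end_s - covg$start_s),
                     max_degree = 1)
cat(sprintf("coverage ~ parabola duration: adj R2 = %.3f over %d parabolas (%.1f-%.1fx fold)\n",
            fit_c$adj_r2, nrow(covg), min(covg$coverage), max(covg$coverage)))
report(fit_c[c("selected_terms", "coefficients", "term_pvalues",
               "adj_r2", "n")], "results/coverage.json")

# MAD screen on binned noise medians
flags <- mad_outliers(bins$median_norm_std[!is.na(bins$median_norm_std)])
cat(sprintf("MAD>3 outliers among %d noise bins: %d (%.2f%%)\n",
            length(flags), sum(flags), 100 * mean(flags)))
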