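# shared fixture builders (everything generated in code; no stored data)

# a minimal event table: `n_bases` per read, constant or supplied columns
tiny_events <- function(read_id = c("r1", "r1", "r2"),
                        channel = c(1, 1, 2),
                        read_start_s = c(10, 10, 20),
                        is_mux = c(FALSE, FALSE, FALSE),
                        genome_pos = c(0, 1, 5),
                        event_len = c(4, 8, 7),
                        norm_mean = 0, norm_std = 0.3, qual = 10) {
  data.frame(read_id = read_id, channel = channel,
             read_start_s = read_start_s, is_mux = is_mux,
             genome_pos = genome_pos, event_len = event_len,
             norm_mean = norm_mean, norm_std = norm_std, qual = qual,
             stringsAsFactors = FALSE)
}

# a low-sample-rate vibration model safe below a 50 Hz Nyquist (peaks sit
# above the 10 Hz high-pass edge so they survive filtering)
low_rate_vib <- function(peak_rms = c(0.02, 0.02), broadband_rms = 0.02) {
  vibration_model(peak_freqs = c(13, 20), peak_rms = peak_rms,
                  broadband_rms = broadband_rms)
}

# a short two-parabola flight plan for quick end-to-end runs
short_plan <- function(targets = c(0.378, 0)) {
  flight_plan(sets = c(length(targets)), targets = targets,
              lead_in_s = 40, tail_s = 30, gap_s = 25)
}

# brute-force two-sample KS statistic by ECDF enumeration
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# brute-force one-way ANOVA F from sums of squares
anova_F_oracle <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}
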