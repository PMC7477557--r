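test_that("flight generation is deterministic and plan-shaped", {
  fl1 <- make_flight(short_plan(), low_rate_vib(), seed = 21, sample_rate = 50)
  fl2 <- make_flight(short_plan(), low_rate_vib(), seed = 21, sample_rate = 50)
  expect_identical(fl1$trace$gz, fl2$trace$gz)
  expect_identical(fl1$periods, fl2$periods)
  fl3 <- make_flight(short_plan(), low_rate_vib(), seed = 22, sample_rate = 50)
  expect_false(identical(fl1$trace$gz, fl3$trace$gz))

  # default plan: 5 + 6 + 4 + 5 = 20 parabolas, full non-overlapping cover
  fl <- make_flight(flight_plan(), low_rate_vib(), seed = 23, sample_rate = 50)
  expect_equal(sum(fl$periods$label == "parabola"), 20)
  expect_equal(fl$periods$target_g[fl$periods$label == "parabola"][1:5],
               c(0.378, 0.378, 0.166, 0, 0))
  expect_equal(fl$periods$start_s[-1], fl$periods$end_s[-nrow(fl$periods)])

  expect_error(make_flight(short_plan(), vibration_model(), seed = 1,
                           sample_rate = 100),
               "Nyquist")
})

test_that("parabola plateaus hold their target levels", {
  fl <- make_flight(short_plan(c(0.378, 0.166, 0, 0)),
                    low_rate_vib(broadband_rms = 0), seed = 24,
                    sample_rate = 50)
  m <- vibration_magnitude(fl$trace)
  t <- (seq_along(m) - 1) / 50
  par <- fl$periods[fl$periods$label == "parabola", ]
  for (i in seq_len(nrow(par))) {
    # interior of the plateau (clear of the entry/exit ramps)
    idx <- t > par$start_s[i] + 3 & t < par$end_s[i] - 3
    sm <- stats::runmed(m[idx], 51)
    expect_lt(max(abs(sm - max(par$target_g[i], 0.04))), 0.07)
  }
})

test_that("expected filtered RMS composes component variances", {
  v <- vibration_model(peak_freqs = 30, peak_rms = 0.05, broadband_rms = 0)
  expect_equal(flight_truth_rms(v, "other"), 0.05)
  v <- vibration_model(peak_freqs = numeric(0), peak_rms = numeric(0),
                       broadband_rms = 0.03)
  expect_equal(flight_truth_rms(v, "other"), 0.03)
  v <- vibration_model(peak_freqs = c(30, 60), peak_rms = c(0.03, 0.04),
                       broadband_rms = 0)
  expect_equal(flight_truth_rms(v, "hypergravity"), 0.05)
  expect_equal(flight_truth_rms(v, "parabola"), 0.025)  # phase scale 0.5
  expect_error(flight_truth_rms(v, "descent"), "unknown phase")
})

test_that("generated vibration carries the configured spectral peaks", {
  plan <- flight_plan(sets = 1, targets = 0, lead_in_s = 60, tail_s = 60)
  vib <- vibration_model()  # full 120-876 Hz peak set
  fl <- make_flight(plan, vib, seed = 25, sample_rate = 5000)
  vibr <- process_vibration(fl$trace)
  p <- welch_psd(vibr$g_f, 5000)
  df <- diff(p$freq_hz[1:2])
  for (f0 in vib$peak_freqs) {
    # peak jittered by up to 2 Hz; look for the local max nearby
    near <- which(abs(p$freq_hz - f0) < 10)
    peak_f <- p$freq_hz[near[which.max(p$power[near])]]
    expect_lt(abs(peak_f - f0), 2 + df + 1e-9)
  }
  # measured per-phase RMS close to the closed-form expectation
  bins <- build_bins(NULL, NULL, vibr, fl$periods)
  other_rms <- mean(bins$rms_g[bins$phase == "other"], na.rm = TRUE)
  par_rms <- mean(bins$rms_g[bins$phase == "parabola"], na.rm = TRUE)
  expect_lt(abs(other_rms - flight_truth_rms(vib, "other")) /
              flight_truth_rms(vib, "other"), 0.15)
  expect_lt(par_rms, other_rms)  # freefall is smoother
  # with all vibration off, filtered RMS collapses to ~0
  quiet <- make_flight(short_plan(), vibration_model(
    peak_freqs = numeric(0), peak_rms = numeric(0), broadband_rms = 0),
    seed = 26, sample_rate = 100)
  vq <- process_vibration(quiet$trace)
  expect_lt(max(vq$rms_bins$rms), 0.02)
})

test_that("genome simulation is deterministic ACGT of the requested length", {
  g1 <- simulate_genome(10, seed = 1)
  g2 <- simulate_genome(10, seed = 1)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 10)
  expect_true(grepl("^[ACGT]+$", g1))
  path <- withr::local_tempfile(fileext = ".fasta")
  simulate_genome(48502, seed = 2, path = path)
  expect_match(readLines(path, n = 1), "length=48502")
  expect_error(simulate_genome(0), "positive")
})

test_that("read simulation is deterministic and hits its distribution targets", {
  per <- phase_periods(0, 400, "other")
  s1 <- simulate_reads(read_model(read_rate = 1, trans_mean_ms = 2.3),
                       per, 400, seed = 31)
  s2 <- simulate_reads(read_model(read_rate = 1, trans_mean_ms = 2.3),
                       per, 400, seed = 31)
  expect_identical(s1$events, s2$events)

  ev <- parse_event_table(s1$events)
  expect_gt(nrow(ev$bases), 1e5)
  # sample mean translocation within 1% of the model mean
  expect_lt(abs(mean(ev$bases$trans_ms) - 2.3) / 2.3, 0.01)
  # median lands on the 7-sample granularity of a 1.8 ms median at 4 kHz
  expect_equal(median(ev$bases$event_len), 7)
  expect_equal(median(ev$bases$trans_ms), 1.75)
  # noise mean near its target
  expect_lt(abs(mean(ev$bases$norm_std) - 0.28) / 0.28, 0.02)
  # early reads are mux-flagged
  expect_true(all(ev$reads$is_mux[ev$reads$start_s < 90]))
  expect_false(any(ev$reads$is_mux[ev$reads$start_s > 90]))
})

test_that("degenerate quality model gives every read that exact quality", {
  per <- phase_periods(0, 100, "other")
  s <- simulate_reads(read_model(read_rate = 0.5, qual_mean = 9, qual_sd = 0),
                      per, 100, seed = 32)
  ev <- parse_event_table(s$events)
  expect_equal(ev$reads$q_pbar, rep(9, nrow(ev$reads)))
})

test_that("a planted linear time trend on quality is recovered with its coefficient", {
  fl <- make_flight(short_plan(), low_rate_vib(), seed = 33, sample_rate = 50)
  slope <- 0.02  # Phred units per second
  model <- read_model(read_rate = 2, read_len_meanlog = log(200),
                      effects = list(qual_time = slope))
  sr <- simulate_reads(model, fl$periods, fl$total_s, seed = 34)
  ev <- exclude_mux(parse_event_table(sr$events))
  vibr <- process_vibration(fl$trace)
  bins <- build_bins(ev$reads, ev$bases, vibr, fl$periods)
  fit <- stepwise_lm(bins$median_q_pbar,
                     data.frame(elapsed_s = bins$elapsed_s,
                                rms_g = bins$rms_g, mean_g = bins$mean_g))
  expect_true("elapsed_s" %in% fit$selected_terms)
  est <- fit$coefficients[["elapsed_s"]]
  se <- summary(fit$fit)$coefficients["elapsed_s", "Std. Error"]
  expect_lt(abs(est - slope), 1.96 * se + 0.002)
})

test_that("read simulation validates its inputs", {
  expect_error(simulate_reads(read_model(), phase_periods(0, 1, "other")[0, ],
                              100, seed = 1),
               "periods")
  expect_error(read_model(read_rate = -1), "positive")
  expect_error(read_model(effects = list(bogus = 1)), "unknown effect")
})
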