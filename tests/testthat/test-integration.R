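test_that("time offsets shift records and compose to identity", {
  reads <- data.frame(start_s = c(5, 10), duration_s = c(1, 2))
  expect_equal(apply_time_offset(reads, 0), reads)
  expect_equal(apply_time_offset(reads, 2.5)$start_s, c(7.5, 12.5))
  expect_equal(apply_time_offset(apply_time_offset(reads, 10), -10), reads)
  expect_error(apply_time_offset(reads, Inf), "finite")
})

test_that("phase assignment requires whole containment, with earlier-period ties", {
  per <- phase_periods(c(90, 96, 98), c(96, 98, 118),
                       c("other", "transition", "parabola"), c(NA, NA, 0))
  expect_equal(assign_phase(100, 105, per), "parabola")
  expect_equal(assign_phase(97, 105, per), "spanning")
  # closed containment: interval ending exactly at the period end is within
  expect_equal(assign_phase(100, 118, per), "parabola")
  # zero-length interval at a shared boundary -> earlier period
  expect_equal(assign_phase(98, 98, per), "transition")
  # out of covered range
  expect_equal(assign_phase(200, 201, per), "spanning")
  expect_error(assign_phase(5, 4, per), "start after end")
})

test_that("phase assignment partitions reads", {
  fl <- make_flight(short_plan(), low_rate_vib(), seed = 5, sample_rate = 100)
  sr <- simulate_reads(read_model(read_rate = 1, read_len_meanlog = log(200)),
                       fl$periods, fl$total_s, seed = 6)
  ev <- parse_event_table(sr$events)
  lab <- assign_phase(ev$reads$start_s, ev$reads$start_s + ev$reads$duration_s,
                      fl$periods)
  expect_true(all(lab %in% c("parabola", "transition", "hypergravity",
                             "other", "spanning")))
  counts <- table(factor(lab, levels = c("parabola", "transition",
                                         "hypergravity", "other", "spanning")))
  expect_equal(sum(counts), nrow(ev$reads))
})

fake_vib <- function(n_bins, rms = 0) {
  list(rms_bins = data.frame(bin_start_s = seq_len(n_bins) - 1,
                             rms = rep(rms, n_bins)))
}

test_that("bin medians aggregate reads covering and bases within each bin", {
  per <- phase_periods(0, 10, "other")
  # one read with q_pbar 8 covering bins starting 3..7
  reads <- data.frame(start_s = 3, duration_s = 4.5, q_pbar = 8)
  bins <- build_bins(reads, NULL, fake_vib(10), per)
  expect_equal(which(!is.na(bins$median_q_pbar)), 4:8)
  expect_equal(bins$median_q_pbar[4:8], rep(8, 5))

  # three overlapping reads -> median of {8, 9, 10}
  reads <- data.frame(start_s = c(0, 0, 0), duration_s = c(10, 10, 10),
                      q_pbar = c(8, 9, 10))
  bins <- build_bins(reads, NULL, fake_vib(10), per)
  expect_equal(bins$median_q_pbar, rep(9, 10))

  # bases use point membership; empty bins carry NA
  bases <- data.frame(t_s = c(2.1, 2.9, 5.5), norm_std = c(0.2, 0.4, 0.9))
  bins <- build_bins(NULL, bases, fake_vib(10), per)
  expect_equal(bins$median_norm_std[3], 0.3)
  expect_equal(bins$median_norm_std[6], 0.9)
  expect_true(all(is.na(bins$median_norm_std[-c(3, 6)])))
  expect_equal(bins$phase, rep("other", 10))
})

test_that("bin construction is insensitive to record order", {
  per <- phase_periods(0, 20, "other")
  set.seed(8)
  reads <- data.frame(start_s = runif(50, 0, 18), duration_s = runif(50, 0.5, 5),
                      q_pbar = rnorm(50, 9))
  bases <- data.frame(t_s = runif(500, 0, 20), norm_std = rlnorm(500, -1.3, 0.2))
  b1 <- build_bins(reads, bases, fake_vib(20), per)
  b2 <- build_bins(reads[sample(50), ], bases[sample(500), ], fake_vib(20), per)
  expect_equal(b1, b2)
})

test_that("elapsed-time truncation keeps bins at or below the cut", {
  per <- phase_periods(0, 5000, "other")
  bins <- build_bins(NULL, NULL, fake_vib(5000), per)
  expect_equal(nrow(truncate_elapsed(bins)), 4001)  # inclusive at 4000 s
  expect_equal(nrow(truncate_elapsed(bins, Inf)), 5000)
  expect_equal(nrow(truncate_elapsed(bins[0, ], 100)), 0)
  expect_error(truncate_elapsed(bins, -1), "positive")
})
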