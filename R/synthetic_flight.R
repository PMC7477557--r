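#' Parabolic-flight plan
#'
#' Describes the low-frequency structure of a parabolic flight: sets of
#' parabolas, per-parabola target g levels, plateau durations, and ramp
#' shapes. The default plan mirrors a typical research flight: four sets of
#' 5, 6, 4 and 5 parabolas, the first set targeting Mars g, Mars g, Lunar g,
#' 0 g, 0 g and all later parabolas targeting 0 g. Parabola plateau duration
#' scales with the target (zero-g arcs are the shortest, Mars arcs the
#' longest, as flown in practice), with a small per-parabola jitter.
#'
#' Each parabola is flown as pull-up hypergravity, reduced-g arc, pull-out
#' hypergravity, with smooth cosine ramps of \code{ramp_s} seconds between
#' plateau levels. During "0 g" plateaus a small residual acceleration
#' remains (default 0.04 g with 0.005 g jitter, matching the residual levels
#' reported for such flights).
#'
#' @param sets Parabola counts per set.
#' @param targets Per-parabola target g levels, in flight order; default:
#'   first set \code{c(0.378, 0.378, 0.166, 0, 0)}, all others 0.
#' @param parabola_s Named plateau durations (s) keyed by target g.
#' @param parabola_jitter_s Half-width of the uniform duration jitter (s).
#' @param hyper_s Hypergravity plateau duration (s).
#' @param hyper_g Hypergravity level (g).
#' @param base_g Level-flight acceleration (g).
#' @param ramp_s Cosine ramp duration between plateaus (s).
#' @param gap_s Level-flight gap between parabolas within a set (s).
#' @param set_break_s Break between sets (s).
#' @param lead_in_s,tail_s Level flight before/after the parabolas (s).
#' @param zero_g_residual,zero_g_jitter Residual acceleration during 0 g
#'   plateaus: mean and jitter SD (g).
#' @param plateau_tol Level tolerance defining where a reduced-g arc truly
#'   begins/ends on a ramp (g); also the hypergravity boundary is placed
#'   where a ramp crosses \code{hyper_thresh}.
#' @param hyper_thresh Hypergravity boundary level (g).
#' @return An object of class \code{flight_plan}.
#' @export
flight_plan <- function(sets = c(5, 6, 4, 5),
                        targets = NULL,
                        parabola_s = c("0" = 20, "0.166" = 30, "0.378" = 40),
                        parabola_jitter_s = 2,
                        hyper_s = 20, hyper_g = 1.8, base_g = 1.0,
                        ramp_s = 3, gap_s = 25, set_break_s = 120,
                        lead_in_s = 120, tail_s = 60,
                        zero_g_residual = 0.04, zero_g_jitter = 0.005,
                        plateau_tol = 0.07, hyper_thresh = 1.2) {
  if (any(sets <= 0)) stop_input("parabola counts must be positive")
  n_par <- sum(sets)
  if (is.null(targets)) {
    targets <- rep(0, n_par)
    first <- c(0.378, 0.378, 0.166, 0, 0)
    targets[seq_len(min(length(first), sets[1]))] <-
      first[seq_len(min(length(first), sets[1]))]
  }
  if (length(targets) != n_par)
    stop_input("targets must have one entry per parabola (", n_par, ")")
  if (any(targets < 0 | targets >= 1))
    stop_input("targets must be in [0, 1)")
  structure(list(sets = sets, targets = targets, parabola_s = parabola_s,
                 parabola_jitter_s = parabola_jitter_s, hyper_s = hyper_s,
                 hyper_g = hyper_g, base_g = base_g, ramp_s = ramp_s,
                 gap_s = gap_s, set_break_s = set_break_s,
                 lead_in_s = lead_in_s, tail_s = tail_s,
                 zero_g_residual = zero_g_residual,
                 zero_g_jitter = zero_g_jitter,
                 plateau_tol = plateau_tol, hyper_thresh = hyper_thresh),
            class = "flight_plan")
}

#' Aircraft vibration model
#'
#' Vibration as a seeded mixture of sinusoidal peaks plus broadband noise,
#' scaled per flight phase (freefall is smoother than powered flight). Peak
#' frequencies default to the bands observed on such aircraft
#' (~120, 260, 495, 620, 876 Hz) and are jittered by up to \code{freq_jitter_hz}
#' per seed so spectral peaks do not sit bin-exactly.
#'
#' @param peak_freqs Sinusoid frequencies (Hz); must stay below Nyquist.
#' @param peak_rms Per-peak RMS amplitude (g).
#' @param broadband_rms Broadband (white) RMS (g).
#' @param phase_scale Named per-label RMS multipliers; parabola defaults to
#'   0.5, everything else 1.
#' @param freq_jitter_hz Uniform frequency jitter half-width (Hz).
#' @return An object of class \code{vibration_model}.
#' @export
vibration_model <- function(peak_freqs = c(120, 260, 495, 620, 876),
                            peak_rms = c(0.03, 0.025, 0.02, 0.015, 0.01),
                            broadband_rms = 0.02,
                            phase_scale = c(parabola = 0.5, transition = 1,
                                            hypergravity = 1, other = 1),
                            freq_jitter_hz = 2) {
  if (length(peak_rms) != length(peak_freqs))
    stop_input("peak_rms must match peak_freqs")
  if (any(peak_rms < 0) || broadband_rms < 0)
    stop_input("RMS values must be nonnegative")
  structure(list(peak_freqs = peak_freqs, peak_rms = peak_rms,
                 broadband_rms = broadband_rms, phase_scale = phase_scale,
                 freq_jitter_hz = freq_jitter_hz),
            class = "vibration_model")
}

# cosine ramp from l1 to l2 over idx in [0, 1]
cos_ramp <- function(frac, l1, l2) l1 + (l2 - l1) * (1 - cos(pi * frac)) / 2

# time (s from ramp start) at which a cosine ramp l1 -> l2 (duration r)
# crosses level c; NA if not crossed
ramp_crossing <- function(l1, l2, r, c) {
  u <- 1 - 2 * (c - l1) / (l2 - l1)
  if (u < -1 || u > 1) return(NA_real_)
  r * acos(u) / pi
}

#' Generate a synthetic parabolic-flight accelerometer trace
#'
#' Builds the low-frequency g-level profile from the flight plan (plateaus
#' joined by cosine ramps), adds seeded sinusoid-plus-noise vibration scaled
#' per phase, and returns the trace together with the true phase periods.
#' Truth boundaries are the analytic level crossings of the constructed
#' profile: a hypergravity period is where the profile is at or above
#' \code{plan$hyper_thresh}, a parabola is where it is within
#' \code{plan$plateau_tol} of its target, and the ramp slivers between them
#' are transitions — so the truth matches what the levels mean, not merely
#' where ramps were stitched.
#'
#' The synthetic vibration is injected along the z axis on top of the
#' profile (gx = gy = 0), so the magnitude channel carries profile plus
#' vibration exactly.
#'
#' @param plan A [flight_plan()].
#' @param vib A [vibration_model()].
#' @param seed Integer seed; the same seed yields a bit-identical trace.
#' @param sample_rate Accelerometer sample rate (Hz), default 5000.
#' @return A list of class \code{synthetic_flight}: \code{trace}
#'   ([accel_trace()]), \code{periods} (true [phase_periods()]), and
#'   \code{total_s}.
#' @export
make_flight <- function(plan = flight_plan(), vib = vibration_model(),
                        seed = 1, sample_rate = 5000) {
  if (any(vib$peak_freqs >= sample_rate / 2))
    stop_input("vibration peak frequencies must be below Nyquist")
  if (any(c(plan$hyper_s, plan$ramp_s) < 2 / sample_rate))
    stop_input("phase durations too short for this sample rate")
  set.seed(seed)

  # --- plateau sequence --------------------------------------------------
  # each element: level, duration, base label for the plateau
  segs <- list()
  push <- function(level, dur, lab) segs[[length(segs) + 1]] <<- list(
    level = level, dur = dur, lab = lab)
  push(plan$base_g, plan$lead_in_s, "other")
  p_i <- 0
  for (s in seq_along(plan$sets)) {
    for (j in seq_len(plan$sets[s])) {
      p_i <- p_i + 1
      tg <- plan$targets[p_i]
      dur_key <- as.character(tg)
      base_dur <- if (dur_key %in% names(plan$parabola_s))
        plan$parabola_s[[dur_key]] else plan$parabola_s[[length(plan$parabola_s)]]
      dur <- base_dur + runif(1, -plan$parabola_jitter_s, plan$parabola_jitter_s)
      level <- if (tg == 0)
        max(0, plan$zero_g_residual + rnorm(1, 0, plan$zero_g_jitter)) else
        tg + rnorm(1, 0, plan$zero_g_jitter)
      push(plan$hyper_g, plan$hyper_s, "hypergravity")
      push(level, dur, "parabola")
      push(plan$hyper_g, plan$hyper_s, "hypergravity")
      if (j < plan$sets[s]) push(plan$base_g, plan$gap_s, "other")
    }
    if (s < length(plan$sets)) push(plan$base_g, plan$set_break_s, "other")
  }
  push(plan$base_g, plan$tail_s, "other")

  # --- low-frequency profile on the sample grid --------------------------
  n_seg <- length(segs)
  levels <- vapply(segs, `[[`, numeric(1), "level")
  durs <- vapply(segs, `[[`, numeric(1), "dur")
  labs <- vapply(segs, `[[`, character(1), "lab")
  total_s <- sum(durs) + (n_seg - 1) * plan$ramp_s
  n <- floor(total_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  lowf <- numeric(n)
  # plateau start times
  starts <- cumsum(c(0, durs[-n_seg] + plan$ramp_s))
  for (i in seq_len(n_seg)) {
    idx <- t >= starts[i] & t < starts[i] + durs[i]
    lowf[idx] <- levels[i]
    if (i < n_seg) {
      r0 <- starts[i] + durs[i]
      idx <- t >= r0 & t < r0 + plan$ramp_s
      lowf[idx] <- cos_ramp((t[idx] - r0) / plan$ramp_s, levels[i], levels[i + 1])
    }
  }

  # --- truth periods from analytic crossings -----------------------------
  # boundary between plateau i and i+1 sits inside the connecting ramp
  targets_seq <- plan$targets
  tol <- plan$plateau_tol; hthr <- plan$hyper_thresh
  cuts <- numeric(n_seg - 1)   # default: ramp midpoint
  cuts2 <- rep(NA_real_, n_seg - 1)  # second boundary for hyper<->parabola ramps
  for (i in seq_len(n_seg - 1)) {
    r0 <- starts[i] + durs[i]
    l1 <- levels[i]; l2 <- levels[i + 1]
    pair <- paste(labs[i], labs[i + 1])
    if (pair %in% c("other hypergravity", "hypergravity other")) {
      cuts[i] <- r0 + ramp_crossing(l1, l2, plan$ramp_s, hthr)
    } else if (pair == "hypergravity parabola") {
      tg <- if (labs[i + 1] == "parabola") {
        # target of this parabola: nearest configured meaning its plan target
        targets_seq[sum(labs[seq_len(i + 1)] == "parabola")]
      } else NA
      cuts[i] <- r0 + ramp_crossing(l1, l2, plan$ramp_s, hthr)
      cuts2[i] <- r0 + ramp_crossing(l1, l2, plan$ramp_s, tg + tol)
    } else if (pair == "parabola hypergravity") {
      tg <- targets_seq[sum(labs[seq_len(i)] == "parabola")]
      cuts[i] <- r0 + ramp_crossing(l1, l2, plan$ramp_s, tg + tol)
      cuts2[i] <- r0 + ramp_crossing(l1, l2, plan$ramp_s, hthr)
    } else {
      cuts[i] <- r0 + plan$ramp_s / 2
    }
  }
  # assemble: walk segments, emitting [prev, cut) with the segment's label,
  # plus a transition sliver where cuts2 applies
  p_start <- numeric(0); p_end <- numeric(0); p_lab <- character(0)
  p_tg <- numeric(0)
  prev <- 0
  par_i <- 0
  for (i in seq_len(n_seg)) {
    seg_end <- if (i < n_seg) cuts[i] else total_s
    tg <- if (labs[i] == "parabola") {
      par_i <- par_i + 1
      targets_seq[par_i]
    } else NA_real_
    p_start <- c(p_start, prev); p_end <- c(p_end, seg_end)
    p_lab <- c(p_lab, labs[i]); p_tg <- c(p_tg, tg)
    prev <- seg_end
    if (i < n_seg && !is.na(cuts2[i])) {  # transition sliver on the ramp
      p_start <- c(p_start, prev); p_end <- c(p_end, cuts2[i])
      p_lab <- c(p_lab, "transition"); p_tg <- c(p_tg, NA_real_)
      prev <- cuts2[i]
    }
  }
  # merge consecutive periods with identical labels (adjacent hypergravity
  # around a short gap never occurs; adjacent "other" does at set breaks)
  keep <- c(TRUE, p_lab[-1] != p_lab[-length(p_lab)] |
              p_lab[-1] == "parabola")
  merged_start <- p_start[keep]
  grp <- cumsum(keep)
  merged_end <- tapply(p_end, grp, max)
  periods <- phase_periods(merged_start, as.numeric(merged_end),
                           p_lab[keep], p_tg[keep])

  # --- vibration ---------------------------------------------------------
  scale <- rep(1, n)
  lab_at <- period_label_at(t, periods)
  for (lb in names(vib$phase_scale)) scale[lab_at == lb] <- vib$phase_scale[[lb]]
  v <- numeric(n)
  if (length(vib$peak_freqs) > 0) {
    f <- vib$peak_freqs + runif(length(vib$peak_freqs),
                                -vib$freq_jitter_hz, vib$freq_jitter_hz)
    ph <- runif(length(f), 0, 2 * pi)
    for (k in seq_along(f))
      v <- v + vib$peak_rms[k] * sqrt(2) * sin(2 * pi * f[k] * t + ph[k])
  }
  if (vib$broadband_rms > 0) v <- v + rnorm(n, 0, vib$broadband_rms)
  gz <- lowf + scale * v

  structure(list(trace = accel_trace(gx = numeric(n), gy = numeric(n),
                                     gz = gz, sample_rate = sample_rate),
                 periods = periods, total_s = total_s, plan = plan, vib = vib,
                 seed = seed),
            class = "synthetic_flight")
}

#' Expected filtered RMS vibration for a phase
#'
#' Closed-form expectation of the 1-s RMS of the high-pass-filtered vibration
#' during a phase: independent components add in variance, so the expected
#' RMS is the phase scale times
#' \code{sqrt(sum(peak_rms^2) + broadband_rms^2)} (the high-pass filter
#' removes a negligible fraction of the broadband power).
#'
#' @param vib A [vibration_model()].
#' @param label Phase label.
#' @return Expected RMS (g).
#' @export
flight_truth_rms <- function(vib, label) {
  if (!label %in% names(vib$phase_scale))
    stop_input("unknown phase label: ", label)
  vib$phase_scale[[label]] *
    sqrt(sum(vib$peak_rms^2) + vib$broadband_rms^2)
}
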