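#' Triaxial accelerometer trace
#'
#' Container for a raw triaxial acceleration recording at a fixed sample rate.
#' Time is implied: sample \code{i} is at \code{(i - 1) / sample_rate} seconds
#' from recording start. Units are Earth-g on all three axes.
#'
#' @param gx,gy,gz Numeric vectors of equal length, acceleration in g units.
#' @param sample_rate Sampling frequency in Hz (default 5000, the rate of the
#'   flight-mounted data logger).
#' @return An object of class \code{accel_trace}.
#' @export
accel_trace <- function(gx, gy, gz, sample_rate = 5000) {
  if (length(gx) != length(gy) || length(gy) != length(gz))
    stop_input("gx, gy, gz must have the same length")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop_input("sample_rate must be a positive scalar")
  structure(list(gx = as.numeric(gx), gy = as.numeric(gy), gz = as.numeric(gz),
                 sample_rate = sample_rate),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %d samples @ %g Hz (%.1f s)\n",
              length(x$gx), x$sample_rate, length(x$gx) / x$sample_rate))
  invisible(x)
}

#' Orientation-independent acceleration magnitude
#'
#' Collapses the three axes to \code{sqrt(gx^2 + gy^2 + gz^2)}, a vibration
#' measure independent of how the logger was mounted.
#'
#' @param trace An [accel_trace()].
#' @return Numeric vector of magnitudes (g units), same length as the axes.
#' @export
vibration_magnitude <- function(trace) {
  if (!inherits(trace, "accel_trace")) stop_input("trace must be an accel_trace")
  sqrt(trace$gx^2 + trace$gy^2 + trace$gz^2)
}

#' High-pass filter specification
#'
#' Frequency-domain specification of the vibration high-pass filter:
#' stopband edge with a required attenuation, passband edge with an allowed
#' ripple, at a given sample rate. Defaults follow the flight analysis
#' (stopband 5 Hz at 60 dB, passband 10 Hz with 1 dB ripple, 5 kHz).
#'
#' @param stop_hz Stopband edge (Hz).
#' @param pass_hz Passband edge (Hz); must exceed \code{stop_hz}.
#' @param stop_atten_db Minimum stopband attenuation (dB, positive).
#' @param pass_ripple_db Maximum passband ripple (dB). "Unity ripple" is read
#'   as 1 dB.
#' @param sample_rate Sample rate (Hz).
#' @return An object of class \code{filter_spec}.
#' @export
filter_spec <- function(stop_hz = 5, pass_hz = 10, stop_atten_db = 60,
                        pass_ripple_db = 1, sample_rate = 5000) {
  if (!(stop_hz > 0 && stop_hz < pass_hz && pass_hz < sample_rate / 2))
    stop_input("need 0 < stop_hz < pass_hz < sample_rate/2")
  if (stop_atten_db <= 0) stop_input("stop_atten_db must be positive")
  if (pass_ripple_db <= 0) stop_input("pass_ripple_db must be positive")
  structure(list(stop_hz = stop_hz, pass_hz = pass_hz,
                 stop_atten_db = stop_atten_db, pass_ripple_db = pass_ripple_db,
                 sample_rate = sample_rate),
            class = "filter_spec")
}

# Minimum elliptic-filter order for a high-pass meeting `spec`.
# Standard elliptic order formula on the bilinear-prewarped lowpass prototype:
# n >= K(k) K'(k1) / (K'(k) K(k1)), selectivity k = tan(pi f_stop/fs)/tan(pi f_pass/fs),
# discrimination k1 = sqrt((10^(Rp/10)-1)/(10^(Rs/10)-1)).
min_elliptic_order <- function(spec) {
  k <- tan(pi * spec$stop_hz / spec$sample_rate) /
       tan(pi * spec$pass_hz / spec$sample_rate)
  k1 <- sqrt((10^(spec$pass_ripple_db / 10) - 1) /
             (10^(spec$stop_atten_db / 10) - 1))
  K <- function(m) pracma::ellipke(m)$k  # complete elliptic integral, modulus^2
  ceiling((K(k^2) * K(1 - k1^2)) / (K(1 - k^2) * K(k1^2)))
}

#' Design the vibration high-pass filter
#'
#' Designs the minimum-order elliptic IIR high-pass filter meeting a
#' [filter_spec()]: single-pass magnitude at or below
#' \code{-stop_atten_db} dB for frequencies up to the stopband edge, and within
#' \code{pass_ripple_db} of unity from the passband edge up. The minimum order
#' is computed from the elliptic-integral order formula and the design is
#' verified against the spec at the band edges (the order is bumped if
#' floating-point slack ever leaves the stopband short).
#'
#' @param spec A [filter_spec()].
#' @return An object of class \code{highpass_filter} with transfer-function
#'   coefficients \code{b}, \code{a}, the realized \code{order}, and the spec.
#' @export
design_highpass <- function(spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) stop_input("spec must be a filter_spec")
  w_pass <- 2 * spec$pass_hz / spec$sample_rate  # normalized (Nyquist = 1)
  ord <- min_elliptic_order(spec)
  for (n in ord:(ord + 2)) {
    filt <- signal::ellip(n, spec$pass_ripple_db, spec$stop_atten_db,
                          w_pass, "high")
    out <- structure(list(b = as.numeric(filt$b), a = as.numeric(filt$a),
                          order = n, spec = spec),
                     class = "highpass_filter")
    atten <- -20 * log10(filter_response(out, spec$stop_hz))
    if (atten >= spec$stop_atten_db - 1e-6) return(out)
  }
  stop("elliptic design failed to meet the stopband specification")
}

#' Frequency-response magnitude of a designed filter
#'
#' Evaluates the single-pass magnitude response \code{|H(f)|} of a
#' \code{highpass_filter} at the given frequencies.
#'
#' @param filt A \code{highpass_filter} from [design_highpass()].
#' @param freqs_hz Frequencies (Hz) at which to evaluate.
#' @return Numeric vector of magnitude responses (linear scale).
#' @export
filter_response <- function(filt, freqs_hz) {
  if (!inherits(filt, "highpass_filter")) stop_input("filt must be a highpass_filter")
  z <- exp(-1i * 2 * pi * freqs_hz / filt$spec$sample_rate)
  nb <- length(filt$b); na <- length(filt$a)
  num <- vapply(z, function(zz) sum(filt$b * zz^(0:(nb - 1))), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(0:(na - 1))), complex(1))
  Mod(num / den)
}

# one IIR pass, direct-form with initial state zi (difference-equation form),
# vectorized through stats::filter: a(z) y = b(z) x + p(z), where the
# polynomial p carries the initial conditions (p[k] = zi[k], k = 1..n-1).
iir_pass <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  u <- stats::filter(c(rep(0, n - 1), x), b, method = "convolution", sides = 1)
  u <- as.numeric(u)[n:(n + length(x) - 1)]
  u[seq_len(n - 1)] <- u[seq_len(n - 1)] + zi
  as.numeric(stats::filter(u, -a[2:n], method = "recursive"))
}

# steady-state initial state (unit-step state vector), as in MATLAB filtfilt:
# solves the direct-form-II-transposed state fixed point for a unit input.
steady_state_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  A <- diag(n - 1)
  A[, 1] <- A[, 1] + a[2:n]
  idx <- cbind(seq_len(n - 2), seq_len(n - 2) + 1)
  A[idx] <- A[idx] - 1
  solve(A, b[2:n] - b[1] * a[2:n])
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies an IIR filter forward and then backward so the net phase shift is
#' zero and the effective magnitude response is \code{|H|^2} (attenuations
#' double in dB). Edges are handled with odd-reflection padding of
#' \code{3 * order} samples and steady-state initial conditions, the standard
#' forward-backward practice.
#'
#' @param x Numeric signal.
#' @param filt A \code{highpass_filter}, or a list with \code{b} and \code{a}.
#' @return Filtered signal, same length as \code{x}.
#' @export
zero_phase_filter <- function(x, filt) {
  b <- filt$b; a <- filt$a
  nfact <- 3 * (max(length(a), length(b)) - 1)
  if (length(x) <= nfact)
    stop_input("signal too short for zero-phase filtering (need > ",
               nfact, " samples)")
  xx <- c(2 * x[1] - x[(nfact + 1):2], x,
          2 * x[length(x)] - x[(length(x) - 1):(length(x) - nfact)])
  zi <- steady_state_zi(b, a)
  y <- iir_pass(b, a, xx, zi * xx[1])
  y <- rev(iir_pass(b, a, rev(y), zi * y[length(y)]))
  y[(nfact + 1):(nfact + length(x))]
}

#' RMS in fixed-width time bins
#'
#' Root-mean-square of a signal in consecutive bins of \code{bin_s} seconds,
#' aligned to the recording's elapsed-time origin (t = 0 at the first sample).
#' A trailing partial bin is dropped.
#'
#' @param x Numeric signal.
#' @param sample_rate Sample rate (Hz).
#' @param bin_s Bin width in seconds (default 1).
#' @return A data.frame with \code{bin_start_s} and \code{rms}.
#' @export
rms_bins <- function(x, sample_rate, bin_s = 1) {
  if (bin_s <= 0) stop_input("bin_s must be positive")
  n_per <- round(bin_s * sample_rate)
  n_bins <- length(x) %/% n_per
  if (n_bins == 0)
    return(data.frame(bin_start_s = numeric(0), rms = numeric(0)))
  m <- matrix(x[seq_len(n_bins * n_per)]^2, nrow = n_per)
  data.frame(bin_start_s = (seq_len(n_bins) - 1) * bin_s,
             rms = sqrt(colMeans(m)))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is split into \code{n_segments}
#' segments with the given fractional overlap, each Hamming-windowed (by
#' default), and the one-sided periodograms are averaged. With the defaults
#' (8 segments, 50\% overlap) the segment length is the largest that fits,
#' mirroring the common default of specs-driven PSD tools. Each segment's
#' mean is removed before windowing, so near-DC leakage from a large static
#' offset (e.g. 1 g) does not mask low-frequency structure.
#'
#' @param x Numeric signal.
#' @param sample_rate Sample rate (Hz).
#' @param n_segments Number of segments (default 8).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param window Window type: \code{"hamming"} (default) or \code{"hann"}.
#' @return An object of class \code{psd_result}: a data.frame with
#'   \code{freq_hz} and \code{power} (signal-units^2 per Hz), one-sided so the
#'   integral of \code{power} over frequency approximates the signal variance.
#' @export
welch_psd <- function(x, sample_rate, n_segments = 8, overlap = 0.5,
                      window = c("hamming", "hann")) {
  window <- match.arg(window)
  x <- as.numeric(x)
  # segment length so that n_segments segments at this overlap tile the signal
  seg_len <- floor(length(x) / ((n_segments - 1) * (1 - overlap) + 1))
  if (seg_len < 8)
    stop_input("signal too short for ", n_segments, " Welch segments")
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, length(x) - seg_len + 1, by = step)
  ph <- 2 * pi * (seq_len(seg_len) - 1) / (seg_len - 1)
  w <- if (window == "hamming") 0.54 - 0.46 * cos(ph) else 0.5 - 0.5 * cos(ph)
  U <- sum(w^2)
  n_freq <- seg_len %/% 2 + 1
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (sample_rate * U)
    acc <- acc + p[seq_len(n_freq)]
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC and (for even lengths) Nyquist
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (seg_len %% 2 == 0) dbl[n_freq] <- 1
  pxx <- pxx * dbl
  structure(data.frame(freq_hz = (seq_len(n_freq) - 1) * sample_rate / seg_len,
                       power = pxx),
            class = c("psd_result", "data.frame"))
}

#' Full vibration processing of an accelerometer trace
#'
#' Convenience wrapper: magnitude, zero-phase high-pass filtering, and 1-s RMS
#' binning in one call.
#'
#' @param trace An [accel_trace()].
#' @param spec A [filter_spec()]; its sample rate is taken from the trace.
#' @param bin_s RMS bin width in seconds.
#' @return An object of class \code{vibration_series}: list with \code{g}
#'   (magnitude), \code{g_f} (filtered magnitude), \code{rms_bins}
#'   (data.frame), and \code{sample_rate}.
#' @export
process_vibration <- function(trace, spec = NULL, bin_s = 1) {
  if (!inherits(trace, "accel_trace")) stop_input("trace must be an accel_trace")
  if (is.null(spec))
    spec <- filter_spec(sample_rate = trace$sample_rate)
  if (spec$sample_rate != trace$sample_rate)
    stop_input("filter spec sample rate does not match the trace")
  g <- vibration_magnitude(trace)
  filt <- design_highpass(spec)
  g_f <- zero_phase_filter(g, filt)
  structure(list(g = g, g_f = g_f,
                 rms_bins = rms_bins(g_f, trace$sample_rate, bin_s),
                 sample_rate = trace$sample_rate, filter = filt),
            class = "vibration_series")
}
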