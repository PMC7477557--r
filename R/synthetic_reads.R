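#' Nanopore read-generation model
#'
#' Distributional model for synthetic event-aligned nanopore data. Reads
#' arrive as a Poisson process over the session; each read carries a run of
#' contiguously aligned genomic bases whose per-base dwell (translocation)
#' times, Phred qualities, and ionic-current noise values are drawn from
#' configurable distributions, optionally coupled to the flight phase,
#' elapsed time, and RMS vibration at the base's timestamp.
#'
#' The translocation-time distribution is lognormal parameterized by its
#' median and mean (\code{sigma^2 = 2 log(mean/median)},
#' \code{mu = log(median)}), giving the long right tail seen in event-dwell
#' data; defaults target a 1.8 ms median and 2.28 ms mean. Dwell times are
#' discretized to whole signal samples (\code{max(1, round(t * rate/1000))}),
#' reproducing the sample-count granularity of real event tables. Per-base
#' Phred scores are rounded truncated normals chosen so the representative
#' read quality lands near 8.5; noise values are lognormal with mean ~0.28.
#'
#' @param read_rate Read starts per second (Poisson, default 3 — the
#'   throughput scale of a single flow cell in such experiments).
#' @param read_len_meanlog,read_len_sdlog Lognormal parameters of the aligned
#'   read length in bases (default log(1000), 0.4).
#' @param trans_median_ms,trans_mean_ms Median and mean translocation time.
#' @param qual_mean,qual_sd Per-base Phred score distribution (rounded
#'   normal, clipped to [0, 40]; qual_sd = 0 gives a degenerate score).
#' @param noise_mean,noise_sdlog Ionic-current noise (norm_std): lognormal
#'   with this mean and log-SD.
#' @param n_channels Number of pore channels (default 512).
#' @param mux_window_s Reads starting within this many seconds of session
#'   start are flagged as multiplex-scan reads (default 90).
#' @param mux_fraction Fraction of reads in the mux window flagged (default 1).
#' @param effects Optional named list of linear couplings:
#'   \code{trans_phase}/\code{qual_phase}/\code{noise_phase} (named per-label
#'   additive shifts), \code{trans_time}/\code{qual_time}/\code{noise_time}
#'   (per-second slopes), \code{trans_rms}/\code{qual_rms}/\code{noise_rms}
#'   (per-g-RMS slopes). Shifts act on the distribution mean on its natural
#'   scale. Default: no effects.
#' @return An object of class \code{read_model}.
#' @export
read_model <- function(read_rate = 3,
                       read_len_meanlog = log(1000), read_len_sdlog = 0.4,
                       trans_median_ms = 1.8, trans_mean_ms = 2.28,
                       qual_mean = 9.5, qual_sd = 3,
                       noise_mean = 0.28, noise_sdlog = 0.25,
                       n_channels = 512, mux_window_s = 90,
                       mux_fraction = 1, effects = list()) {
  if (read_rate <= 0 || trans_median_ms <= 0 || noise_mean <= 0)
    stop_input("rates and distribution parameters must be positive")
  if (trans_mean_ms < trans_median_ms)
    stop_input("lognormal dwell needs mean >= median")
  known <- c("trans_phase", "trans_time", "trans_rms",
             "qual_phase", "qual_time", "qual_rms",
             "noise_phase", "noise_time", "noise_rms")
  if (length(effects) > 0 && !all(names(effects) %in% known))
    stop_input("unknown effect(s): ",
               paste(setdiff(names(effects), known), collapse = ", "))
  structure(list(read_rate = read_rate,
                 read_len_meanlog = read_len_meanlog,
                 read_len_sdlog = read_len_sdlog,
                 trans_median_ms = trans_median_ms,
                 trans_mean_ms = trans_mean_ms,
                 qual_mean = qual_mean, qual_sd = qual_sd,
                 noise_mean = noise_mean, noise_sdlog = noise_sdlog,
                 n_channels = n_channels, mux_window_s = mux_window_s,
                 mux_fraction = mux_fraction, effects = effects),
            class = "read_model")
}

#' Simulate a reference genome sequence
#'
#' Uniform-random ACGT sequence of the given length, deterministic per seed.
#' Optionally written as FASTA (via Biostrings when available).
#'
#' @param length Sequence length in bases (default 48502, the lambda genome
#'   size).
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return The sequence as a single character string; the header used when
#'   writing records the length.
#' @export
simulate_genome <- function(length = 48502, seed = 1, path = NULL) {
  if (length <= 0) stop_input("genome length must be positive")
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  if (!is.null(path)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::DNAStringSet(seq)
      names(ss) <- sprintf("synthetic_lambda length=%d", length)
      Biostrings::writeXStringSet(ss, path)
    } else {
      writeLines(c(sprintf(">synthetic_lambda length=%d", length), seq), path)
    }
  }
  seq
}

# per-base mean shift from the model's effects, on the natural scale
effect_shift <- function(model, prefix, lab, t_s, rms) {
  e <- model$effects
  shift <- rep(0, length(t_s))
  ph <- e[[paste0(prefix, "_phase")]]
  if (!is.null(ph)) {
    hit <- lab %in% names(ph)
    shift[hit] <- shift[hit] + unlist(ph)[lab[hit]]
  }
  if (!is.null(e[[paste0(prefix, "_time")]]))
    shift <- shift + e[[paste0(prefix, "_time")]] * t_s
  if (!is.null(e[[paste0(prefix, "_rms")]]) && !is.null(rms))
    shift <- shift + e[[paste0(prefix, "_rms")]] * rms
  shift
}

#' Simulate an event-aligned nanopore read table
#'
#' Draws read start times as a Poisson process over \code{[0, duration_s)},
#' assigns channels, aligned-segment genome start positions and lengths, and
#' generates per-base dwell times, qualities and noise values per the model,
#' with any configured phase/time/vibration couplings evaluated at each
#' base's timestamp. Returns the table in the tabular event dialect together
#' with a ground-truth record of every generator parameter.
#'
#' @param model A [read_model()].
#' @param periods A [phase_periods()] table covering the session (used for
#'   phase-coupled effects and recorded in the truth).
#' @param duration_s Session length in seconds.
#' @param seed Integer seed; identical seeds yield identical tables.
#' @param signal_sample_rate Raw-signal rate (Hz) for event-length
#'   discretization (default 4000).
#' @param rms Optional RMS-vibration bin table (\code{bin_start_s},
#'   \code{rms}) for vibration-coupled effects.
#' @param genome A [genome_ref()].
#' @return A list of class \code{synthetic_reads}: \code{events} (data.table
#'   in the event dialect), \code{truth} (generator parameters and realized
#'   counts).
#' @export
simulate_reads <- function(model = read_model(), periods, duration_s,
                           seed = 1, signal_sample_rate = 4000,
                           rms = NULL, genome = genome_ref()) {
  if (missing(periods) || nrow(periods) == 0)
    stop_input("periods must be supplied (at least one covering period)")
  if (duration_s <= 0) stop_input("duration_s must be positive")
  set.seed(seed)

  n_reads <- rpois(1, model$read_rate * duration_s)
  if (n_reads == 0)
    return(structure(list(events = data.table::data.table(),
                          truth = list(model = model, n_reads = 0)),
                     class = "synthetic_reads"))
  start_s <- sort(runif(n_reads, 0, duration_s))
  channel <- sample.int(model$n_channels, n_reads, replace = TRUE)
  n_bases <- pmax(1L, as.integer(round(
    rlnorm(n_reads, model$read_len_meanlog, model$read_len_sdlog))))
  n_bases <- pmin(n_bases, genome$length)
  is_mux <- (start_s < model$mux_window_s) &
    (runif(n_reads) < model$mux_fraction)
  g_start <- vapply(n_bases, function(m)
    sample.int(genome$length - m + 1L, 1L) - 1L, integer(1))

  total <- sum(n_bases)
  read_idx <- rep.int(seq_len(n_reads), n_bases)
  within <- sequence(n_bases)  # 1..m per read

  # dwell times: lognormal(mu, sigma) with per-base mean shift applied as a
  # location shift on the ms scale, then discretized to whole samples
  sigma2 <- 2 * log(model$trans_mean_ms / model$trans_median_ms)
  mu <- log(model$trans_median_ms)
  dwell <- rlnorm(total, mu, sqrt(max(sigma2, 0)))

  # provisional timestamps (exact dwell) to evaluate covariates; effects act
  # on the generating distributions, so a first pass without effects is used
  # to place bases in time
  cs <- cumsum(dwell) - dwell  # flat start offset of each base
  first <- cs[cumsum(n_bases) - n_bases + 1L]
  t_s <- start_s[read_idx] + (cs - rep.int(first, n_bases)) / 1000

  has_eff <- length(model$effects) > 0
  lab <- NULL; rms_at <- NULL
  if (has_eff) {
    lab <- period_label_at(pmin(t_s, max(periods$end_s) - 1e-9), periods)
    if (!is.null(rms)) {
      bi <- findInterval(t_s, rms$bin_start_s)
      rms_at <- rms$rms[pmax(1L, pmin(bi, nrow(rms)))]
    }
    dwell <- dwell + effect_shift(model, "trans", lab, t_s, rms_at)
    dwell <- pmax(dwell, 1e-3)
  }
  event_len <- pmax(1L, as.integer(round(dwell * signal_sample_rate / 1000)))

  qual <- rnorm(total, model$qual_mean, model$qual_sd)
  if (has_eff) qual <- qual + effect_shift(model, "qual", lab, t_s, rms_at)
  qual <- pmin(pmax(round(qual), 0), 40)

  noise_mu <- log(model$noise_mean) - model$noise_sdlog^2 / 2
  noise <- rlnorm(total, noise_mu, model$noise_sdlog)
  if (has_eff) {
    noise <- noise + effect_shift(model, "noise", lab, t_s, rms_at)
    noise <- pmax(noise, 0)
  }

  events <- data.table::data.table(
    read_id = sprintf("read_%06d", read_idx),
    channel = channel[read_idx],
    read_start_s = start_s[read_idx],
    is_mux = is_mux[read_idx],
    genome_pos = g_start[read_idx] + within - 1L,
    event_len = event_len,
    norm_mean = rnorm(total, 0, 1),
    norm_std = noise,
    qual = qual)

  structure(list(events = events,
                 truth = list(model = model, seed = seed,
                              duration_s = duration_s,
                              signal_sample_rate = signal_sample_rate,
                              n_reads = n_reads, n_bases = total,
                              trans_mu = mu, trans_sigma2 = sigma2)),
            class = "synthetic_reads")
}
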