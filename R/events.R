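#' Representative read quality from per-base Phred scores
#'
#' The Phred (dB) transform of the mean per-base error probability:
#' \code{q_pbar = -10 log10(mean(10^(-q/10)))}. Because the mean is taken on
#' the probability scale, the result is bounded by the extreme per-base
#' scores and never exceeds the arithmetic mean of the scores (Jensen).
#'
#' @param base_quals Nonempty numeric vector of per-base Phred scores (>= 0).
#' @return The representative read quality, in dB.
#' @export
read_quality <- function(base_quals) {
  if (length(base_quals) == 0) stop_input("base_quals must be nonempty")
  if (any(base_quals < 0)) stop_input("Phred scores must be >= 0")
  -10 * log10(mean(10^(-base_quals / 10)))
}

#' Base translocation time from event length
#'
#' Converts an event length in raw-signal samples to the dwell time of the
#' motor protein per base: \code{1000 * event_len / signal_sample_rate}
#' milliseconds. The inverse is the instantaneous per-pore sequencing rate.
#'
#' @param event_len Event length(s) in samples (positive integers).
#' @param signal_sample_rate Raw-signal sampling rate in Hz (default 4000,
#'   the standard MinION rate; configurable because the effective rate of a
#'   given dataset may differ).
#' @return Translocation time(s) in milliseconds.
#' @export
translocation_time <- function(event_len, signal_sample_rate = 4000) {
  if (any(event_len < 1)) stop_input("event_len must be >= 1 sample")
  if (signal_sample_rate <= 0) stop_input("signal_sample_rate must be positive")
  1000 * event_len / signal_sample_rate
}

#' Genome reference descriptor
#'
#' @param name Reference name.
#' @param length Reference length in bases (default 48502, phage lambda).
#' @return An object of class \code{genome_ref}.
#' @export
genome_ref <- function(name = "lambda", length = 48502) {
  if (length <= 0) stop_input("genome length must be positive")
  structure(list(name = name, length = length), class = "genome_ref")
}

#' Per-period genome coverage of aligned bases
#'
#' For each period, the number of aligned bases whose timestamp falls in
#' \code{[start_s, end_s)} divided by the genome length — coverage in
#' genome-fold units.
#'
#' @param bases Base-event data.frame with a \code{t_s} column (seconds).
#' @param periods A [phase_periods()] table.
#' @param genome A [genome_ref()].
#' @return The \code{periods} table with an added \code{coverage} column.
#' @export
phase_coverage <- function(bases, periods, genome = genome_ref()) {
  if (nrow(periods) == 0) {
    out <- periods
    out$coverage <- numeric(0)
    return(out)
  }
  cov <- vapply(seq_len(nrow(periods)), function(i) {
    sum(bases$t_s >= periods$start_s[i] & bases$t_s < periods$end_s[i])
  }, numeric(1)) / genome$length
  out <- periods
  out$coverage <- cov
  out
}

# columns of the tabular event dialect (one row per aligned base; read-level
# fields repeat on every row of the read)
EVENT_COLS <- c("read_id", "channel", "read_start_s", "is_mux", "genome_pos",
                "event_len", "norm_mean", "norm_std", "qual")

#' Parse an event-aligned nanopore base table
#'
#' Reads the tab-separated event dialect (columns \code{read_id, channel,
#' read_start_s, is_mux, genome_pos, event_len, norm_mean, norm_std, qual};
#' one row per aligned base, read-level fields repeated within a read) and
#' derives the per-read and per-base records used downstream:
#' \itemize{
#'   \item reads: one row per read with channel, start time, mux flag, base
#'     count, duration (sum of event lengths over the signal rate) and the
#'     representative quality \code{q_pbar};
#'   \item bases: one row per aligned base with its genome position (0-based),
#'     event length, normalized signal mean/SD, derived translocation time
#'     \code{trans_ms}, and timestamp \code{t_s} (read start plus cumulative
#'     event lengths, i.e. the event's start on the instrument clock).
#' }
#'
#' Rows with a missing/empty read id (orphan bases), non-positive event
#' lengths, or read-level fields that disagree between rows of the same read
#' are format errors.
#'
#' @param path Path to the TSV event table, or a data.frame already in that
#'   layout.
#' @param signal_sample_rate Raw-signal sampling rate (Hz) used to derive
#'   durations and translocation times.
#' @param genome A [genome_ref()] used to validate positions.
#' @return A list of class \code{event_data} with data.tables \code{reads}
#'   and \code{bases}.
#' @export
parse_event_table <- function(path, signal_sample_rate = 4000,
                              genome = genome_ref()) {
  d <- if (is.data.frame(path)) data.table::as.data.table(path)
       else {
         if (!file.exists(path)) stop_input("no such file: ", path)
         data.table::fread(path, sep = "\t")
       }
  if (nrow(d) == 0) {
    return(structure(list(reads = data.table::data.table(),
                          bases = data.table::data.table(),
                          signal_sample_rate = signal_sample_rate),
                     class = "event_data"))
  }
  missing_cols <- setdiff(EVENT_COLS, names(d))
  if (length(missing_cols) > 0)
    stop_input("event table missing column(s): ",
               paste(missing_cols, collapse = ", "))
  if (any(is.na(d$read_id) | d$read_id == ""))
    stop_input("event table has base rows with no read_id (orphan bases)")
  if (any(d$event_len < 1))
    stop_input("event table has non-positive event lengths")
  if (any(d$genome_pos < 0 | d$genome_pos >= genome$length))
    stop_input("genome_pos outside [0, ", genome$length, ")")

  read_id <- channel <- read_start_s <- is_mux <- event_len <- qual <-
    t_s <- trans_ms <- NULL
  consist <- d[, list(n_channel = data.table::uniqueN(channel),
                      n_start = data.table::uniqueN(read_start_s),
                      n_mux = data.table::uniqueN(is_mux)), by = read_id]
  if (any(consist$n_channel > 1 | consist$n_start > 1 | consist$n_mux > 1))
    stop_input("read-level fields disagree across rows of the same read")

  bases <- data.table::copy(d)
  bases[, t_s := read_start_s + (cumsum(event_len) - event_len) / signal_sample_rate,
        by = read_id]
  bases[, trans_ms := translocation_time(event_len, signal_sample_rate)]

  reads <- bases[, list(channel = channel[1], start_s = read_start_s[1],
                        is_mux = as.logical(is_mux[1]), n_bases = .N,
                        duration_s = sum(event_len) / signal_sample_rate,
                        q_pbar = read_quality(qual)),
                 by = read_id]
  structure(list(reads = reads,
                 bases = bases[, c("read_id", "genome_pos", "event_len",
                                   "norm_mean", "norm_std", "qual",
                                   "t_s", "trans_ms"), with = FALSE],
                 signal_sample_rate = signal_sample_rate),
            class = "event_data")
}

#' Write an event table in the tabular dialect
#'
#' @param events A data.frame in the event-table layout (see
#'   [parse_event_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_event_table <- function(events, path) {
  missing_cols <- setdiff(EVENT_COLS, names(events))
  if (length(missing_cols) > 0)
    stop_input("event table missing column(s): ",
               paste(missing_cols, collapse = ", "))
  data.table::fwrite(as.data.frame(events)[, EVENT_COLS, drop = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' Exclude multiplex-scan (mux) reads
#'
#' Drops reads flagged as produced during the sequencer's initial
#' pore-selection scan, and their bases, to avoid start-up effects.
#'
#' @param ev An \code{event_data} object.
#' @return The filtered \code{event_data}.
#' @export
exclude_mux <- function(ev) {
  stopifnot(inherits(ev, "event_data"))
  if (nrow(ev$reads) == 0) return(ev)
  keep <- ev$reads$read_id[!ev$reads$is_mux]
  ev$reads <- ev$reads[ev$reads$read_id %in% keep, ]
  ev$bases <- ev$bases[ev$bases$read_id %in% keep, ]
  ev
}
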