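#' Shift sequencing records onto the accelerometer clock
#'
#' Adds a constant offset to the time fields of reads (\code{start_s}) and/or
#' bases (\code{t_s}), aligning the sequencer's clock with the accelerometer's
#' elapsed time. Record order is preserved.
#'
#' @param x A data.frame with a \code{start_s} or \code{t_s} column, or an
#'   \code{event_data} object (both tables are shifted).
#' @param offset_s Finite offset in seconds.
#' @return The shifted object.
#' @export
apply_time_offset <- function(x, offset_s) {
  if (!is.finite(offset_s)) stop_input("offset_s must be finite")
  if (inherits(x, "event_data")) {
    x$reads <- apply_time_offset(x$reads, offset_s)
    x$bases <- apply_time_offset(x$bases, offset_s)
    return(x)
  }
  if ("start_s" %in% names(x)) x$start_s <- x$start_s + offset_s
  if ("t_s" %in% names(x)) x$t_s <- x$t_s + offset_s
  x
}

#' Assign a time interval to a flight phase
#'
#' An interval is assigned a phase label iff it lies wholly within one period
#' (closed containment: an interval ending exactly at a period's end is still
#' within it). Intervals crossing a period boundary, or outside the covered
#' range, are \code{"spanning"}. A zero-length interval at a shared boundary
#' belongs to the earlier period.
#'
#' @param start_s,end_s Interval bounds (vectors; \code{start_s <= end_s}).
#' @param periods A [phase_periods()] table.
#' @return Character vector of labels (one of the phase labels or
#'   \code{"spanning"}).
#' @export
assign_phase <- function(start_s, end_s, periods) {
  if (any(start_s > end_s)) stop_input("interval start after end")
  n <- length(start_s)
  out <- rep("spanning", n)
  if (nrow(periods) == 0) return(out)
  idx <- findInterval(start_s, periods$start_s)
  # a point exactly at a shared boundary belongs to the earlier period
  at_bound <- idx > 1 & start_s == periods$start_s[pmax(idx, 1)] &
    start_s == end_s
  idx[at_bound] <- idx[at_bound] - 1
  ok <- idx >= 1 & idx <= nrow(periods)
  ii <- which(ok)
  contained <- start_s[ii] >= periods$start_s[idx[ii]] &
               end_s[ii] <= periods$end_s[idx[ii]] + 1e-9
  out[ii[contained]] <- periods$label[idx[ii][contained]]
  out
}

#' Build the joint 1-second bin series
#'
#' Joins sequencing and acceleration data on a common binned timeline, the
#' substrate for all regressions: per bin, the median representative read
#' quality over reads covering the bin (interval overlap, point contact
#' included), the median ionic-current noise over bases within the bin
#' (point membership \code{t_s} in \code{[k, k+bin_s)}), the RMS vibration,
#' the mean acceleration magnitude, and the phase label at the bin midpoint.
#' Bins with no reads or no bases carry \code{NA} medians and are dropped
#' listwise by the regressions.
#'
#' All inputs must already be on the accelerometer clock, with mux reads
#' excluded upstream.
#'
#' @param reads Read table (needs \code{start_s}, \code{duration_s},
#'   \code{q_pbar}).
#' @param bases Base table (needs \code{t_s}, \code{norm_std}).
#' @param vib A \code{vibration_series} from [process_vibration()], or a
#'   list with \code{rms_bins} and (optionally) \code{g} + \code{sample_rate}.
#' @param periods A [phase_periods()] table.
#' @param bin_s Bin width (s); 1 s matches the published analyses.
#' @return A data.frame of class \code{bin_series}: \code{bin_start_s},
#'   \code{elapsed_s}, \code{median_q_pbar}, \code{median_norm_std},
#'   \code{rms_g}, \code{mean_g}, \code{phase}.
#' @export
build_bins <- function(reads, bases, vib, periods, bin_s = 1) {
  n_bins <- nrow(vib$rms_bins)
  if (n_bins == 0) stop_input("vibration series has no RMS bins")
  bin_start <- vib$rms_bins$bin_start_s

  med_q <- rep(NA_real_, n_bins)
  if (!is.null(reads) && nrow(reads) > 0) {
    r_start <- reads$start_s
    r_end <- reads$start_s + reads$duration_s
    # bins touched by each read: point contact at the boundary counts
    first <- pmax(1L, findInterval(r_start, bin_start))
    last <- pmin(n_bins, findInterval(r_end, bin_start))
    keep <- which(first <= last & r_end >= bin_start[1] &
                    r_start <= bin_start[n_bins] + bin_s)
    if (length(keep) > 0) {
      reps <- last[keep] - first[keep] + 1L
      dt <- data.table::data.table(
        bin = unlist(lapply(keep, function(i) first[i]:last[i])),
        q = rep(reads$q_pbar[keep], reps))
      bin <- q <- NULL
      mq <- dt[, list(m = median(q)), by = bin]
      med_q[mq$bin] <- mq$m
    }
  }

  med_noise <- rep(NA_real_, n_bins)
  if (!is.null(bases) && nrow(bases) > 0) {
    bidx <- floor((bases$t_s - bin_start[1]) / bin_s) + 1L
    ok <- bidx >= 1 & bidx <= n_bins
    if (any(ok)) {
      dt <- data.table::data.table(bin = bidx[ok], v = bases$norm_std[ok])
      bin <- v <- NULL
      mn <- dt[, list(m = median(v)), by = bin]
      med_noise[mn$bin] <- mn$m
    }
  }

  mean_g <- rep(NA_real_, n_bins)
  if (!is.null(vib$g) && !is.null(vib$sample_rate)) {
    n_per <- round(bin_s * vib$sample_rate)
    usable <- n_bins * n_per
    mean_g <- colMeans(matrix(vib$g[seq_len(usable)], nrow = n_per))
  }

  phase <- period_label_at(bin_start + bin_s / 2, periods)
  structure(data.frame(bin_start_s = bin_start, elapsed_s = bin_start,
                       median_q_pbar = med_q, median_norm_std = med_noise,
                       rms_g = vib$rms_bins$rms, mean_g = mean_g,
                       phase = phase, stringsAsFactors = FALSE),
            class = c("bin_series", "data.frame"))
}

#' Truncate a bin series by elapsed time
#'
#' Keeps bins with \code{elapsed_s <= max_s} (inclusive), e.g. the 4000 s
#' cut used to exclude aircraft descent and landing from flight regressions.
#'
#' @param bins A \code{bin_series}.
#' @param max_s Maximum elapsed time (s), default 4000.
#' @return The truncated bin series.
#' @export
truncate_elapsed <- function(bins, max_s = 4000) {
  if (max_s <= 0) stop_input("max_s must be positive")
  bins[bins$elapsed_s <= max_s, , drop = FALSE]
}
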