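PHASE_LABELS <- c("parabola", "transition", "hypergravity", "other")

#' Segmentation parameters
#'
#' Tunable thresholds for classifying an acceleration-magnitude timeline into
#' flight phases. All values are configurable; the defaults reproduce the
#' four-phase vocabulary of parabolic-flight analyses: hypergravity is a
#' sustained excursion above \code{hyper_thresh}, a parabola is a sustained
#' plateau near one of the reduced-g targets, transitions are the short
#' intervals connecting a hypergravity period to an adjacent parabola, and
#' everything else (level flight, climbs, turns) is "other".
#'
#' @param hyper_thresh Hypergravity threshold in g (default 1.2).
#' @param hyper_min_s Minimum sustained duration for hypergravity (s).
#' @param plateau_tol Tolerance around a target g for a parabola plateau (g).
#' @param parabola_max_g Upper bound on smoothed g during a parabola (g).
#' @param parabola_min_s Minimum sustained duration for a parabola (s).
#' @param targets Candidate target g levels (0 g, Lunar, Mars by default).
#' @param smooth_s Width of the moving-median smoother (s).
#' @return An object of class \code{segmentation_params}.
#' @export
segmentation_params <- function(hyper_thresh = 1.2, hyper_min_s = 2,
                                plateau_tol = 0.07, parabola_max_g = 0.5,
                                parabola_min_s = 5,
                                targets = c(0, 0.166, 0.378), smooth_s = 1) {
  stopifnot(hyper_thresh > 0, hyper_min_s > 0, plateau_tol > 0,
            parabola_min_s > 0, smooth_s > 0, all(targets >= 0))
  structure(list(hyper_thresh = hyper_thresh, hyper_min_s = hyper_min_s,
                 plateau_tol = plateau_tol, parabola_max_g = parabola_max_g,
                 parabola_min_s = parabola_min_s,
                 targets = sort(targets), smooth_s = smooth_s),
            class = "segmentation_params")
}

#' Construct a phase-period table
#'
#' Validates and assembles a table of labeled flight periods: consecutive,
#' non-overlapping intervals \code{[start_s, end_s)} with a label from
#' \code{parabola}, \code{transition}, \code{hypergravity}, \code{other}, and
#' a target g for parabolas (NA otherwise).
#'
#' @param start_s,end_s Numeric vectors of period bounds (seconds).
#' @param label Character vector of phase labels.
#' @param target_g Numeric vector of parabola targets (NA for non-parabola).
#' @return A data.frame of class \code{phase_periods}.
#' @export
phase_periods <- function(start_s, end_s, label,
                          target_g = rep(NA_real_, length(start_s))) {
  label <- as.character(label)
  bad <- setdiff(unique(label), PHASE_LABELS)
  if (length(bad) > 0)
    stop_input("unknown phase label(s): ", paste(bad, collapse = ", "))
  if (any(start_s >= end_s)) stop_input("periods must have start_s < end_s")
  o <- order(start_s)
  p <- data.frame(start_s = start_s[o], end_s = end_s[o],
                  label = label[o], target_g = as.numeric(target_g)[o],
                  stringsAsFactors = FALSE)
  if (nrow(p) > 1 && any(p$start_s[-1] < p$end_s[-nrow(p)] - 1e-9))
    stop_input("periods overlap")
  class(p) <- c("phase_periods", "data.frame")
  p
}

# runs of TRUE in a logical vector -> start/end sample indices
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Segment an acceleration-magnitude timeline into flight phases
#'
#' Smooths the magnitude with a moving median, detects sustained hypergravity
#' excursions and sustained reduced-g plateaus near the configured targets,
#' labels the gaps that directly connect a hypergravity period to an adjacent
#' parabola as transitions, and labels the remainder "other". The output
#' covers \code{[0, length(magnitude)/sample_rate)} without overlap.
#'
#' A trace with no excursions yields a single "other" period. Parabola target
#' assignment is the nearest configured target of the plateau's median level;
#' ties break toward the lower g.
#'
#' @param magnitude Nonnegative acceleration magnitude (g), uniform sampling.
#' @param sample_rate Sample rate (Hz).
#' @param params A [segmentation_params()].
#' @return A [phase_periods()] table.
#' @export
segment_phases <- function(magnitude, sample_rate,
                           params = segmentation_params()) {
  if (any(magnitude < 0)) stop_input("magnitude must be nonnegative")
  n <- length(magnitude)
  total_s <- n / sample_rate
  k <- round(params$smooth_s * sample_rate)
  if (k %% 2 == 0) k <- k + 1
  sm <- if (n > k) stats::runmed(magnitude, k, endrule = "median") else magnitude

  # sustained hypergravity runs
  hyper <- logical_runs(sm >= params$hyper_thresh)
  hyper <- hyper[(hyper$end - hyper$start + 1) >= params$hyper_min_s * sample_rate, ,
                 drop = FALSE]

  # sustained plateaus near a target (nearest-target distance, vectorized;
  # ties break toward the lower target because max.col takes the first)
  dmat <- vapply(params$targets, function(tg) abs(sm - tg),
                 numeric(length(sm)))
  min_dist <- do.call(pmin, as.data.frame(dmat))
  para_mask <- (min_dist <= params$plateau_tol) & (sm < params$parabola_max_g)
  para <- logical_runs(para_mask)
  para <- para[(para$end - para$start + 1) >= params$parabola_min_s * sample_rate, ,
               drop = FALSE]
  para$target <- vapply(seq_len(nrow(para)), function(i) {
    med <- median(sm[para$start[i]:para$end[i]])
    d <- abs(params$targets - med)
    params$targets[which.min(d)]
  }, numeric(1))

  # assemble core periods on the sample grid (end index exclusive in seconds)
  core <- rbind(
    if (nrow(hyper) > 0)
      data.frame(start = hyper$start, end = hyper$end,
                 label = "hypergravity", target = NA_real_),
    if (nrow(para) > 0)
      data.frame(start = para$start, end = para$end,
                 label = "parabola", target = para$target)
  )
  if (is.null(core) || nrow(core) == 0)
    return(phase_periods(0, total_s, "other"))
  core <- core[order(core$start), ]
  core$start_s <- (core$start - 1) / sample_rate
  core$end_s <- core$end / sample_rate

  # label gaps: transition iff it sits directly between a hypergravity period
  # and a parabola (either order); everything else is other
  out <- list()
  add <- function(s, e, lab, tg = NA_real_) {
    if (e - s > 1e-9) out[[length(out) + 1]] <<- data.frame(
      start_s = s, end_s = e, label = lab, target_g = tg)
  }
  prev_end <- 0
  prev_lab <- NA_character_
  for (i in seq_len(nrow(core))) {
    gap_lab <- if (!is.na(prev_lab) &&
                   ((prev_lab == "hypergravity" && core$label[i] == "parabola") ||
                    (prev_lab == "parabola" && core$label[i] == "hypergravity")))
      "transition" else "other"
    add(prev_end, core$start_s[i], gap_lab)
    add(core$start_s[i], core$end_s[i], core$label[i], core$target[i])
    prev_end <- core$end_s[i]
    prev_lab <- core$label[i]
  }
  add(prev_end, total_s, "other")
  res <- do.call(rbind, out)
  phase_periods(res$start_s, res$end_s, res$label, res$target_g)
}

#' Read a phase-period table from file
#'
#' Reads the tab-separated period-table dialect: header
#' \code{start_s  end_s  label  target_g}, with \code{target_g} empty for
#' non-parabola rows. Overlapping rows or unknown labels are format errors.
#'
#' @param path File path.
#' @return A [phase_periods()] table.
#' @export
read_periods <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "label", "target_g")
  if (!all(need %in% names(d)))
    stop_input("period table must have columns: ", paste(need, collapse = ", "))
  if (nrow(d) == 0)
    return(phase_periods(numeric(0), numeric(0), character(0), numeric(0)))
  phase_periods(d$start_s, d$end_s, d$label, suppressWarnings(as.numeric(d$target_g)))
}

#' Write a phase-period table to file
#'
#' @param periods A [phase_periods()] table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_periods <- function(periods, path) {
  stopifnot(inherits(periods, "phase_periods"))
  write.table(periods, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# label of the period containing time t (closed containment; points on a
# shared boundary belong to the earlier period). NA if uncovered.
period_label_at <- function(t, periods) {
  idx <- findInterval(t, periods$start_s)
  lab <- rep(NA_character_, length(t))
  ok <- idx >= 1
  # boundary points t == start of period i also equal end of period i-1:
  # findInterval puts t at period i; shift back when t equals that start
  at_start <- ok & idx > 1 & t == periods$start_s[pmin(idx, nrow(periods))]
  idx[at_start] <- idx[at_start] - 1
  inside <- ok & t <= periods$end_s[pmin(idx, nrow(periods))] + 1e-9
  lab[inside] <- periods$label[idx[inside]]
  lab
}
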