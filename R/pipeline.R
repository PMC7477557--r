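#' Pipeline configuration
#'
#' Validated configuration for an end-to-end run. Either supply paths to an
#' accelerometer trace CSV and an event table, or set \code{simulate = TRUE}
#' to generate both synthetically (the default study-shaped conditions).
#' All stages, parameters and seeds are recorded so identical configurations
#' give identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate Generate synthetic flight + reads instead of reading
#'   input files.
#' @param accel_path CSV/TSV with columns \code{t, gx, gy, gz} (ignored when
#'   simulating).
#' @param events_path Event-table TSV (ignored when simulating).
#' @param periods_path Optional period table; when absent, periods come from
#'   segmentation (or generator truth if \code{use_truth_periods}).
#' @param use_truth_periods When simulating, use the generator's true
#'   periods instead of re-segmenting (default FALSE).
#' @param offset_s Clock offset added to sequencing times (s).
#' @param accel_rate Accelerometer sample rate (Hz).
#' @param signal_rate Nanopore raw-signal rate (Hz).
#' @param bin_s Bin width (s).
#' @param max_elapsed_s Elapsed-time truncation for regressions (s).
#' @param genome_length Reference length in bases.
#' @param seed Master seed for the simulated stages.
#' @param plan,vib,model Generator settings used when simulating.
#' @param exclude_transition Drop transition-phase groups from the
#'   phase ANOVA (their read counts are tiny).
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, accel_path = NULL,
                            events_path = NULL, periods_path = NULL,
                            use_truth_periods = FALSE, offset_s = 0,
                            accel_rate = 5000, signal_rate = 4000,
                            bin_s = 1, max_elapsed_s = 4000,
                            genome_length = 48502, seed = 1,
                            plan = flight_plan(), vib = vibration_model(),
                            model = read_model(),
                            exclude_transition = TRUE) {
  if (missing(out_dir)) stop_input("config field missing: out_dir")
  if (!simulate) {
    if (is.null(accel_path)) stop_input("config field missing: accel_path")
    if (is.null(events_path)) stop_input("config field missing: events_path")
    for (p in c(accel_path, events_path, periods_path))
      if (!file.exists(p)) stop_input("input path does not exist: ", p)
  }
  stopifnot(accel_rate > 0, signal_rate > 0, bin_s > 0, max_elapsed_s > 0)
  structure(list(out_dir = out_dir, simulate = simulate,
                 accel_path = accel_path, events_path = events_path,
                 periods_path = periods_path,
                 use_truth_periods = use_truth_periods,
                 offset_s = offset_s, accel_rate = accel_rate,
                 signal_rate = signal_rate, bin_s = bin_s,
                 max_elapsed_s = max_elapsed_s,
                 genome_length = genome_length, seed = seed,
                 plan = plan, vib = vib, model = model,
                 exclude_transition = exclude_transition),
            class = "pipeline_config")
}

#' Read an accelerometer trace from CSV/TSV
#'
#' Expects a header with columns \code{t, gx, gy, gz} (units Earth-g); the
#' sample rate is inferred from the time column and checked for uniformity.
#'
#' @param path File path.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  d <- data.table::fread(path)
  need <- c("t", "gx", "gy", "gz")
  if (!all(need %in% names(d)))
    stop_input("accelerometer file must have columns: ",
               paste(need, collapse = ", "))
  dt <- diff(d$t)
  if (length(dt) == 0) stop_input("accelerometer file has fewer than 2 samples")
  if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-12)
    stop_input("time column is not uniformly sampled")
  accel_trace(d$gx, d$gy, d$gz, sample_rate = 1 / mean(dt))
}

report_json <- function(x, path, cfg_hash) {
  x$config_hash <- cfg_hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

stepwise_report <- function(fit) {
  list(selected_terms = as.list(fit$selected_terms),
       coefficients = as.list(fit$coefficients),
       term_pvalues = as.list(fit$term_pvalues),
       r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: accelerometer processing (magnitude,
#' zero-phase high-pass, 1-s RMS, Welch PSD), flight segmentation (unless a
#' period table is supplied), event parsing and mux exclusion, clock-offset
#' alignment, joint 1-s binning with elapsed-time truncation, and the
#' statistical battery (stepwise regressions of binned quality and
#' ionic-current noise on time/vibration/g, phase ANOVA + Tukey HSD,
#' per-parabola coverage regression on duration). Writes
#' \code{periods.txt}, \code{bins.tsv}, \code{rms.tsv}, \code{psd.tsv},
#' \code{regression_quality.json}, \code{regression_noise.json},
#' \code{anova_quality.json}, \code{coverage.json} and a human-readable
#' \code{summary.txt} into the output directory; every report declares the
#' hash of the configuration that produced it. Identical config + seeds give
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class \code{pipeline_result} with the in-memory stage
#'   outputs (invisibly also written to \code{config$out_dir}).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_input("config must be a pipeline_config")
  # hash the scientific configuration only (not where outputs land)
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- acquire inputs ----------------------------------------------------
  truth_periods <- NULL
  if (config$simulate) {
    fl <- stage("simulate-flight",
                make_flight(config$plan, config$vib, seed = config$seed,
                            sample_rate = config$accel_rate))
    trace <- fl$trace
    truth_periods <- fl$periods
    sr <- stage("simulate-reads",
                simulate_reads(config$model, fl$periods, fl$total_s,
                               seed = config$seed + 1,
                               signal_sample_rate = config$signal_rate,
                               genome = genome_ref(length = config$genome_length)))
    events_in <- sr$events
  } else {
    trace <- stage("read-accel", read_accel_csv(config$accel_path))
    events_in <- config$events_path
  }

  # --- accelerometer processing -----------------------------------------
  vibr <- stage("accel", process_vibration(
    trace, filter_spec(sample_rate = trace$sample_rate), config$bin_s))
  psd <- stage("accel", welch_psd(vibr$g, trace$sample_rate))

  # --- segmentation ------------------------------------------------------
  periods <- if (!is.null(config$periods_path)) {
    stage("segment", read_periods(config$periods_path))
  } else if (config$simulate && config$use_truth_periods) {
    truth_periods
  } else {
    stage("segment", segment_phases(vibr$g, trace$sample_rate))
  }

  # --- events ------------------------------------------------------------
  ev <- stage("metrics", parse_event_table(
    events_in, signal_sample_rate = config$signal_rate,
    genome = genome_ref(length = config$genome_length)))
  ev <- exclude_mux(ev)
  ev <- apply_time_offset(ev, config$offset_s)

  # --- integration -------------------------------------------------------
  bins <- stage("integrate",
                build_bins(ev$reads, ev$bases, vibr, periods, config$bin_s))
  bins_t <- truncate_elapsed(bins, config$max_elapsed_s)

  # --- statistics --------------------------------------------------------
  cand <- data.frame(elapsed_s = bins_t$elapsed_s, rms_g = bins_t$rms_g,
                     mean_g = bins_t$mean_g)
  reg_q <- stage("stats", stepwise_lm(bins_t$median_q_pbar, cand))
  reg_n <- stage("stats", stepwise_lm(bins_t$median_norm_std, cand))

  read_phase <- assign_phase(ev$reads$start_s,
                             ev$reads$start_s + ev$reads$duration_s, periods)
  keep_lab <- setdiff(PHASE_LABELS,
                      if (config$exclude_transition) "transition" else NULL)
  grp <- split(ev$reads$q_pbar, read_phase)[
    intersect(keep_lab, unique(read_phase))]
  grp <- grp[lengths(grp) > 0]
  anova_q <- tukey_q <- NULL
  if (length(grp) >= 2 && sum(lengths(grp)) > length(grp)) {
    anova_q <- stage("stats-phase", anova_oneway(grp))
    tukey_q <- stage("stats-phase", tukey_hsd(grp))
  }

  cov_fit <- NULL
  par_rows <- periods[periods$label == "parabola", , drop = FALSE]
  if (nrow(par_rows) >= 3) {
    covg <- phase_coverage(ev$bases, par_rows,
                           genome_ref(length = config$genome_length))
    cov_fit <- stage("stats", stepwise_lm(
      covg$coverage,
      data.frame(duration_s = covg$end_s - covg$start_s), max_degree = 1))
  }

  # --- outputs -----------------------------------------------------------
  od <- config$out_dir
  write_periods(periods, file.path(od, "periods.txt"))
  write.table(bins, file.path(od, "bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(vibr$rms_bins, file.path(od, "rms.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(psd), file.path(od, "psd.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  report_json(stepwise_report(reg_q),
              file.path(od, "regression_quality.json"), cfg_hash)
  report_json(stepwise_report(reg_n),
              file.path(od, "regression_noise.json"), cfg_hash)
  if (!is.null(anova_q))
    report_json(list(F = anova_q$F, p_value = anova_q$p_value,
                     means = as.list(anova_q$means),
                     tukey = tukey_q),
                file.path(od, "anova_quality.json"), cfg_hash)
  if (!is.null(cov_fit))
    report_json(stepwise_report(cov_fit), file.path(od, "coverage.json"),
                cfg_hash)
  summary_lines <- c(
    sprintf("gravseq pipeline (config %s)", cfg_hash),
    sprintf("reads: %d (non-mux), bases: %d", nrow(ev$reads), nrow(ev$bases)),
    sprintf("periods: %d (%d parabolas)", nrow(periods),
            sum(periods$label == "parabola")),
    sprintf("bins: %d total, %d after %g s truncation",
            nrow(bins), nrow(bins_t), config$max_elapsed_s),
    sprintf("quality regression: %s (adj R2 = %.3f)",
            if (length(reg_q$selected_terms) == 0) "intercept only"
            else paste(reg_q$selected_terms, collapse = ", "), reg_q$adj_r2),
    sprintf("noise regression: %s (adj R2 = %.3f)",
            if (length(reg_n$selected_terms) == 0) "intercept only"
            else paste(reg_n$selected_terms, collapse = ", "), reg_n$adj_r2))
  writeLines(summary_lines, file.path(od, "summary.txt"))

  invisible(structure(list(config = config, config_hash = cfg_hash,
                           trace = trace, vibration = vibr, psd = psd,
                           periods = periods, truth_periods = truth_periods,
                           events = ev, bins = bins, bins_truncated = bins_t,
                           regression_quality = reg_q,
                           regression_noise = reg_n,
                           anova_quality = anova_q, tukey_quality = tukey_q,
                           coverage_fit = cov_fit),
                      class = "pipeline_result"))
}
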