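# Detection pipeline: map transient onsets back through the stimulus
# geometry to detection distances, summarise trials, and drive the full
# experiment -> tidy table -> statistics run.

#' Detection distance for peak onsets
#'
#' Maps each peak's onset time to the lateral glyph position at that moment
#' and on to the eye-to-stimulus distance (the hypotenuse of the eye--screen
#' triangle). Detection must occur while the stimulus approaches: peaks whose
#' onset falls on a receding leg or a dwell get `NA` (they are kept for the
#' shape metrics but carry no distance). An onset before motion start is an
#' error — such peaks should have been artifact-flagged.
#'
#' @param peaks A peak table (or any data frame with `t_onset`).
#' @param kin A [stimulus_kinematics()] object.
#' @param geo An [eye_geometry()] object.
#' @return Numeric vector of distances in mm (`NA` off the approach legs),
#'   with attribute `phase` giving the trajectory phase per onset.
#' @export
#' @examples
#' kin <- stimulus_kinematics()
#' pk <- data.frame(t_onset = kin$t_move_start)
#' detection_distance_for_peak(pk, kin, eye_geometry())  # 6.3789 mm
detection_distance_for_peak <- function(peaks, kin, geo) {
  if (!nrow(peaks)) return(numeric(0))
  st <- trajectory_state(peaks$t_onset, kin)
  if (any(st$phase == "pre")) {
    stop("peak onset precedes stimulus motion start; ",
         "flag such peaks as artifacts first", call. = FALSE)
  }
  dd <- rep(NA_real_, nrow(peaks))
  app <- st$phase == "approach"
  dd[app] <- distance_from_lateral(st$x[app], geo)
  structure(dd, phase = st$phase)
}

#' Summarise one trial
#'
#' Full per-trial chain: artifact flagging, double-top merging, first-five
#' selection, then the detection distance and the three peak-shape metrics
#' for every retained peak.
#'
#' @param trace A [fluorescence_trace()].
#' @param kin A [stimulus_kinematics()] object.
#' @param geo An [eye_geometry()] object.
#' @param n_keep Number of leading peaks retained (default 5).
#' @param merge_window Double-top merge window in s.
#' @param dd_policy How `dd_summary` condenses the per-peak distances:
#'   `"mean"` (default) or `"first"` (the first approach-leg peak only).
#' @param ... Further arguments to [detect_peaks()].
#' @return An object of class `trial_result`: a list with `peaks` (retained
#'   peak table), `detection_distances`, `dd_summary`, `durations`, `fwhms`,
#'   `intervals`, `fmax_fbase`, `f_base`, `sigma_noise`, `status`
#'   (`"ok"` or `"empty"`), and `n_detected` (count before selection).
#' @export
summarize_trial <- function(trace, kin = stimulus_kinematics(),
                            geo = eye_geometry(), n_keep = 5L,
                            merge_window = 1, dd_policy = c("mean", "first"),
                            ...) {
  dd_policy <- match.arg(dd_policy)
  peaks <- detect_peaks(trace, ...)
  f_base <- attr(peaks, "f_base")
  sigma <- attr(peaks, "sigma_noise")
  n_detected <- nrow(peaks)
  peaks <- flag_artifacts(peaks, trace, t_move_start = kin$t_move_start)
  peaks <- merge_double_tops(peaks, trace, merge_window)
  peaks <- select_first_n(peaks, n_keep)
  if (!nrow(peaks)) {
    return(structure(list(peaks = peaks, detection_distances = numeric(0),
                          dd_summary = NA_real_, durations = numeric(0),
                          fwhms = numeric(0), intervals = numeric(0),
                          fmax_fbase = numeric(0), f_base = f_base,
                          sigma_noise = sigma, status = "empty",
                          n_detected = n_detected),
                     class = "trial_result"))
  }
  dd <- detection_distance_for_peak(peaks, kin, geo)
  dd_ok <- dd[!is.na(dd)]
  dd_summary <- if (!length(dd_ok)) {
    NA_real_
  } else if (dd_policy == "mean") {
    mean(dd_ok)
  } else {
    dd_ok[1]
  }
  structure(list(peaks = peaks, detection_distances = as.numeric(dd),
                 dd_summary = dd_summary, durations = duration(peaks),
                 fwhms = peaks$fwhm, intervals = inter_peak_intervals(peaks),
                 fmax_fbase = fmax_fbase(peaks), f_base = f_base,
                 sigma_noise = sigma, status = "ok",
                 n_detected = n_detected),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Trial result:", nrow(x$peaks), "retained peaks (", x$n_detected,
      "detected ), status", x$status, "\n")
  if (!is.na(x$dd_summary)) {
    cat("  detection distance:", round(x$dd_summary, 3), "mm\n")
  }
  invisible(x)
}

#' Run the full experiment
#'
#' Analyses every labelled trial, assembles the long-format results table
#' (one row per peak-level measurement), and runs the group-comparison
#' battery for each of the four response parameters. The statistical unit is
#' the peak (`unit = "peak"`, matching per-peak measurement counts) or the
#' trial mean (`unit = "trial"`).
#'
#' @param trials List of trials; each element needs `trial_id`,
#'   `temperature`, and `trace` (as produced by [simulate_experiment()]).
#' @param kin A [stimulus_kinematics()] object.
#' @param geo An [eye_geometry()] object.
#' @param unit Statistical unit for the group comparisons.
#' @param alpha Significance level for the battery.
#' @param posthoc_assignment Passed to [group_stats()].
#' @param ... Further arguments to [summarize_trial()].
#' @return An object of class `experiment_result`: a list with `table` (long
#'   data frame: `trial_id`, `temperature`, `parameter`, `value`), `stats`
#'   (per-parameter [group_stats()] reports, or `NULL` with a notice when
#'   fewer than two groups are present), `summaries` (per-trial
#'   `trial_result`s) and `group_means` (temperature x parameter means).
#' @export
run_experiment <- function(trials, kin = stimulus_kinematics(),
                           geo = eye_geometry(), unit = c("peak", "trial"),
                           alpha = 0.05,
                           posthoc_assignment = c("conventional",
                                                  "as_published"), ...) {
  unit <- match.arg(unit)
  posthoc_assignment <- match.arg(posthoc_assignment)
  if (!length(trials)) stop("no trials supplied", call. = FALSE)
  if (is.null(trials[[1]]$temperature)) {
    stop("every trial needs a temperature label", call. = FALSE)
  }
  summaries <- vector("list", length(trials))
  rows <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    s <- summarize_trial(tr$trace, kin, geo, ...)
    summaries[[i]] <- s
    if (s$status == "empty") next
    dd <- s$detection_distances[!is.na(s$detection_distances)]
    add <- function(parameter, value) {
      if (!length(value)) return(NULL)
      data.frame(trial_id = tr$trial_id, temperature = tr$temperature,
                 parameter = parameter, value = value)
    }
    if (unit == "peak") {
      rows[[length(rows) + 1L]] <- rbind(
        add("detection_distance", dd),
        add("duration", s$durations),
        add("fwhm", s$fwhms[!is.na(s$fwhms)]),
        add("interval", s$intervals),
        add("fmax_fbase", s$fmax_fbase)
      )
    } else {
      rows[[length(rows) + 1L]] <- rbind(
        add("detection_distance", s$dd_summary[!is.na(s$dd_summary)]),
        add("duration", mean(s$durations)),
        add("fwhm", mean(s$fwhms, na.rm = TRUE)),
        add("interval", if (length(s$intervals)) mean(s$intervals)),
        add("fmax_fbase", mean(s$fmax_fbase))
      )
    }
  }
  table <- do.call(rbind, rows)
  if (is.null(table)) stop("no peaks detected in any trial", call. = FALSE)
  rownames(table) <- NULL

  group_means <- stats::aggregate(value ~ temperature + parameter, table,
                                  mean)
  n_groups <- length(unique(table$temperature))
  stats_reports <- NULL
  notice <- NULL
  if (n_groups >= 2) {
    stats_reports <- lapply(split(table, table$parameter), function(df) {
      gd <- split(df$value, df$temperature)
      tryCatch(group_stats(gd, alpha = alpha,
                           posthoc_assignment = posthoc_assignment),
               error = function(e) list(error = conditionMessage(e)))
    })
  } else {
    notice <- "single temperature group: group statistics skipped"
  }
  structure(list(table = table, stats = stats_reports,
                 summaries = summaries, group_means = group_means,
                 notice = notice),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Experiment:", length(x$summaries), "trials,", nrow(x$table),
      "peak-level measurements\n")
  if (!is.null(x$notice)) cat(" ", x$notice, "\n")
  wide <- stats::reshape(x$group_means, idvar = "parameter",
                         timevar = "temperature", direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Write experiment results to disk
#'
#' Writes `results.csv` (the long table), `stats.json` (the statistics
#' reports) and `group_means.csv` into `dir`.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_experiment_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$table, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(result$group_means, file.path(dir, "group_means.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Read geometry / kinematics configuration from YAML or JSON
#'
#' Recognised top-level blocks: `screen`, `kinematics`, `eye`, `glyph`; each
#' maps field names onto the corresponding constructor arguments.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A list with `screen`, `kin`, `geo`, `glyph`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- function(ctor, args) do.call(ctor, as.list(args))
  list(screen = build(screen_spec, cfg$screen %||% list()),
       kin = build(stimulus_kinematics, cfg$kinematics %||% list()),
       geo = build(eye_geometry, cfg$eye %||% list()),
       glyph = build(glyph_spec, cfg$glyph %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
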