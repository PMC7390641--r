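# Synthetic-data generator: GCaMP-like fluorescence traces (and optional
# image stacks) with known ground truth, emulating recordings of the optic
# tectum across three temperature treatments.

#' Calcium-indicator impulse-response parameters
#'
#' Double-exponential kernel parameters: rise and decay time constants and
#' the peak amplitude expressed as relative fluorescence (dF/F at the kernel
#' maximum).
#'
#' @param tau_rise Rise time constant in s; `0 < tau_rise < tau_decay`.
#' @param tau_decay Decay time constant in s.
#' @param amplitude Peak relative-fluorescence amplitude; positive.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(tau_rise = 0.05, tau_decay = 0.7,
                          amplitude = 0.2) {
  stopifnot(tau_rise > 0, amplitude > 0)
  if (tau_decay <= tau_rise) {
    stop("tau_decay must exceed tau_rise", call. = FALSE)
  }
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 amplitude = amplitude),
            class = "kernel_params")
}

#' Time of the kernel maximum
#'
#' Closed form for the double-exponential kernel:
#' `tau_rise * log(1 + tau_decay / tau_rise)`.
#'
#' @param k A [kernel_params()] object.
#' @return Peak time in seconds after event onset.
#' @export
kernel_peak_time <- function(k) {
  k$tau_rise * log(1 + k$tau_decay / k$tau_rise)
}

#' Double-exponential calcium-indicator kernel
#'
#' `A * (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)`, normalised so the
#' maximum over t equals `k$amplitude`; zero for `t < 0` (causality).
#'
#' @param t Time(s) in seconds relative to event onset; vectorised.
#' @param k A [kernel_params()] object.
#' @return Relative-fluorescence value(s).
#' @export
#' @examples
#' k <- kernel_params(0.05, 0.5, 1)
#' gcamp_kernel(kernel_peak_time(k), k)  # equals the amplitude
gcamp_kernel <- function(t, k) {
  tstar <- kernel_peak_time(k)
  peak <- (1 - exp(-tstar / k$tau_rise)) * exp(-tstar / k$tau_decay)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- k$amplitude / peak *
    (1 - exp(-t[pos] / k$tau_rise)) * exp(-t[pos] / k$tau_decay)
  out
}

#' Ground truth for one synthetic trial
#'
#' @param dd_true True detection distance in mm; must lie in the attainable
#'   range of the geometry it is later simulated under.
#' @param kernel A [kernel_params()] object.
#' @param latency Detection-to-fluorescence delay in s (default 0).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   baseline fluorescence.
#' @param f_base_true Baseline fluorescence in arbitrary units.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(dd_true, kernel = kernel_params(), latency = 0,
                            noise_sd = 0.02, f_base_true = 100) {
  stopifnot(dd_true > 0, latency >= 0, noise_sd >= 0, f_base_true > 0)
  structure(list(dd_true = dd_true, kernel = kernel, latency = latency,
                 noise_sd = noise_sd, f_base_true = f_base_true),
            class = "synthetic_truth")
}

#' Temperature-treatment effect model for the generator
#'
#' Per-treatment generator parameters emulating the study conditions: the
#' detection distance and the transient decay time fall with temperature
#' (hence peak duration and FWHM fall, and the inter-peak interval grows),
#' and the peak amplitude follows the printed mean F_max/F_base ratios
#' (1.251, 1.154, 1.152 at 18, 23, 28 degrees C).
#'
#' @param temperatures Treatment temperatures in degrees C.
#' @param dd_mean,dd_sd Per-treatment mean and SD of the true detection
#'   distance in mm.
#' @param tau_decay_mean Per-treatment kernel decay time constant in s.
#' @param tau_rise Kernel rise time constant in s (shared).
#' @param amplitude Per-treatment kernel peak amplitude (dF/F).
#' @param noise_sd Per-treatment relative noise SD.
#' @return An object of class `temperature_effect_model`: a data frame with
#'   one row per treatment.
#' @export
temperature_effect_model <- function(temperatures = c(18, 23, 28),
                                     dd_mean = c(5.5, 4.9, 4.2),
                                     dd_sd = c(0.6, 0.6, 0.6),
                                     tau_decay_mean = c(1.4, 1.0, 0.7),
                                     tau_rise = 0.05,
                                     amplitude = c(0.251, 0.154, 0.152),
                                     noise_sd = c(0.02, 0.02, 0.02)) {
  k <- length(temperatures)
  stopifnot(k >= 1, all(dd_sd >= 0), all(noise_sd >= 0),
            all(dd_mean > 0), all(tau_decay_mean > tau_rise),
            all(amplitude > 0))
  df <- data.frame(temperature = temperatures,
                   dd_mean = rep_len(dd_mean, k),
                   dd_sd = rep_len(dd_sd, k),
                   tau_decay_mean = rep_len(tau_decay_mean, k),
                   tau_rise = tau_rise,
                   amplitude = rep_len(amplitude, k),
                   noise_sd = rep_len(noise_sd, k))
  structure(df, class = c("temperature_effect_model", "data.frame"))
}

#' Default number of frames covering a full trial
#'
#' Motion starts at `kin$t_move_start`; acquisition runs until 30 s after the
#' last cycle ends, at the given frame period.
#'
#' @param kin A [stimulus_kinematics()] object.
#' @param frame_period Frame period in s.
#' @param post_motion Extra acquisition time after motion ends, in s.
#' @return Number of frames (integer).
#' @export
default_n_frames <- function(kin, frame_period = 0.05, post_motion = 30) {
  as.integer(ceiling((motion_end_time(kin) + post_motion) / frame_period))
}

#' Simulate one fluorescence trial
#'
#' Places one ground-truth event per approach leg at the first time the
#' stimulus comes within `dd_true` (plus `latency`), convolves events with
#' the double-exponential kernel, and adds Gaussian noise:
#' `F(t) = f_base * (1 + sum_e kernel(t - t_e)) + N(0, noise_sd * f_base)`.
#'
#' @param truth A [synthetic_truth()] object.
#' @param kin A [stimulus_kinematics()] object.
#' @param geo An [eye_geometry()] object.
#' @param frame_period Frame period in s (default 0.05: 20 ms exposure plus
#'   30 ms gap).
#' @param n_frames Number of frames; default covers all cycles plus 30 s.
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @return A list with `trace` (a [fluorescence_trace()]) and `event_times`
#'   (ground-truth event onset times in s).
#' @export
simulate_trial <- function(truth, kin = stimulus_kinematics(),
                           geo = eye_geometry(), frame_period = 0.05,
                           n_frames = default_n_frames(kin, frame_period),
                           seed = NULL) {
  dmax <- max_attainable_distance(kin, geo)
  if (truth$dd_true < geo$eye_screen_distance || truth$dd_true > dmax) {
    stop("dd_true outside the attainable distance range", call. = FALSE)
  }
  if (n_frames * frame_period < motion_end_time(kin)) {
    stop("n_frames * frame_period must cover all stimulus cycles",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  event_times <- vapply(seq_len(kin$n_cycles) - 1L,
                        function(cyc) first_time_within(truth$dd_true, kin,
                                                        geo, cyc),
                        numeric(1)) + truth$latency
  times <- (seq_len(n_frames) - 1L) * frame_period
  rel <- numeric(n_frames)
  for (te in event_times) {
    rel <- rel + gcamp_kernel(times - te, truth$kernel)
  }
  values <- truth$f_base_true * (1 + rel)
  if (truth$noise_sd > 0) {
    values <- values + stats::rnorm(n_frames, 0,
                                    truth$noise_sd * truth$f_base_true)
  }
  list(trace = fluorescence_trace(times, values, frame_period),
       event_times = event_times)
}

#' Simulate a full temperature experiment
#'
#' Draws a per-trial true detection distance from each treatment's normal
#' distribution (truncated to the attainable range), simulates every trial,
#' and returns the labelled trials plus a ground-truth table.
#'
#' @param model A [temperature_effect_model()].
#' @param n_trials_per_temp Trials per treatment (>= 2).
#' @param kin,geo Stimulus kinematics and eye geometry shared by all trials.
#' @param frame_period Frame period in s.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `trials` (list of per-trial lists: `trial_id`,
#'   `temperature`, `trace`, `event_times`) and `truth` (data frame with one
#'   row per trial: `trial_id`, `temperature`, `dd_true`, `tau_decay`,
#'   `amplitude`).
#' @export
simulate_experiment <- function(model = temperature_effect_model(),
                                n_trials_per_temp = 20L,
                                kin = stimulus_kinematics(),
                                geo = eye_geometry(),
                                frame_period = 0.05, seed = NULL) {
  stopifnot(n_trials_per_temp >= 2)
  if (!is.null(seed)) set.seed(seed)
  dmin <- geo$eye_screen_distance
  dmax <- max_attainable_distance(kin, geo)
  trials <- list()
  truth_rows <- list()
  id <- 0L
  for (g in seq_len(nrow(model))) {
    for (j in seq_len(n_trials_per_temp)) {
      id <- id + 1L
      dd <- if (model$dd_sd[g] > 0) {
        # truncate by redrawing; the defaults put the mass well inside range
        repeat {
          cand <- stats::rnorm(1, model$dd_mean[g], model$dd_sd[g])
          if (cand >= dmin && cand <= dmax) break
        }
        cand
      } else {
        model$dd_mean[g]
      }
      tr <- synthetic_truth(
        dd_true = dd,
        kernel = kernel_params(model$tau_rise[g], model$tau_decay_mean[g],
                               model$amplitude[g]),
        noise_sd = model$noise_sd[g]
      )
      sim <- simulate_trial(tr, kin, geo, frame_period)
      trials[[id]] <- list(trial_id = id,
                           temperature = model$temperature[g],
                           trace = sim$trace,
                           event_times = sim$event_times)
      truth_rows[[id]] <- data.frame(trial_id = id,
                                     temperature = model$temperature[g],
                                     dd_true = dd,
                                     tau_decay = model$tau_decay_mean[g],
                                     amplitude = model$amplitude[g])
    }
  }
  list(trials = trials, truth = do.call(rbind, truth_rows))
}

#' Render a fluorescence trace as a synthetic image stack
#'
#' Builds one frame per trace sample: pixels on a ring annulus carry the
#' trace value, everything else the background, plus Gaussian read noise.
#'
#' @param trace A [fluorescence_trace()].
#' @param image_shape `c(n_rows, n_cols)` in pixels.
#' @param roi_center Ring centre as `c(row, col)` (1-based pixel coords).
#' @param roi_diameter_um Ring outer diameter in micrometres (default 10).
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param background Background pixel value (a.u.).
#' @param noise_sd Gaussian read-noise SD (a.u.).
#' @param thickness Ring thickness in pixels.
#' @param seed Optional integer seed.
#' @return A numeric array `[row, col, frame]` with attribute `frame_period`.
#' @export
render_stack <- function(trace, image_shape = c(64L, 64L),
                         roi_center = c(32, 32), roi_diameter_um = 10,
                         pixel_size_um = 0.457, background = 10,
                         noise_sd = 0, thickness = 1, seed = NULL) {
  roi <- ring_roi(center = roi_center, diameter = roi_diameter_um,
                  pixel_size = pixel_size_um, thickness = thickness)
  mask <- ring_mask(roi, image_shape)  # errors if the ring is out of bounds
  if (!is.null(seed)) set.seed(seed)
  n_frames <- length(trace$values)
  stack <- array(background, dim = c(image_shape[1], image_shape[2],
                                     n_frames))
  idx <- which(mask)
  npx <- prod(image_shape)
  for (f in seq_len(n_frames)) {
    stack[idx + (f - 1L) * npx] <- trace$values[f]
  }
  if (noise_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                           dim = dim(stack))
  }
  attr(stack, "frame_period") <- trace$frame_period
  stack
}

#' Write an image stack as a multi-page TIFF
#'
#' Scales values into [0, 1] as required by the TIFF writer and records the
#' scale factor; intended for fixtures and the command-line interface.
#'
#' @param stack Array `[row, col, frame]` of non-negative values.
#' @param path Output file path.
#' @param scale Divisor applied before writing; defaults to the stack max.
#' @return Invisibly, the scale used.
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack)) {
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(f) stack[, , f] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Read a single-channel multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param scale Multiplier applied after reading (inverse of the writer's).
#' @return A numeric array `[row, col, frame]`.
#' @export
read_stack_tiff <- function(path, scale = 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(fr) {
    if (length(dim(fr)) == 3) fr <- fr[, , 1]
    fr
  })
  out <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (f in seq_along(frames)) out[, , f] <- frames[[f]] * scale
  out
}
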