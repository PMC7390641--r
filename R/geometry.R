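# Stimulus geometry: the moving-glyph trajectory on the OLED screen and the
# eye--screen right triangle that converts lateral screen positions into
# eye-to-stimulus distances.

#' OLED screen specification
#'
#' Physical description of the miniature display used to present the moving
#' prey-like glyph. Defaults describe a 64x48 monochrome OLED with 0.21 mm
#' pixel pitch and 0.19 mm dot size.
#'
#' @param n_cols,n_rows Display resolution in pixels.
#' @param pixel_pitch Centre-to-centre pixel spacing in mm.
#' @param dot_size Lit dot size in mm; must not exceed `pixel_pitch`.
#' @param contrast_ratio Display contrast ratio (dimensionless).
#' @return An object of class `screen_spec`.
#' @export
#' @examples
#' screen_spec()
screen_spec <- function(n_cols = 64L, n_rows = 48L, pixel_pitch = 0.21,
                        dot_size = 0.19, contrast_ratio = 2000) {
  stopifnot(n_cols >= 1, n_rows >= 1, pixel_pitch > 0, dot_size > 0,
            contrast_ratio > 0)
  if (dot_size > pixel_pitch) {
    stop("dot_size must not exceed pixel_pitch", call. = FALSE)
  }
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 pixel_pitch = pixel_pitch, dot_size = dot_size,
                 contrast_ratio = contrast_ratio),
            class = "screen_spec")
}

#' Stimulus kinematics
#'
#' Triangular-wave trajectory of the glyph along the screen: repeated
#' approach--recede cycles at constant speed, with an optional dwell (pause)
#' at the track ends. The lateral coordinate `x` is measured along the screen
#' from the closest-approach point (`x = 0` opposite the eye); an approach
#' leg is decreasing `x`.
#'
#' Defaults follow the experimental protocol: speed 2.1 mm/s (pixel pitch
#' 0.21 mm advanced every 0.1 s), one-way track 30 pixels = 6.3 mm, ten
#' cycles. A round trip at 2.1 mm/s over 6.3 mm takes 6 s while ten cycles
#' span two minutes, so the default dwell is 6 s per cycle, split equally
#' between the two track ends.
#'
#' @param speed Glyph speed in mm/s while moving.
#' @param track_length One-way track length in mm.
#' @param start_offset Lateral position (mm) where the glyph sits before
#'   motion begins; defaults to the far end of the track.
#' @param n_cycles Number of approach--recede cycles.
#' @param t_move_start Time (s) at which motion begins.
#' @param dwell_per_cycle Total stationary time (s) per cycle, split equally
#'   between the near and far track ends.
#' @return An object of class `stimulus_kinematics`.
#' @export
#' @examples
#' kin <- stimulus_kinematics()
#' cycle_period(kin)  # 12 s
stimulus_kinematics <- function(speed = 2.1, track_length = 6.3,
                                start_offset = track_length, n_cycles = 10L,
                                t_move_start = 0, dwell_per_cycle = 6) {
  stopifnot(speed > 0, track_length > 0, n_cycles >= 1, t_move_start >= 0,
            dwell_per_cycle >= 0)
  if (start_offset < 0 || start_offset > track_length) {
    stop("start_offset must lie within [0, track_length]", call. = FALSE)
  }
  structure(list(speed = speed, track_length = track_length,
                 start_offset = start_offset, n_cycles = as.integer(n_cycles),
                 t_move_start = t_move_start,
                 dwell_per_cycle = dwell_per_cycle),
            class = "stimulus_kinematics")
}

#' Eye--screen geometry
#'
#' The right triangle used to convert a lateral glyph position into an
#' eye-to-stimulus distance: the eye sits `eye_screen_distance` (|bc|) from
#' the screen, opposite the lateral coordinate `eye_opposite_x` (point b).
#'
#' @param eye_screen_distance Perpendicular eye-to-screen distance |bc| in mm.
#' @param eye_opposite_x Lateral coordinate (mm) of the screen point opposite
#'   the eye.
#' @return An object of class `eye_geometry`.
#' @export
eye_geometry <- function(eye_screen_distance = 1.0, eye_opposite_x = 0) {
  stopifnot(eye_screen_distance > 0)
  structure(list(eye_screen_distance = eye_screen_distance,
                 eye_opposite_x = eye_opposite_x),
            class = "eye_geometry")
}

#' Glyph specification
#'
#' The cross-shaped (plus-sign) glyph drawn with 5 pixels spanning an odd
#' number of pixel pitches in each direction.
#'
#' @param n_pixels Number of lit pixels forming the glyph.
#' @param extent_pitches Glyph extent in pixel pitches (odd, >= 1).
#' @return An object of class `glyph_spec`.
#' @export
glyph_spec <- function(n_pixels = 5L, extent_pitches = 3L) {
  stopifnot(n_pixels >= 1, extent_pitches >= 1)
  if (extent_pitches %% 2 != 1) {
    stop("extent_pitches must be odd", call. = FALSE)
  }
  structure(list(n_pixels = as.integer(n_pixels),
                 extent_pitches = as.integer(extent_pitches)),
            class = "glyph_spec")
}

#' @export
print.stimulus_kinematics <- function(x, ...) {
  cat("Stimulus kinematics: speed", x$speed, "mm/s, track", x$track_length,
      "mm,", x$n_cycles, "cycles,",
      "dwell", x$dwell_per_cycle, "s/cycle, motion starts at t =",
      x$t_move_start, "s\n")
  invisible(x)
}

#' Cycle period of the triangular trajectory
#'
#' One full approach--recede cycle: `2 * track_length / speed +
#' dwell_per_cycle` seconds.
#'
#' @param kin A [stimulus_kinematics()] object.
#' @return Cycle period in seconds.
#' @export
cycle_period <- function(kin) {
  2 * kin$track_length / kin$speed + kin$dwell_per_cycle
}

#' Time at which all stimulus cycles have completed
#'
#' @param kin A [stimulus_kinematics()] object.
#' @return Time in seconds at which the last cycle ends.
#' @export
motion_end_time <- function(kin) {
  # the first approach leg may be shortened when start_offset < track_length
  first_short <- (kin$track_length - kin$start_offset) / kin$speed
  kin$t_move_start + kin$n_cycles * cycle_period(kin) - first_short
}

# Phase of the trajectory at time t (vectorised): one of "pre", "approach",
# "dwell_near", "recede", "dwell_far", "post", plus the cycle index and the
# lateral position. Internal workhorse for lateral_position / angular_speed /
# detection_distance_for_peak.
trajectory_state <- function(t, kin) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  period <- cycle_period(kin)
  half_dwell <- kin$dwell_per_cycle / 2
  t_app <- kin$track_length / kin$speed       # full approach-leg duration
  # shift so that every cycle (including the first) is laid out as a full
  # cycle starting with an approach from track_length; a start_offset short
  # of the far end simply enters the first approach leg part-way through
  offset0 <- (kin$track_length - kin$start_offset) / kin$speed
  u <- t - kin$t_move_start + offset0
  cyc <- floor(u / period)
  phase_t <- u - cyc * period
  x <- numeric(length(t))
  phase <- character(length(t))
  pre <- t < kin$t_move_start
  post <- cyc >= kin$n_cycles & !pre
  # the approach leg includes its endpoint: detection exactly at closest
  # approach still counts as an approach-phase event
  in_app <- !pre & !post & phase_t <= t_app
  in_dn <- !pre & !post & phase_t > t_app & phase_t < t_app + half_dwell
  in_rec <- !pre & !post & phase_t >= t_app + half_dwell &
    phase_t < 2 * t_app + half_dwell
  in_df <- !pre & !post & phase_t >= 2 * t_app + half_dwell
  x[pre] <- kin$start_offset
  x[in_app] <- kin$track_length - kin$speed * phase_t[in_app]
  x[in_dn] <- 0
  x[in_rec] <- kin$speed * (phase_t[in_rec] - t_app - half_dwell)
  x[in_df] <- kin$track_length
  x[post] <- kin$track_length
  phase[pre] <- "pre"
  phase[post] <- "post"
  phase[in_app] <- "approach"
  phase[in_dn] <- "dwell_near"
  phase[in_rec] <- "recede"
  phase[in_df] <- "dwell_far"
  list(x = pmin(pmax(x, 0), kin$track_length), phase = phase,
       cycle = as.integer(pmin(pmax(cyc, 0), kin$n_cycles - 1L)))
}

#' Lateral glyph position at a given time
#'
#' Piecewise-linear triangular wave: constant at `start_offset` before motion
#' starts, slope `-speed` on approach legs and `+speed` on receding legs,
#' constant during dwells, and constant at the far track end once all cycles
#' have completed.
#'
#' @param t Time(s) in seconds, non-negative; vectorised.
#' @param kin A [stimulus_kinematics()] object.
#' @return Lateral position(s) in mm, within `[0, track_length]`.
#' @export
#' @examples
#' kin <- stimulus_kinematics(dwell_per_cycle = 0)
#' lateral_position(3, kin)  # 0: full one-way traverse of 6.3 mm at 2.1 mm/s
lateral_position <- function(t, kin) {
  trajectory_state(t, kin)$x
}

#' Eye-to-stimulus distance from a lateral screen position
#'
#' Hypotenuse of the right triangle with legs `|x - eye_opposite_x|` (along
#' the screen) and `eye_screen_distance` (perpendicular to it):
#' `sqrt((x - b)^2 + |bc|^2)`.
#'
#' @param x Lateral position(s) in mm, non-negative; vectorised.
#' @param geo An [eye_geometry()] object.
#' @return Distance(s) in mm; always >= `eye_screen_distance`.
#' @export
#' @examples
#' distance_from_lateral(6.3, eye_geometry())  # sqrt(40.69) = 6.3789 mm
distance_from_lateral <- function(x, geo) {
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  sqrt((x - geo$eye_opposite_x)^2 + geo$eye_screen_distance^2)
}

#' Eye-to-stimulus distance at a given time
#'
#' Composition of [lateral_position()] and [distance_from_lateral()].
#'
#' @inheritParams lateral_position
#' @param geo An [eye_geometry()] object.
#' @return Distance(s) in mm.
#' @export
distance_at_time <- function(t, kin, geo) {
  distance_from_lateral(lateral_position(t, kin), geo)
}

#' Largest eye-to-stimulus distance attainable on the track
#'
#' @param kin A [stimulus_kinematics()] object.
#' @param geo An [eye_geometry()] object.
#' @return Distance in mm of the track end farthest from the eye.
#' @export
max_attainable_distance <- function(kin, geo) {
  max(distance_from_lateral(c(0, kin$track_length), geo))
}

#' First time the stimulus comes within a given distance on an approach leg
#'
#' Exact analytic inversion of the piecewise-linear trajectory: the earliest
#' time on the approach leg of cycle `cycle` at which the eye-to-stimulus
#' distance drops to `dd` or below. Used by the synthetic generator to place
#' ground-truth events and by recovery tests as the inverse of the forward
#' pipeline.
#'
#' @param dd Target distance in mm; must lie within the attainable range
#'   `[eye_screen_distance, max_attainable_distance(kin, geo)]`.
#' @param kin A [stimulus_kinematics()] object.
#' @param geo An [eye_geometry()] object.
#' @param cycle Zero-based cycle index, `< n_cycles`.
#' @return Time in seconds.
#' @export
#' @examples
#' kin <- stimulus_kinematics(dwell_per_cycle = 0)
#' first_time_within(1.0, kin, eye_geometry(), cycle = 0)  # 3 s
first_time_within <- function(dd, kin, geo, cycle = 0L) {
  stopifnot(length(dd) == 1, length(cycle) == 1, cycle >= 0,
            cycle < kin$n_cycles)
  dmax <- max_attainable_distance(kin, geo)
  if (dd < geo$eye_screen_distance || dd > dmax) {
    stop("dd outside the attainable distance range [",
         format(geo$eye_screen_distance), ", ", format(dmax), "] mm",
         call. = FALSE)
  }
  period <- cycle_period(kin)
  t_app <- kin$track_length / kin$speed
  offset0 <- (kin$track_length - kin$start_offset) / kin$speed
  leg_start <- kin$t_move_start - offset0 + cycle * period
  x_start <- if (cycle == 0) kin$start_offset else kin$track_length
  # lateral threshold on the approach side (x decreasing toward b from above)
  lat <- sqrt(max(dd^2 - geo$eye_screen_distance^2, 0))
  x_dd <- geo$eye_opposite_x + lat
  if (x_start <= x_dd) {
    return(leg_start + (kin$track_length - x_start) / kin$speed)
  }
  leg_start + (kin$track_length - x_dd) / kin$speed
}

#' Glyph speed implied by the pixel-jump cadence
#'
#' The glyph advances one pixel pitch per jump interval, so its continuous
#' speed is `pixel_pitch / jump_interval` (0.21 mm / 0.1 s = 2.1 mm/s with
#' the defaults).
#'
#' @param screen A [screen_spec()] object.
#' @param jump_interval Time between pixel jumps in s.
#' @return Speed in mm/s.
#' @export
pixel_speed <- function(screen, jump_interval = 0.1) {
  stopifnot(jump_interval > 0)
  screen$pixel_pitch / jump_interval
}

#' Glyph extent in millimetres
#'
#' @param glyph A [glyph_spec()] object.
#' @param screen A [screen_spec()] object.
#' @return Outer glyph dimension in mm: `extent_pitches * pixel_pitch`.
#' @export
#' @examples
#' glyph_extent(glyph_spec(), screen_spec())  # 0.63 mm
glyph_extent <- function(glyph, screen) {
  glyph$extent_pitches * screen$pixel_pitch
}

#' Angular size of an object at a viewing distance
#'
#' Full visual angle `2 * atan(width / (2 * distance))`, in degrees.
#'
#' @param width Object width in mm; positive.
#' @param distance Viewing distance in mm; positive. Vectorised.
#' @return Angular size(s) in degrees; monotone decreasing in distance.
#' @export
#' @examples
#' angular_size(0.63, 1)  # glyph seen from 1 mm
angular_size <- function(width, distance) {
  if (any(width <= 0) || any(distance <= 0)) {
    stop("width and distance must be positive", call. = FALSE)
  }
  2 * atan(width / (2 * distance)) * 180 / pi
}

#' Angular speed of the glyph as seen from the eye
#'
#' Magnitude of the time derivative of the bearing angle
#' `atan((x(t) - b) / |bc|)`:
#' `speed * |bc| / (|bc|^2 + (x - b)^2)` radians/s, converted to degrees/s.
#' Returns 0 during dwell phases and outside the motion window.
#'
#' @inheritParams distance_at_time
#' @return Angular speed(s) in degrees/s.
#' @export
angular_speed <- function(t, kin, geo) {
  st <- trajectory_state(t, kin)
  moving <- st$phase %in% c("approach", "recede")
  out <- numeric(length(t))
  bc <- geo$eye_screen_distance
  dx <- st$x[moving] - geo$eye_opposite_x
  out[moving] <- kin$speed * bc / (bc^2 + dx^2) * 180 / pi
  out
}
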