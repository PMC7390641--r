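# Ring-ROI extraction: mean-fluorescence traces from image stacks and the
# response-score search that locates the most responsive ring.

#' Ring-shaped region of interest
#'
#' A 1-pixel-thick annulus (by default) of given outer diameter, mirroring
#' the 10 micrometre ring used to read out the responsive tectal neuropil.
#'
#' @param center Ring centre as `c(row, col)`, 1-based pixel coordinates.
#' @param diameter Ring diameter in micrometres (default 10).
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param thickness Ring thickness in pixels.
#' @return An object of class `ring_roi`.
#' @export
ring_roi <- function(center, diameter = 10, pixel_size = 0.457,
                     thickness = 1) {
  stopifnot(length(center) == 2, diameter > 0, pixel_size > 0,
            thickness > 0)
  structure(list(center = as.numeric(center), diameter = diameter,
                 pixel_size = pixel_size, thickness = thickness),
            class = "ring_roi")
}

#' Ring radius in pixels
#' @param roi A [ring_roi()].
#' @return Radius in pixels: `diameter / (2 * pixel_size)`.
#' @export
ring_radius_px <- function(roi) {
  roi$diameter / (2 * roi$pixel_size)
}

#' Boolean mask of a ring ROI
#'
#' True exactly for pixels whose centre distance from the ring centre lies
#' within `[r - thickness/2, r + thickness/2]`, where `r` is the ring radius
#' in pixels.
#'
#' @param roi A [ring_roi()].
#' @param image_shape `c(n_rows, n_cols)`.
#' @return A logical matrix of dimension `image_shape`.
#' @export
ring_mask <- function(roi, image_shape) {
  r <- ring_radius_px(roi)
  lo <- r - roi$thickness / 2
  hi <- r + roi$thickness / 2
  if (roi$center[1] - hi < 0.5 || roi$center[2] - hi < 0.5 ||
      roi$center[1] + hi > image_shape[1] + 0.5 ||
      roi$center[2] + hi > image_shape[2] + 0.5) {
    stop("ring extends outside the image bounds", call. = FALSE)
  }
  rows <- matrix(seq_len(image_shape[1]), image_shape[1], image_shape[2])
  cols <- matrix(seq_len(image_shape[2]), image_shape[1], image_shape[2],
                 byrow = TRUE)
  d <- sqrt((rows - roi$center[1])^2 + (cols - roi$center[2])^2)
  mask <- d >= lo & d <= hi
  if (sum(mask) < 4) {
    stop("ring mask contains fewer than 4 pixels", call. = FALSE)
  }
  mask
}

#' Extract a mean-fluorescence trace from an image stack
#'
#' Per-frame mean over the masked ring pixels; the time axis is the frame
#' index times the frame period.
#'
#' @param stack Numeric array `[row, col, frame]`.
#' @param roi A [ring_roi()].
#' @param frame_period Frame period in s; defaults to the stack's
#'   `frame_period` attribute, else 0.05.
#' @return A [fluorescence_trace()].
#' @export
extract_trace <- function(stack, roi, frame_period = NULL) {
  if (is.null(frame_period)) {
    frame_period <- attr(stack, "frame_period")
    if (is.null(frame_period)) frame_period <- 0.05
  }
  dims <- dim(stack)
  stopifnot(length(dims) == 3, dims[3] >= 1)
  mask <- ring_mask(roi, dims[1:2])
  idx <- which(mask)
  npx <- dims[1] * dims[2]
  vals <- vapply(seq_len(dims[3]),
                 function(f) mean(stack[idx + (f - 1L) * npx]),
                 numeric(1))
  fluorescence_trace((seq_len(dims[3]) - 1L) * frame_period, vals,
                     frame_period, validate_length = FALSE)
}

#' Select the ring ROI maximising the response score
#'
#' Scores every candidate centre by the F_max/F_base ratio of its extracted
#' trace (baseline from the two-pass peak-aware estimator) and returns the
#' best ring; ties are broken deterministically by the lowest (row, col).
#'
#' @param stack Numeric array `[row, col, frame]`.
#' @param candidate_centers Matrix or data frame with columns (row, col);
#'   default: every pixel whose ring fits in bounds, at `stride` spacing.
#' @param roi_template A [ring_roi()] supplying diameter, pixel size and
#'   thickness; its centre is ignored.
#' @param stride Candidate-grid spacing in pixels for the default grid.
#' @param frame_period Frame period in s passed to [extract_trace()].
#' @return The winning [ring_roi()], with attributes `score` (F_max/F_base)
#'   and `trace`.
#' @export
select_roi <- function(stack, candidate_centers = NULL,
                       roi_template = ring_roi(c(1, 1)), stride = 1L,
                       frame_period = NULL) {
  dims <- dim(stack)
  hi <- ring_radius_px(roi_template) + roi_template$thickness / 2
  margin <- ceiling(hi + 0.5)
  if (is.null(candidate_centers)) {
    rows <- seq(margin, dims[1] - margin + 1L, by = stride)
    cols <- seq(margin, dims[2] - margin + 1L, by = stride)
    if (!length(rows) || !length(cols)) {
      stop("no candidate centre admits a full ring inside the image",
           call. = FALSE)
    }
    candidate_centers <- as.matrix(expand.grid(row = rows, col = cols))
  }
  candidate_centers <- as.matrix(candidate_centers)
  stopifnot(nrow(candidate_centers) >= 1)
  # deterministic tie-break: scan in lexicographic (row, col) order and keep
  # strict improvements only
  ord <- order(candidate_centers[, 1], candidate_centers[, 2])
  candidate_centers <- candidate_centers[ord, , drop = FALSE]
  best <- NULL
  best_score <- -Inf
  for (i in seq_len(nrow(candidate_centers))) {
    roi <- ring_roi(candidate_centers[i, ], roi_template$diameter,
                    roi_template$pixel_size, roi_template$thickness)
    tr <- extract_trace(stack, roi, frame_period)
    score <- tryCatch(roi_response_score(tr), error = function(e) NA_real_)
    if (!is.na(score) && score > best_score) {
      best_score <- score
      best <- roi
      attr(best, "trace") <- tr
    }
  }
  if (is.null(best)) {
    stop("all candidate traces are degenerate (flat or zero baseline)",
         call. = FALSE)
  }
  attr(best, "score") <- best_score
  best
}

# F_max/F_base of a trace: maximum over the peak-aware baseline. Degenerate
# (flat or non-positive-baseline) traces raise an error.
roi_response_score <- function(trace) {
  an <- analyze_trace(trace)
  if (an$f_base <= 0) {
    stop("degenerate trace: non-positive baseline", call. = FALSE)
  }
  max(trace$values) / an$f_base
}
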