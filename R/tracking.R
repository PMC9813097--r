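#' Segment the two eyes in one frame
#'
#' Each region of interest is thresholded (Otsu on the ROI histogram; dark
#' objects by default) and the largest connected component kept. An empty
#' component flags that eye as missing for the frame.
#'
#' @param frame Numeric intensity matrix `[row, col]` (any range; 8-bit
#'   levels typical).
#' @param rois A list of two ROIs, each `c(x_min, x_max, y_min, y_max)` in
#'   pixel coordinates (as in `render_geometry()$rois`). Must lie within
#'   the frame and not overlap.
#' @param dark_objects If `TRUE` (default) the eyes are darker than the
#'   background (infrared illumination from above); set `FALSE` to flip
#'   polarity.
#' @return A list of two logical mask matrices (full frame size), possibly
#'   `NULL` where segmentation failed.
#' @export
segment_eyes <- function(frame, rois, dark_objects = TRUE) {
  stopifnot(length(rois) == 2)
  for (r in rois) {
    if (r["x_min"] < 1 || r["y_min"] < 1 ||
        r["x_max"] > ncol(frame) || r["y_max"] > nrow(frame)) {
      abort("ROI outside frame bounds.")
    }
  }
  if (rois_overlap(rois[[1]], rois[[2]])) abort("ROIs overlap.")
  lapply(rois, function(r) {
    rows <- r["y_min"]:r["y_max"]; cols <- r["x_min"]:r["x_max"]
    sub <- frame[rows, cols, drop = FALSE]
    rng <- range(sub)
    if (diff(rng) < 1e-9) return(NULL) # flat ROI: nothing to segment
    norm <- (sub - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    obj <- if (dark_objects) norm < th else norm > th
    lab <- EBImage::bwlabel(EBImage::Image(obj * 1))
    lab <- EBImage::imageData(lab)
    if (max(lab) < 1) return(NULL)
    counts <- tabulate(lab[lab > 0])
    keep <- which.max(counts)
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    mask[rows, cols] <- lab == keep
    mask
  })
}

rois_overlap <- function(a, b) {
  a["x_min"] <= b["x_max"] && b["x_min"] <= a["x_max"] &&
    a["y_min"] <= b["y_max"] && b["y_min"] <= a["y_max"]
}

#' Fit an ellipse to a binary mask by image moments
#'
#' Center = centroid; orientation from the second-order central moments,
#' `theta = 0.5 * atan2(2 * mu11, mu20 - mu02)`, mapped to (-90, +90] deg
#' (counterclockwise positive, y-axis up); semi-axes from the moment
#' eigenvalues (`a = 2 * sqrt(lambda_max)` matches an exact filled
#' ellipse). Near-circular masks (a/b below `ecc_threshold`) have an
#' ill-defined orientation and are flagged `eccentricity_ok = FALSE`.
#'
#' @param mask Logical matrix `[row, col]`; must contain at least one
#'   `TRUE` pixel.
#' @param ecc_threshold Minimum axis ratio a/b for a trustworthy
#'   orientation.
#' @return A one-row tibble: `center_x`, `center_y` (raster pixel
#'   coordinates), `semi_major`, `semi_minor` (pixels),
#'   `orientation_deg` in (-90, 90], `eccentricity_ok`.
#' @examples
#' m <- matrix(FALSE, 40, 60)
#' m[11:30, 11:50] <- TRUE # wide rectangle: horizontal long axis
#' fit_ellipse(m)$orientation_deg # 0
#' @export
fit_ellipse <- function(mask, ecc_threshold = 1.2) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) abort("empty mask.")
  x <- idx[, 2]
  y <- -idx[, 1] # y-axis up
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  a <- 2 * sqrt(max(l1, 0))
  b <- 2 * sqrt(max(l2, 0))
  ok <- b > 0 && (a / b) >= ecc_threshold
  tibble::tibble(
    center_x = cx, center_y = -cy,
    semi_major = a, semi_minor = b,
    orientation_deg = if (ok) theta else NA_real_,
    eccentricity_ok = ok
  )
}

#' Track both eyes through an image stack
#'
#' Per-frame segmentation and moment-based ellipse fitting, followed by
#' temporal unwrapping of the orientation series: among the
#' 180-deg-equivalent orientations, the one closest to the previous valid
#' frame is chosen, so a series crossing +90 deg shows no 180-deg jump.
#' Missing frames are flagged, not interpolated (interpolation belongs to
#' the preprocessing stage).
#'
#' @param stack A `phantom_stack` from [render_frames()], or a numeric
#'   array `height x width x n`.
#' @param rois Two eye ROIs (defaults to the stack geometry's).
#' @param timestamps Frame times, s (defaults to the stack truth's).
#' @param max_missing Maximum tolerated fraction of missing frames per
#'   eye.
#' @param ... Passed to [segment_eyes()] and [fit_ellipse()].
#' @return An eye-track tibble: `time_s`, `left_deg`, `right_deg`,
#'   `left_ok`, `right_ok`.
#' @export
track_eyes <- function(stack, rois = NULL, timestamps = NULL,
                       max_missing = 0.5, ...) {
  if (inherits(stack, "phantom_stack")) {
    rois <- rois %||% stack$geometry$rois
    timestamps <- timestamps %||% stack$truth$time_s
    stack <- stack$frames
  }
  if (is.null(rois)) abort("eye ROIs required.")
  n <- dim(stack)[3]
  if (!n) abort("empty stack.")
  timestamps <- timestamps %||% seq_len(n)

  dots <- list(...)
  seg_args <- dots[names(dots) %in% "dark_objects"]
  fit_args <- dots[names(dots) %in% "ecc_threshold"]

  ang <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    masks <- do.call(segment_eyes,
                     c(list(stack[, , i], rois = rois), seg_args))
    for (e in 1:2) {
      if (is.null(masks[[e]])) next
      f <- do.call(fit_ellipse, c(list(masks[[e]]), fit_args))
      if (f$eccentricity_ok) ang[i, e] <- f$orientation_deg
    }
  }
  missing_frac <- colMeans(is.na(ang))
  if (any(missing_frac > max_missing)) {
    abort(sprintf("more than %.0f%% of frames missing for one eye.",
                  100 * max_missing))
  }
  for (e in 1:2) ang[, e] <- unwrap_orientation(ang[, e])
  tibble::tibble(
    time_s = timestamps,
    left_deg = ang[, 1], right_deg = ang[, 2],
    left_ok = !is.na(ang[, 1]), right_ok = !is.na(ang[, 2])
  )
}

# Choose, per frame, the +/-180-deg-equivalent orientation closest to the
# previous valid value.
unwrap_orientation <- function(theta) {
  prev <- NA_real_
  for (i in seq_along(theta)) {
    if (is.na(theta[i])) next
    if (!is.na(prev)) {
      cand <- theta[i] + c(-180, 0, 180)
      theta[i] <- cand[which.min(abs(cand - prev))]
    }
    prev <- theta[i]
  }
  theta
}
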