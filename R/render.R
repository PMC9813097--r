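#' Geometry of the rendered phantom view
#'
#' Describes the top-down camera view used for phantom videos: two filled
#' dark ellipses ("eyes") on a light background. Angles follow the
#' package-wide convention: degrees, counterclockwise positive, measured
#' from the image horizontal with the y-axis taken upward (raster rows
#' flipped).
#'
#' @param width,height Image size, pixels.
#' @param left_center,right_center Eye centers, pixel coordinates
#'   `c(x, y)` with y as raster row.
#' @param semi_major,semi_minor Eye semi-axes a > b > 0, pixels.
#' @param foreground,background Eye and background intensities, 8-bit
#'   levels (dark-on-light by default).
#' @return An object of class `render_geometry` (includes the two eye ROIs
#'   used by the tracker).
#' @export
render_geometry <- function(width = 200, height = 120,
                            left_center = c(55, 60),
                            right_center = c(145, 60),
                            semi_major = 20, semi_minor = 10,
                            foreground = 40, background = 200) {
  if (!(semi_major > semi_minor && semi_minor > 0)) {
    abort("need semi_major > semi_minor > 0 (otherwise orientation is undefined).")
  }
  gap <- sqrt(sum((left_center - right_center)^2))
  if (gap <= 2 * semi_major) abort("eyes overlap: centers closer than 2 * semi_major.")
  half <- ceiling(semi_major) + 4
  roi <- function(center) {
    c(x_min = max(1, center[1] - half), x_max = min(width, center[1] + half),
      y_min = max(1, center[2] - half), y_max = min(height, center[2] + half))
  }
  structure(
    list(width = width, height = height,
         left_center = left_center, right_center = right_center,
         semi_major = semi_major, semi_minor = semi_minor,
         foreground = foreground, background = background,
         rois = list(left = roi(left_center), right = roi(right_center))),
    class = "render_geometry"
  )
}

# Fill one ellipse into an intensity matrix [row, col]. Angle in degrees,
# CCW-positive with y up, so the raster dy is negated.
draw_ellipse <- function(img, center, a, b, angle_deg, value) {
  th <- angle_deg * pi / 180
  nr <- nrow(img); nc <- ncol(img)
  x0 <- max(1, floor(center[1] - a - 1)); x1 <- min(nc, ceiling(center[1] + a + 1))
  y0 <- max(1, floor(center[2] - a - 1)); y1 <- min(nr, ceiling(center[2] + a + 1))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - center[1])
  dy <- outer(-(ys - center[2]), rep(1, length(xs))) # y up
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  inside <- u^2 + v^2 <= 1
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- value
  img[ys, xs] <- sub
  img
}

#' Render a phantom image stack from eye angles
#'
#' Each frame contains two filled dark ellipses on a light background,
#' their long axes rotated to the frame's left/right eye angles. The
#' per-frame ground-truth angles are returned alongside for end-to-end
#' tracker validation.
#'
#' @param angles A tibble with columns `time_s`, `left_deg`, `right_deg`
#'   (e.g. a down-sampled [simulate_animal()] recording).
#' @param geometry A [render_geometry()].
#' @return A list of class `phantom_stack`: `frames` (numeric array
#'   `height x width x n`, 8-bit levels), `truth` (the input angle tibble)
#'   and `geometry`.
#' @export
render_frames <- function(angles, geometry = render_geometry()) {
  stopifnot(inherits(geometry, "render_geometry"))
  need <- c("time_s", "left_deg", "right_deg")
  if (!all(need %in% names(angles))) {
    abort("`angles` needs columns time_s, left_deg, right_deg.")
  }
  n <- nrow(angles)
  frames <- array(geometry$background,
                  dim = c(geometry$height, geometry$width, n))
  for (i in seq_len(n)) {
    img <- matrix(geometry$background, geometry$height, geometry$width)
    img <- draw_ellipse(img, geometry$left_center, geometry$semi_major,
                        geometry$semi_minor, angles$left_deg[i],
                        geometry$foreground)
    img <- draw_ellipse(img, geometry$right_center, geometry$semi_major,
                        geometry$semi_minor, angles$right_deg[i],
                        geometry$foreground)
    frames[, , i] <- img
  }
  structure(
    list(frames = frames, truth = angles, geometry = geometry),
    class = "phantom_stack"
  )
}
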