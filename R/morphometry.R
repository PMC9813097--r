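#' Serial-section label mask stack
#'
#' Container for per-slice binary masks of two labels (Purkinje-cell
#' somata and dendritic regions) plus the physical metadata needed for
#' volume estimation.
#'
#' @param soma,dendrite Logical arrays `[row, col, slice]` (or a list of
#'   matrices) of the same shape.
#' @param pixel_size_um Pixel edge length, micrometres (> 0).
#' @param thickness_um Slice thickness, micrometres (> 0; 10 or 30 in the
#'   standard protocols).
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(soma, dendrite, pixel_size_um, thickness_um) {
  as_stack <- function(x) {
    if (is.list(x)) x <- simplify2array(x)
    if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
    storage.mode(x) <- "logical"
    x
  }
  soma <- as_stack(soma); dendrite <- as_stack(dendrite)
  if (!identical(dim(soma), dim(dendrite))) {
    abort("soma and dendrite stacks must have the same shape.")
  }
  if (pixel_size_um <= 0) abort("`pixel_size_um` must be > 0.")
  if (thickness_um <= 0) abort("`thickness_um` must be > 0.")
  structure(
    list(soma = soma, dendrite = dendrite,
         pixel_size_um = pixel_size_um, thickness_um = thickness_um,
         n_slices = dim(soma)[3]),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf(
    "<mask_stack> %d slice(s) of %d x %d px, %g um/px, %g um thick\n",
    x$n_slices, dim(x$soma)[1], dim(x$soma)[2], x$pixel_size_um,
    x$thickness_um
  ))
  invisible(x)
}

#' Volume of one label across a slice stack
#'
#' Per-slice area (pixel count times squared pixel size) multiplied by the
#' slice thickness and summed across slices - the standard serial-section
#' volume approximation, with no overlap correction between adjacent
#' slices.
#'
#' @param stack A [mask_stack()].
#' @param label `"soma"` or `"dendrite"`.
#' @return Volume in cubic micrometres.
#' @examples
#' m <- array(FALSE, c(20, 20, 10)); m[1:10, 1:10, ] <- TRUE
#' st <- mask_stack(m, m, pixel_size_um = 1, thickness_um = 30)
#' stack_volume(st, "soma") # 10 slices x 100 um^2 x 30 um = 3e4
#' @export
stack_volume <- function(stack, label = c("soma", "dendrite")) {
  stopifnot(inherits(stack, "mask_stack"))
  label <- match.arg(label)
  masks <- stack[[label]]
  areas <- apply(masks, 3, sum) * stack$pixel_size_um^2
  sum(areas * stack$thickness_um)
}

#' Dendrite and soma volumes with their ratio
#'
#' @param stack A [mask_stack()].
#' @return A one-row tibble: `soma_volume_um3`, `dendrite_volume_um3`,
#'   `ratio` (dendrite/soma).
#' @export
dendrite_soma_ratio <- function(stack) {
  soma <- stack_volume(stack, "soma")
  dend <- stack_volume(stack, "dendrite")
  if (soma <= 0) abort("soma volume is zero; ratio undefined.")
  tibble::tibble(
    soma_volume_um3 = soma,
    dendrite_volume_um3 = dend,
    ratio = dend / soma
  )
}

#' Synthetic ellipsoid phantom stack
#'
#' Voxelises an axis-aligned ellipsoid into a slice stack - a phantom with
#' a known analytic volume `(4/3) * pi * a * b * c` for validating the
#' serial-section volume approximation.
#'
#' @param semi_axes_um Ellipsoid semi-axes `c(a, b, c)` in micrometres;
#'   `c` is along the slicing axis.
#' @param pixel_size_um In-plane pixel size, micrometres.
#' @param thickness_um Slice thickness, micrometres.
#' @return A logical array `[row, col, slice]`.
#' @export
ellipsoid_mask_stack <- function(semi_axes_um, pixel_size_um = 1,
                                 thickness_um = 10) {
  a <- semi_axes_um[1]; b <- semi_axes_um[2]; c3 <- semi_axes_um[3]
  nx <- ceiling(2 * a / pixel_size_um) + 4
  ny <- ceiling(2 * b / pixel_size_um) + 4
  ns <- max(1, ceiling(2 * c3 / thickness_um))
  xs <- (seq_len(nx) - (nx + 1) / 2) * pixel_size_um
  ys <- (seq_len(ny) - (ny + 1) / 2) * pixel_size_um
  zs <- (seq_len(ns) - (ns + 1) / 2) * thickness_um # slice mid-planes
  out <- array(FALSE, c(ny, nx, ns))
  for (k in seq_len(ns)) {
    rad2 <- 1 - (zs[k] / c3)^2
    if (rad2 <= 0) next
    out[, , k] <- outer(ys^2 / (b^2 * rad2), xs^2 / (a^2 * rad2), "+") <= 1
  }
  out
}
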