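#' ImageStack: a pixel array with physical metadata
#'
#' The universal carrier between pipeline stages: a non-negative intensity
#' array with named axes (a subset of C, T, Z, Y, X), the physical metadata
#' needed for any unit-bearing computation (pixel size, z step, frame
#' interval), and an append-only provenance log of applied operations.
#'
#' @param pixels numeric array (or matrix). Dimensions must match `axes`.
#' @param axes character vector naming each dimension, e.g. `c("Y","X","Z")`.
#'   Allowed names: C, T, Z, Y, X. `Y` and `X` are mandatory.
#' @param pixel_size_nm physical pixel size (nm/pixel), or `NULL` if unknown.
#' @param z_step_um z spacing between planes (micrometres).
#' @param frame_interval_s time between frames (seconds).
#' @param channels optional character names for the C axis.
#' @param provenance list of operation records (created empty).
#' @return an object of class `ImageStack`.
#' @examples
#' s <- image_stack(matrix(0, 8, 8), c("Y", "X"), pixel_size_nm = 110)
#' @export
image_stack <- function(pixels, axes, pixel_size_nm = NULL, z_step_um = NULL,
                        frame_interval_s = NULL, channels = NULL,
                        provenance = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  stopifnot(is.array(pixels), length(dim(pixels)) == length(axes))
  if (!all(axes %in% c("C", "T", "Z", "Y", "X")) || anyDuplicated(axes))
    stop("axes must be a duplicate-free subset of C, T, Z, Y, X")
  if (!all(c("Y", "X") %in% axes)) stop("axes must include Y and X")
  if (any(dim(pixels) < 1)) stop("all axis lengths must be positive")
  for (v in c(pixel_size_nm, z_step_um, frame_interval_s))
    if (!is.null(v) && (!is.finite(v) || v <= 0))
      stop("physical metadata must be positive and finite")
  if (!is.null(channels)) stopifnot(length(channels) == dim(pixels)[match("C", axes)])
  structure(list(
    pixels = pixels, axes = axes,
    pixel_size_nm = pixel_size_nm, z_step_um = z_step_um,
    frame_interval_s = frame_interval_s,
    channels = channels, provenance = provenance
  ), class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat("ImageStack [", paste(x$axes, dim(x$pixels), sep = "=", collapse = ", "),
      "]\n", sep = "")
  if (!is.null(x$pixel_size_nm)) cat("  pixel size:", x$pixel_size_nm, "nm\n")
  if (!is.null(x$z_step_um)) cat("  z step:", x$z_step_um, "um\n")
  if (!is.null(x$frame_interval_s)) cat("  frame interval:", x$frame_interval_s, "s\n")
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "op"), collapse = " -> "), "\n")
  invisible(x)
}

# Append one provenance record (op name + parameter list). Append-only.
add_provenance <- function(stack, op, params = list()) {
  stack$provenance <- c(stack$provenance, list(list(op = op, params = params)))
  stack
}

#' Extract a single 2D plane from an ImageStack
#'
#' @param stack an [image_stack()].
#' @param channel,z,t 1-based indices along the C, Z and T axes; ignored when
#'   the corresponding axis is absent.
#' @return a numeric (Y, X) matrix.
#' @export
stack_plane <- function(stack, channel = 1L, z = 1L, t = 1L) {
  stopifnot(inherits(stack, "ImageStack"))
  idx <- lapply(seq_along(stack$axes), function(i) {
    switch(stack$axes[i],
           C = channel, Z = z, T = t,
           Y = seq_len(dim(stack$pixels)[i]),
           X = seq_len(dim(stack$pixels)[i]))
  })
  pl <- do.call(`[`, c(list(stack$pixels), idx, list(drop = FALSE)))
  yi <- match("Y", stack$axes); xi <- match("X", stack$axes)
  out <- matrix(aperm(pl, c(yi, xi, setdiff(seq_along(stack$axes), c(yi, xi)))),
                dim(stack$pixels)[yi], dim(stack$pixels)[xi])
  out
}

# Replace one plane (inverse of stack_plane); used by per-plane filters.
set_stack_plane <- function(stack, value, channel = 1L, z = 1L, t = 1L) {
  idx <- lapply(seq_along(stack$axes), function(i) {
    switch(stack$axes[i],
           C = channel, Z = z, T = t,
           Y = seq_len(dim(stack$pixels)[i]),
           X = seq_len(dim(stack$pixels)[i]))
  })
  yi <- match("Y", stack$axes); xi <- match("X", stack$axes)
  perm <- c(yi, xi, setdiff(seq_along(stack$axes), c(yi, xi)))
  arr <- array(value, dim = c(dim(stack$pixels)[yi], dim(stack$pixels)[xi],
                              rep(1L, length(perm) - 2L)))
  arr <- aperm(arr, order(perm))
  stack$pixels <- do.call(`[<-`, c(list(stack$pixels), idx, list(arr)))
  stack
}

# Axis length helper (0 if the axis is absent).
axis_len <- function(stack, ax) {
  i <- match(ax, stack$axes)
  if (is.na(i)) 0L else dim(stack$pixels)[i]
}

n_frames <- function(stack) max(1L, axis_len(stack, "T"))
n_planes <- function(stack) max(1L, axis_len(stack, "Z"))
n_channels <- function(stack) max(1L, axis_len(stack, "C"))

#' Write / read an ImageStack as multi-page TIFF plus JSON sidecar
#'
#' Pages are the Y-X planes in C-major, then T, then Z order; pixel data are
#' stored as uncompressed little-endian 32-bit IEEE floats. Physical metadata
#' (pixel_size_nm, z_step_um, frame_interval_s, channel names, axes) go to a
#' `.json` sidecar next to the TIFF. Only this dialect is read back.
#'
#' @param stack an [image_stack()].
#' @param path output path, conventionally ending in `.tif`.
#' @return `write_image_stack()` the path, invisibly; `read_image_stack()` an
#'   `ImageStack`.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ImageStack"))
  other <- setdiff(stack$axes, c("Y", "X"))
  planes <- list()
  nz <- n_planes(stack); nt <- n_frames(stack); nc <- n_channels(stack)
  for (z in seq_len(nz)) for (t in seq_len(nt)) for (ch in seq_len(nc))
    planes[[length(planes) + 1L]] <- stack_plane(stack, channel = ch, z = z, t = t)
  write_tiff_float(planes, path)
  meta <- list(axes = stack$axes, dim = dim(stack$pixels),
               pixel_size_nm = stack$pixel_size_nm, z_step_um = stack$z_step_um,
               frame_interval_s = stack$frame_interval_s, channels = stack$channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- read_tiff_float(path)
  axes <- meta$axes
  dm <- as.integer(meta$dim)
  arr <- array(0, dim = dm)
  st <- image_stack(arr, axes,
                    pixel_size_nm = meta$pixel_size_nm %||% NULL,
                    z_step_um = meta$z_step_um %||% NULL,
                    frame_interval_s = meta$frame_interval_s %||% NULL,
                    channels = meta$channels %||% NULL)
  nz <- n_planes(st); nt <- n_frames(st); nc <- n_channels(st)
  k <- 1L
  for (z in seq_len(nz)) for (t in seq_len(nt)) for (ch in seq_len(nc)) {
    st <- set_stack_plane(st, planes[[k]], channel = ch, z = z, t = t)
    k <- k + 1L
  }
  st
}
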