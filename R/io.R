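# Image and annotation IO. Raster data are plain numeric matrices indexed
# [row = y, col = x]; physical coordinates are (x, y) in micrometers with the
# origin at the top-left pixel corner and pixel centers at half-integers
# times the pixel size.

#' Construct a multi-channel z-stack
#'
#' @param voxels 4D numeric array indexed (z, channel, y, x).
#' @param channel_names character vector naming the channels.
#' @param pixel_size_um physical edge length of one pixel, micrometers.
#' @return a `multichannel_stack` object.
#' @export
multichannel_stack <- function(voxels, channel_names, pixel_size_um) {
  stopifnot(length(dim(voxels)) == 4L)
  if (length(channel_names) != dim(voxels)[2L])
    stop("channel_names length must match the channel dimension")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(voxels = voxels, channel_names = as.character(channel_names),
                 pixel_size_um = pixel_size_um),
            class = "multichannel_stack")
}

#' Construct a planar (2D) image
#'
#' @param pixels numeric matrix, rows indexing y and columns indexing x.
#' @param channel_name label of the channel.
#' @param pixel_size_um physical pixel size, micrometers.
#' @return a `planar_image` object.
#' @export
planar_image <- function(pixels, channel_name = "unnamed", pixel_size_um = 1) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(pixels = pixels, channel_name = channel_name,
                 pixel_size_um = pixel_size_um),
            class = "planar_image")
}

#' @export
print.planar_image <- function(x, ...) {
  cat(sprintf("<planar_image '%s' %d x %d px, %.4g um/px>\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Construct (and validate) an edge annotation
#'
#' Holds the manually drawn invasive and nuclear edges of a leader cell, and
#' optionally the closed polygon delimiting the front cytoplasm and the
#' protrusion tip. All coordinates in micrometers.
#'
#' @param invasive_edge,nuclear_edge open polylines (n x 2 matrices, n >= 2)
#'   in micrometers; the invasive edge is the d = 0 reference, the nuclear
#'   edge the d = 1 reference.
#' @param front_region optional closed polygon (n x 2) bounding the front
#'   cytoplasm.
#' @param tip optional length-2 point marking the protrusion tip.
#' @param boundary_tol_um tolerance used to check that the edges lie on the
#'   front-region boundary when one is supplied.
#' @return an `edge_annotation` object.
#' @export
edge_annotation <- function(invasive_edge, nuclear_edge, front_region = NULL,
                            tip = NULL, boundary_tol_um = 0.5) {
  invasive_edge <- as_points(invasive_edge)
  nuclear_edge <- as_points(nuclear_edge)
  for (nm in c("invasive_edge", "nuclear_edge")) {
    e <- get(nm)
    if (nrow(e) < 2L) stop(nm, " must have at least 2 points")
    if (polyline_self_intersects(e)) stop(nm, " is self-intersecting")
  }
  if (!is.null(front_region)) {
    front_region <- as_points(front_region)
    bd <- close_polygon(front_region)
    for (nm in c("invasive_edge", "nuclear_edge")) {
      d <- point_polyline_distance(get(nm), bd)
      if (any(d > boundary_tol_um))
        stop(nm, " does not lie on the front_region boundary (max deviation ",
             format(max(d)), " um)")
    }
  }
  if (!is.null(tip)) {
    tip <- as.numeric(tip)
    if (length(tip) != 2L) stop("tip must be a single (x, y) point")
  }
  structure(list(invasive_edge = invasive_edge, nuclear_edge = nuclear_edge,
                 front_region = front_region, tip = tip),
            class = "edge_annotation")
}

#' Load a TIFF file as a multi-channel stack
#'
#' Pages of a multi-page TIFF are interpreted as channels (optionally as
#' `n_z` z-slices per channel, channel-major); a plain 2D TIFF becomes a
#' single-slice, single-channel stack.
#'
#' @param path path to a readable TIFF.
#' @param channel_map named integer vector or list mapping channel label to
#'   0-based page/channel index.
#' @param pixel_size_um physical pixel size, micrometers.
#' @param n_z number of z-slices per channel (pages = channels * n_z,
#'   channel-major ordering).
#' @param intensity_scale multiply stored sample values by this factor
#'   (float TIFF samples are stored normalized to \[0, 1\]).
#' @return a [multichannel_stack].
#' @export
load_stack <- function(path, channel_map = NULL, pixel_size_um = 1,
                       n_z = 1L, intensity_scale = 1) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse RGB storage
    p * intensity_scale
  })
  n_pages <- length(pages)
  if (n_pages %% n_z != 0L) stop("page count ", n_pages,
                                 " is not a multiple of n_z = ", n_z)
  n_ch <- n_pages %/% n_z
  if (is.null(channel_map)) {
    channel_map <- stats::setNames(seq_len(n_ch) - 1L, paste0("ch", seq_len(n_ch) - 1L))
  }
  idx <- unlist(channel_map)
  if (any(idx < 0L) || any(idx >= n_ch))
    stop("channel_map index out of range: file has ", n_ch, " channel(s)")
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  vox <- array(0, dim = c(n_z, length(idx), ny, nx))
  for (ci in seq_along(idx)) {
    for (zi in seq_len(n_z)) {
      vox[zi, ci, , ] <- pages[[idx[ci] * n_z + zi]]
    }
  }
  multichannel_stack(vox, names(channel_map), pixel_size_um)
}

#' Maximum-intensity projection of a stack
#'
#' Projects each channel along z by taking the per-pixel maximum, the
#' standard reduction applied to confocal z-stacks before 2D analysis.
#'
#' @param stack a [multichannel_stack].
#' @return named list of [planar_image], one per channel.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "multichannel_stack"))
  d <- dim(stack$voxels)
  if (d[1L] < 1L) stop("stack has no z-slices")
  out <- lapply(seq_len(d[2L]), function(ci) {
    planar_image(apply(stack$voxels[, ci, , , drop = FALSE], c(3L, 4L), max),
                 channel_name = stack$channel_names[ci],
                 pixel_size_um = stack$pixel_size_um)
  })
  stats::setNames(out, stack$channel_names)
}

#' Read an edge annotation from JSON
#'
#' The JSON dialect has fields `units` ("px" or "um"), `pixel_size_um`,
#' `invasive_edge` and `nuclear_edge` as arrays of \[x, y\] pairs, and
#' optional `front_region` and `tip`. Pixel-unit coordinates are converted
#' to micrometers using `pixel_size_um`.
#'
#' @param path path to the JSON file.
#' @return an [edge_annotation].
#' @export
read_edge_annotation <- function(path) {
  if (!file.exists(path)) stop("cannot read annotation: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("units", "invasive_edge", "nuclear_edge")) {
    if (is.null(j[[field]])) stop("annotation is missing required field '", field, "'")
  }
  if (!j$units %in% c("px", "um")) stop("units must be 'px' or 'um'")
  scale <- 1
  if (j$units == "px") {
    if (is.null(j$pixel_size_um)) stop("pixel units require pixel_size_um")
    scale <- j$pixel_size_um
  }
  cv <- function(m) if (is.null(m)) NULL else as_points(m) * scale
  edge_annotation(cv(j$invasive_edge), cv(j$nuclear_edge),
                  front_region = cv(j$front_region),
                  tip = if (is.null(j$tip)) NULL else as.numeric(j$tip) * scale)
}

#' Write an edge annotation to JSON
#'
#' @param annotation an [edge_annotation].
#' @param path output path.
#' @param units "um" (default) or "px"; with "px", coordinates are divided
#'   by `pixel_size_um` before writing.
#' @param pixel_size_um pixel size recorded in the file (required for "px").
#' @export
write_edge_annotation <- function(annotation, path, units = "um",
                                  pixel_size_um = NULL) {
  stopifnot(inherits(annotation, "edge_annotation"))
  if (units == "px" && is.null(pixel_size_um))
    stop("pixel units require pixel_size_um")
  scale <- if (units == "px") 1 / pixel_size_um else 1
  cv <- function(m) if (is.null(m)) NULL else unname(as_points(m) * scale)
  obj <- list(units = units,
              pixel_size_um = pixel_size_um,
              invasive_edge = cv(annotation$invasive_edge),
              nuclear_edge = cv(annotation$nuclear_edge),
              front_region = cv(annotation$front_region),
              tip = if (is.null(annotation$tip)) NULL else annotation$tip * scale)
  obj <- obj[!vapply(obj, is.null, logical(1L))]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write planar images as a multi-page float TIFF
#'
#' Sample values are stored normalized to \[0, 1\]; the normalization factor
#' is returned (and recorded in run manifests) so intensities can be
#' restored on load via `intensity_scale`.
#'
#' @param images list of [planar_image] sharing dimensions.
#' @param path output TIFF path.
#' @return invisibly, the intensity scale used.
#' @export
write_stack <- function(images, path) {
  mats <- lapply(images, function(im) im$pixels)
  scale <- max(1e-12, max(vapply(mats, max, numeric(1L))))
  tiff::writeTIFF(lapply(mats, function(m) pmin(pmax(m / scale, 0), 1)),
                  path, bits.per.sample = 32L)
  invisible(scale)
}
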