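# Perimeter intensity profiling relative to the protrusion tip, profile
# aggregation across cells with a t-based confidence band, and the
# Peripheral Distribution Index (PDI) of a single cell.

#' Intensity profile along a front-cytoplasm contour
#'
#' Resamples the contour at fixed arc-length steps and reports, at each
#' sample, the mean image intensity over a disk of radius `band_um`
#' centered on the contour point. Positions are signed arc lengths from the
#' protrusion tip (0 at the tip, sign following the traversal direction of
#' the polyline).
#'
#' @param image a [planar_image] (e.g. a laminin immunostain projection).
#' @param front_contour open polyline (n x 2, um) along the front-cytoplasm
#'   perimeter.
#' @param tip (x, y) point of the protrusion tip; must lie within
#'   `tip_tol_um` of the contour.
#' @param band_um sampling disk radius.
#' @param step_um arc-length resampling step.
#' @param cell_id identifier carried into the profile.
#' @param tip_tol_um maximum allowed tip-to-contour distance.
#' @return a `perimeter_profile`: data.frame with arclength_um, intensity,
#'   cell_id.
#' @export
perimeter_intensity_profile <- function(image, front_contour, tip,
                                        band_um = 1, step_um = 0.5,
                                        cell_id = "cell", tip_tol_um = 1) {
  stopifnot(inherits(image, "planar_image"))
  tip <- as.numeric(tip)
  if (point_polyline_distance(matrix(tip, 1L), front_contour) > tip_tol_um)
    stop("tip is farther than ", tip_tol_um, " um from the contour")
  rs <- resample_polyline(front_contour, step_um)
  # snap the tip to the nearest resampled point
  d2tip <- rowSums(sweep(rs$points, 2L, tip)^2)
  s0 <- rs$arclength[which.min(d2tip)]
  px <- image$pixel_size_um
  pix <- image$pixels
  ny <- nrow(pix); nx <- ncol(pix)
  half <- ceiling(band_um / px) + 1L
  intensity <- vapply(seq_len(nrow(rs$points)), function(i) {
    cx <- rs$points[i, 1L]; cy <- rs$points[i, 2L]
    c0 <- max(1L, floor(cx / px - half)); c1 <- min(nx, ceiling(cx / px + half))
    r0 <- max(1L, floor(cy / px - half)); r1 <- min(ny, ceiling(cy / px + half))
    if (c0 > c1 || r0 > r1) return(NA_real_)
    ccx <- (c0:c1 - 0.5) * px; ccy <- (r0:r1 - 0.5) * px
    inside <- outer((ccy - cy)^2, (ccx - cx)^2, "+") <= band_um^2
    vals <- pix[r0:r1, c0:c1][inside]
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }, numeric(1L))
  out <- data.frame(arclength_um = rs$arclength - s0, intensity = intensity,
                    cell_id = cell_id, stringsAsFactors = FALSE)
  out <- out[is.finite(out$intensity), , drop = FALSE]
  class(out) <- c("perimeter_profile", "data.frame")
  out
}

#' Aggregate perimeter profiles across cells
#'
#' Optionally normalizes each profile by its own mean intensity (removing
#' per-cell exposure differences), interpolates all profiles onto a common
#' signed arc-length grid, and reports the across-cell mean with a t-based
#' 95% confidence band at each grid point. Grid points to which fewer than
#' `min_cells` profiles contribute are truncated.
#'
#' @param profiles list of [perimeter_intensity_profile] outputs.
#' @param normalize divide each profile by its own mean intensity first.
#' @param grid_step_um step of the common grid.
#' @param conf_level confidence level of the band.
#' @param min_cells minimum contributing profiles per retained grid point.
#' @return data.frame with grid_um, mean_intensity, ci_low, ci_high,
#'   n_cells.
#' @export
aggregate_profiles <- function(profiles, normalize = TRUE, grid_step_um = 0.5,
                               conf_level = 0.95, min_cells = 3L) {
  if (length(profiles) < 3L) stop("need at least 3 profiles")
  rngs <- vapply(profiles, function(p) range(p$arclength_um), numeric(2L))
  lo <- min(rngs[1L, ]); hi <- max(rngs[2L, ])
  if (max(rngs[1L, ]) >= min(rngs[2L, ]))
    stop("profiles have non-overlapping arc-length ranges")
  grid <- seq(lo, hi, by = grid_step_um)
  vals <- vapply(profiles, function(p) {
    y <- p$intensity
    if (normalize) y <- y / mean(y)
    stats::approx(p$arclength_um, y, xout = grid, rule = 1L, ties = "ordered")$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(is.finite(vals))
  keep <- n >= min_cells
  if (!any(keep)) stop("no grid point receives ", min_cells, " profiles")
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  se <- s / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = pmax(n - 1L, 1L))
  data.frame(grid_um = grid, mean_intensity = m,
             ci_low = m - tq * se, ci_high = m + tq * se,
             n_cells = n)[keep, , drop = FALSE]
}

#' Peripheral Distribution Index of a single cell
#'
#' Second-moment polarity index of a signal about the nucleus centroid:
#' the intensity-weighted mean squared distance of the signal from the
#' nucleus centroid, divided by the same moment for a hypothetical uniform
#' distribution over the cytoplasm (cell mask minus nucleus mask). A
#' uniformly diffuse signal therefore gives PDI = 1; peripheral enrichment
#' gives PDI > 1, perinuclear concentration PDI < 1.
#'
#' @param signal a [planar_image] (pixel intensities inside the cytoplasm
#'   are the weights), a `spot_set`, or an n x 2 matrix of point
#'   coordinates in micrometers (unit weights).
#' @param cell_mask,nucleus_mask logical matrices; the nucleus must lie
#'   inside the cell.
#' @param pixel_size_um pixel size of the masks (um); taken from `signal`
#'   when it is a [planar_image].
#' @return list with `pdi`, `n_signal_pixels`, `nucleus_centroid_um`.
#' @export
compute_pdi <- function(signal, cell_mask, nucleus_mask, pixel_size_um = NULL) {
  stopifnot(identical(dim(cell_mask), dim(nucleus_mask)))
  if (any(nucleus_mask & !cell_mask)) stop("nucleus_mask must lie inside cell_mask")
  cyto <- cell_mask & !nucleus_mask
  if (!any(cyto)) stop("empty cytoplasm (cell mask minus nucleus mask)")
  if (inherits(signal, "planar_image") && is.null(pixel_size_um))
    pixel_size_um <- signal$pixel_size_um
  if (is.null(pixel_size_um)) stop("pixel_size_um is required")

  if (!any(nucleus_mask)) stop("empty nucleus mask")
  ctr <- colMeans(mask_pixel_centers(nucleus_mask, pixel_size_um))

  cyto_xy <- mask_pixel_centers(cyto, pixel_size_um)
  denom <- mean((cyto_xy[, 1L] - ctr[1L])^2 + (cyto_xy[, 2L] - ctr[2L])^2)

  if (inherits(signal, "planar_image")) {
    stopifnot(identical(dim(signal$pixels), dim(cell_mask)))
    w <- signal$pixels[cyto]
    if (any(w < 0)) stop("negative signal intensities inside the cytoplasm")
    if (sum(w) <= 0) stop("no signal inside the cytoplasm")
    num <- sum(w * ((cyto_xy[, 1L] - ctr[1L])^2 + (cyto_xy[, 2L] - ctr[2L])^2)) / sum(w)
    n_sig <- sum(w > 0)
  } else {
    pts <- if (inherits(signal, "spot_set"))
      as.matrix(signal$spots[, c("x_um", "y_um")]) else as_points(signal)
    if (nrow(pts) == 0L) stop("no signal points supplied")
    num <- mean((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2)
    n_sig <- nrow(pts)
  }
  list(pdi = num / denom, n_signal_pixels = n_sig, nucleus_centroid_um = ctr)
}
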