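# Single-molecule FISH spot detection: single-scale Laplacian-of-Gaussian
# response, robust MAD-based thresholding, greedy non-maximum suppression
# and per-axis quadratic sub-pixel refinement. The response is linear and
# zero-mean under constant offsets, so detection is invariant to intensity
# scaling (with a relative threshold) and to additive offsets.

#' Parameters of the spot detector
#'
#' @param scale_um expected spot radius (the LoG sigma), micrometers.
#' @param threshold_k detection threshold in units of the robust (MAD-based)
#'   standard deviation of the LoG response; ignored if `threshold_abs` is
#'   given.
#' @param threshold_abs absolute response threshold, or NULL.
#' @param min_separation_um minimum center-to-center distance between
#'   reported spots; defaults to twice the scale.
#' @return a `spot_params` list.
#' @export
spot_params <- function(scale_um, threshold_k = 5, threshold_abs = NULL,
                        min_separation_um = 2 * scale_um) {
  stopifnot(scale_um > 0, threshold_k > 0, min_separation_um >= 0)
  structure(list(scale_um = scale_um, threshold_k = threshold_k,
                 threshold_abs = threshold_abs,
                 min_separation_um = min_separation_um),
            class = "spot_params")
}

log_response <- function(pixels, sigma_px) {
  # Gaussian smoothing followed by the discrete 5-point Laplacian, scaled by
  # -sigma^2 (scale normalization); bright blobs of matching scale give
  # positive peaks.
  ks <- 2L * ceiling(3 * sigma_px) + 1L
  g <- EBImage::makeBrush(ks, shape = "gaussian", sigma = sigma_px)
  sm <- EBImage::filter2(pixels, g, boundary = "replicate")
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  -sigma_px^2 * EBImage::filter2(sm, lap, boundary = "replicate")
}

#' Detect smFISH spots in a planar image
#'
#' Local maxima of a single-scale Laplacian-of-Gaussian response above a
#' (robust, background-referenced) threshold, restricted to an optional
#' mask, non-maximum-suppressed, with quadratic sub-pixel localization.
#' Candidate ties are broken by higher response, then by (y, x) order, so
#' detection is deterministic.
#'
#' @param image a [planar_image].
#' @param params a [spot_params].
#' @param mask optional logical matrix restricting detection; an empty mask
#'   yields an empty spot set.
#' @param species label attached to the detected spots.
#' @return a `spot_set`: list with `spots` (data.frame: species, x_um, y_um,
#'   peak_intensity, quality), `source_channel`, `params`.
#' @export
detect_spots <- function(image, params, mask = NULL, species = image$channel_name) {
  stopifnot(inherits(image, "planar_image"), inherits(params, "spot_params"))
  px <- image$pixel_size_um
  sigma_px <- params$scale_um / px
  if (sigma_px < 1) stop("scale_um is below one pixel (", format(params$scale_um),
                         " um at ", format(px), " um/px)")
  pixels <- image$pixels
  ny <- nrow(pixels); nx <- ncol(pixels)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(pixels)))
    if (!any(mask)) return(empty_spot_set(image, params))
  }
  resp <- log_response(pixels, sigma_px)

  bg <- if (is.null(mask)) resp else resp[mask]
  robust_sd <- stats::mad(bg)
  thr <- if (!is.null(params$threshold_abs)) params$threshold_abs
         else params$threshold_k * robust_sd

  # 3x3 local maxima away from the 1-px border
  inner_r <- 2:(ny - 1L); inner_c <- 2:(nx - 1L)
  ctr <- resp[inner_r, inner_c]
  is_max <- ctr >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & (ctr >= resp[inner_r + dr, inner_c + dc])
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty_spot_set(image, params))
  cand_r <- cand[, 1L] + 1L; cand_c <- cand[, 2L] + 1L
  if (!is.null(mask)) {
    keep <- mask[cbind(cand_r, cand_c)]
    cand_r <- cand_r[keep]; cand_c <- cand_c[keep]
  }
  if (length(cand_r) == 0L) return(empty_spot_set(image, params))
  q <- resp[cbind(cand_r, cand_c)]

  # deterministic order: response descending, then (y, x)
  o <- order(-q, cand_r, cand_c)
  cand_r <- cand_r[o]; cand_c <- cand_c[o]; q <- q[o]

  # greedy non-maximum suppression at min_separation
  min_sep_px2 <- (params$min_separation_um / px)^2
  keep <- logical(length(q))
  for (i in seq_along(q)) {
    ok <- TRUE
    if (i > 1L) {
      prev <- which(keep[seq_len(i - 1L)])
      if (length(prev) &&
          any((cand_r[prev] - cand_r[i])^2 + (cand_c[prev] - cand_c[i])^2 < min_sep_px2))
        ok <- FALSE
    }
    keep[i] <- ok
  }
  cand_r <- cand_r[keep]; cand_c <- cand_c[keep]; q <- q[keep]

  # quadratic sub-pixel refinement per axis, offset clamped to half a pixel
  sub <- function(rm, r0, rp) {
    den <- rm - 2 * r0 + rp
    off <- ifelse(abs(den) < .Machine$double.eps, 0, 0.5 * (rm - rp) / den)
    pmin(pmax(off, -0.5), 0.5)
  }
  dr <- sub(resp[cbind(cand_r - 1L, cand_c)], q, resp[cbind(cand_r + 1L, cand_c)])
  dc <- sub(resp[cbind(cand_r, cand_c - 1L)], q, resp[cbind(cand_r, cand_c + 1L)])

  spots <- data.frame(
    species = species,
    x_um = (cand_c - 0.5 + dc) * px,
    y_um = (cand_r - 0.5 + dr) * px,
    peak_intensity = pixels[cbind(cand_r, cand_c)],
    quality = q,
    stringsAsFactors = FALSE)
  structure(list(spots = spots, source_channel = image$channel_name,
                 params = params, robust_sd = robust_sd),
            class = "spot_set")
}

empty_spot_set <- function(image, params) {
  structure(list(spots = data.frame(species = character(0), x_um = numeric(0),
                                    y_um = numeric(0), peak_intensity = numeric(0),
                                    quality = numeric(0)),
                 source_channel = image$channel_name, params = params,
                 robust_sd = NA_real_),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set: %d spots from channel '%s'>\n",
              nrow(x$spots), x$source_channel))
  invisible(x)
}

#' Match detected spots against ground truth
#'
#' Greedy nearest-neighbor one-to-one matching within a radius, then
#' standard precision, recall and F1. With no detections, precision is 1 by
#' convention (no false positives were produced).
#'
#' @param detected a [spot_set] or n x 2 coordinate matrix (um).
#' @param truth m x 2 matrix of true spot centers (um).
#' @param radius_um maximum match distance.
#' @return list with `precision`, `recall`, `f1`, `n_matched`.
#' @export
match_spots <- function(detected, truth, radius_um) {
  stopifnot(radius_um > 0)
  det <- if (inherits(detected, "spot_set"))
    as.matrix(detected$spots[, c("x_um", "y_um")]) else as_points(detected)
  truth <- if (length(truth) == 0L) matrix(numeric(0), 0L, 2L) else as_points(truth)
  nd <- nrow(det); nt <- nrow(truth)
  n_matched <- 0L
  if (nd > 0L && nt > 0L) {
    dx <- outer(det[, 1L], truth[, 1L], "-")
    dy <- outer(det[, 2L], truth[, 2L], "-")
    dist <- sqrt(dx^2 + dy^2)
    pairs <- which(dist <= radius_um, arr.ind = TRUE)
    if (nrow(pairs) > 0L) {
      pairs <- pairs[order(dist[pairs]), , drop = FALSE]
      used_d <- logical(nd); used_t <- logical(nt)
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        if (!used_d[i] && !used_t[j]) {
          used_d[i] <- TRUE; used_t[j] <- TRUE
          n_matched <- n_matched + 1L
        }
      }
    }
  }
  precision <- if (nd == 0L) 1 else n_matched / nd
  recall <- if (nt == 0L) 1 else n_matched / nt
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, n_matched = n_matched)
}
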