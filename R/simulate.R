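# Synthetic-scene generator. Produces leader-cell geometries with
# ground-truth RNA spot placements whose normalized front distance follows a
# chosen Beta law, rendered smFISH-like channels, and branched spheroid
# silhouettes of controllable invasiveness. Every downstream stage of the
# pipeline is testable against these scenes without any raw microscopy data.

#' Configuration of a synthetic leader-cell scene
#'
#' The front cytoplasm is modeled as a tapering protrusion: a straight
#' invasive-edge transect at normalized distance d = 0, a straight
#' nuclear-edge transect at d = 1 a distance `protrusion_length_um` away,
#' with the region widening from 0.6 x `protrusion_width_um` at the tip to
#' the full width at the nuclear end. Behind the nuclear edge sits a round
#' cell body containing a disk nucleus. Spot normalized distances are i.i.d.
#' Beta(alpha, beta) draws per species, mapped onto the protrusion axis,
#' with uniform transverse placement inside the central band spanned by both
#' edge transects (so the recorded true d is exact).
#'
#' @param protrusion_length_um axial length L of the front cytoplasm.
#' @param protrusion_width_um full transverse width at the nuclear end.
#' @param n_spots_per_species named integer vector, spots per RNA species.
#' @param bias named list mapping species to c(alpha, beta) of the Beta law
#'   over normalized distance d (alpha = beta = 1 is uniform; beta > alpha
#'   biases toward the invasive front).
#' @param psf_sigma_um Gaussian PSF sigma of a rendered diffraction-limited
#'   spot.
#' @param background_level additive constant background of rendered images.
#' @param noise_sd standard deviation of additive Gaussian read noise.
#' @param pixel_size_um pixel size of rendered rasters.
#' @param spot_snr peak spot amplitude over `noise_sd`; used to derive the
#'   per-spot integrated amplitude.
#' @param seed integer seed; all randomness in the scene flows from it.
#' @return a validated `scene_config` list.
#' @export
scene_config <- function(protrusion_length_um = 25,
                         protrusion_width_um = 10,
                         n_spots_per_species = c(target = 25, control = 25),
                         bias = list(target = c(2, 6), control = c(1, 1)),
                         psf_sigma_um = 0.15,
                         background_level = 100,
                         noise_sd = 10,
                         pixel_size_um = 0.1,
                         spot_snr = 8,
                         seed = 1L) {
  stopifnot(protrusion_length_um > 0, protrusion_width_um > 0,
            psf_sigma_um > 0, pixel_size_um > 0, noise_sd >= 0, spot_snr > 0)
  if (is.null(names(n_spots_per_species)) || any(n_spots_per_species < 0))
    stop("n_spots_per_species must be a named vector of non-negative counts")
  for (sp in names(n_spots_per_species)) {
    ab <- bias[[sp]]
    if (is.null(ab) || length(ab) != 2L || any(ab <= 0))
      stop("bias for species '", sp, "' must be c(alpha, beta) with both > 0")
  }
  cfg <- list(protrusion_length_um = protrusion_length_um,
              protrusion_width_um = protrusion_width_um,
              n_spots_per_species = n_spots_per_species,
              bias = bias,
              psf_sigma_um = psf_sigma_um,
              background_level = background_level,
              noise_sd = noise_sd,
              pixel_size_um = pixel_size_um,
              spot_snr = spot_snr,
              seed = as.integer(seed))
  # peak value of a unit-integral Gaussian PSF sampled on the pixel grid is
  # px^2 / (2 pi sigma^2); scale so that peak = snr * noise_sd
  cfg$spot_amplitude <- spot_snr * max(noise_sd, 1) *
    2 * pi * psf_sigma_um^2 / pixel_size_um^2
  class(cfg) <- "scene_config"
  cfg
}

# Deterministic scene geometry derived from a config (no randomness).
scene_geometry <- function(config) {
  L <- config$protrusion_length_um
  h1 <- config$protrusion_width_um / 2   # half-width at nuclear end
  h0 <- 0.6 * h1                         # half-width at the tip
  margin <- 2
  x0 <- margin
  rn <- 0.8 * h1                         # nucleus radius
  rb <- rn + 1                           # rear body radius
  body_cx <- x0 + L + rn
  width_um <- x0 + L + rn + rb + margin
  height_um <- 2 * (rb + margin)
  yc <- height_um / 2
  theta <- seq(0, 2 * pi, length.out = 65L)[-65L]
  front_region <- rbind(c(x0, yc - h0), c(x0 + L, yc - h1),
                        c(x0 + L, yc + h1), c(x0, yc + h0))
  list(
    x0 = x0, L = L, h0 = h0, h1 = h1, yc = yc, rn = rn,
    width_um = width_um, height_um = height_um,
    invasive_edge = cbind(x0, yc + seq(-h0, h0, length.out = 5L)),
    nuclear_edge = cbind(x0 + L, yc + seq(-h0, h0, length.out = 5L)),
    front_region = front_region,
    tip = c(x0, yc),
    body = cbind(body_cx + rb * cos(theta), yc + rb * sin(theta)),
    nucleus = cbind(body_cx + rn * cos(theta), yc + rn * sin(theta))
  )
}

# Raster dimensions c(ny, nx) of a scene's rendered channels.
scene_raster_dims <- function(config) {
  g <- scene_geometry(config)
  c(ceiling(g$height_um / config$pixel_size_um),
    ceiling(g$width_um / config$pixel_size_um))
}

#' Generate a synthetic leader-cell scene
#'
#' Draws, for each species, spot normalized distances d from the configured
#' Beta law, places the spots inside the front cytoplasm, and renders one
#' smFISH-like channel per species. Given equal configs (including the
#' seed), two calls return identical scenes.
#'
#' @param config a [scene_config].
#' @param render render the per-species smFISH channels; set FALSE when
#'   only geometry and ground-truth spot placements are needed.
#' @return a `synthetic_scene` list with elements `edge_annotation`
#'   ([edge_annotation] with front region and tip), `cell_mask` and
#'   `nucleus_mask` (logical rasters), `true_spots` (data.frame with
#'   species, x_um, y_um, d_true), `rendered` (named list of
#'   [planar_image], one channel per species; empty if `render = FALSE`),
#'   and `config`.
#' @export
make_leader_scene <- function(config, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(config$seed)
  g <- scene_geometry(config)
  dims <- scene_raster_dims(config)
  px <- config$pixel_size_um

  cell_mask <- rasterize_polygon(g$front_region, dims, px) |
    rasterize_polygon(g$body, dims, px)
  nucleus_mask <- rasterize_polygon(g$nucleus, dims, px)

  in_mask <- function(x, y) {
    r <- ceiling(y / px); c <- ceiling(x / px)
    ok <- r >= 1 & r <= dims[1L] & c >= 1 & c <= dims[2L]
    ok[ok] <- cell_mask[cbind(r[ok], c[ok])]
    ok
  }

  spots <- list()
  for (sp in names(config$n_spots_per_species)) {
    n <- config$n_spots_per_species[[sp]]
    if (n == 0L) next
    ab <- config$bias[[sp]]
    xs <- ys <- ds <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        d <- stats::rbeta(1L, ab[1L], ab[2L])
        x <- g$x0 + d * g$L
        # transverse band spanned by both straight edge transects, so the
        # perpendicular foot onto either polyline exists and d is exact
        y <- g$yc + stats::runif(1L, -0.9 * g$h0, 0.9 * g$h0)
        if (in_mask(x, y)) {
          xs[i] <- x; ys[i] <- y; ds[i] <- d
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place a spot inside the mask after 100 ",
                        "attempts: degenerate geometry")
    }
    spots[[sp]] <- data.frame(species = sp, x_um = xs, y_um = ys, d_true = ds,
                              stringsAsFactors = FALSE)
  }
  true_spots <- do.call(rbind, c(spots, list(make.row.names = FALSE)))

  rendered <- list()
  if (render) {
    rendered <- lapply(names(config$n_spots_per_species), function(sp) {
      pts <- true_spots[true_spots$species == sp, c("x_um", "y_um"), drop = FALSE]
      render_spots(as.matrix(pts), config, dims = dims, channel_name = sp)
    })
    names(rendered) <- names(config$n_spots_per_species)
  }

  ann <- edge_annotation(g$invasive_edge, g$nuclear_edge,
                         front_region = g$front_region, tip = g$tip)
  structure(list(edge_annotation = ann, cell_mask = cell_mask,
                 nucleus_mask = nucleus_mask, true_spots = true_spots,
                 rendered = rendered, geometry = g, config = config),
            class = "synthetic_scene")
}

#' Render diffraction-limited spots into an image
#'
#' Each spot contributes an isotropic Gaussian of scale `psf_sigma_um` with
#' unit integrated intensity times the per-spot amplitude, on top of a
#' constant background plus additive Gaussian read noise.
#'
#' @param spots n x 2 matrix of spot centers (x, y) in micrometers.
#' @param config a [scene_config] providing PSF, background, noise,
#'   amplitude, and pixel size.
#' @param dims raster dimensions c(ny, nx); defaults to the scene raster.
#' @param amplitudes per-spot integrated amplitudes (recycled).
#' @param channel_name channel label of the output.
#' @param seed optional seed for the noise draw; by default the current RNG
#'   stream is used (so [make_leader_scene] stays single-seeded).
#' @return a [planar_image].
#' @export
render_spots <- function(spots, config, dims = scene_raster_dims(config),
                         amplitudes = config$spot_amplitude,
                         channel_name = "spots", seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(seed)) set.seed(seed)
  px <- config$pixel_size_um
  sigma <- config$psf_sigma_um
  ny <- dims[1L]; nx <- dims[2L]
  img <- matrix(0, ny, nx)
  spots <- if (length(spots) == 0L) matrix(numeric(0), 0L, 2L) else as_points(spots)
  if (nrow(spots) > 0L) {
    amplitudes <- rep_len(amplitudes, nrow(spots))
    if (any(spots[, 1L] < 0 | spots[, 1L] > nx * px |
            spots[, 2L] < 0 | spots[, 2L] > ny * px))
      stop("spot outside image bounds")
    half <- ceiling(5 * sigma / px)
    for (i in seq_len(nrow(spots))) {
      cx <- spots[i, 1L] / px + 0.5  # center in pixel-index units
      cy <- spots[i, 2L] / px + 0.5
      c0 <- max(1L, floor(cx) - half); c1 <- min(nx, floor(cx) + half)
      r0 <- max(1L, floor(cy) - half); r1 <- min(ny, floor(cy) + half)
      gx <- exp(-((c0:c1) - cx)^2 * px^2 / (2 * sigma^2))
      gy <- exp(-((r0:r1) - cy)^2 * px^2 / (2 * sigma^2))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
        amplitudes[i] * px^2 / (2 * pi * sigma^2) * outer(gy, gx)
    }
  }
  img <- img + config$background_level
  if (config$noise_sd > 0)
    img <- img + matrix(stats::rnorm(ny * nx, 0, config$noise_sd), ny, nx)
  planar_image(img, channel_name = channel_name, pixel_size_um = px)
}

#' Generate a branched spheroid silhouette
#'
#' Builds a simple polygon consisting of a disk body (regular 256-gon) with
#' `n_branches` radial strands of constant width at seeded angles, emulating
#' a calcein-stained invasive spheroid: more strands mean higher shape
#' complexity at nearly constant area. The exact polygon perimeter and area
#' are recorded as ground truth alongside the rasterized mask.
#'
#' @param n_branches number of radial strands (0 gives the plain disk).
#' @param branch_length_um radial strand length beyond the body.
#' @param branch_width_um strand width; must be smaller than the body
#'   radius.
#' @param body_radius_um body disk radius.
#' @param seed integer seed for the strand angles.
#' @param pixel_size_um raster pixel size.
#' @return list with `polygon` (n x 2, um), `perimeter_um`, `area_um2`,
#'   `complexity` (exact polygon values), `mask` (logical raster) and
#'   `pixel_size_um`.
#' @export
make_spheroid_silhouette <- function(n_branches, branch_length_um = 40,
                                     branch_width_um = 8, body_radius_um = 40,
                                     seed = 1L, pixel_size_um = 1) {
  stopifnot(n_branches >= 0, branch_width_um > 0, body_radius_um > 0,
            branch_length_um >= 0)
  if (branch_width_um >= body_radius_um)
    stop("branch_width_um must be smaller than body_radius_um")
  set.seed(as.integer(seed))
  R <- body_radius_um
  phi <- asin((branch_width_um / 2) / R)  # angular half-width of a strand root

  angles <- numeric(0)
  if (n_branches > 0L) {
    for (try in seq_len(10L)) {
      angles <- sort(stats::runif(n_branches, 0, 2 * pi))
      gaps <- diff(c(angles, angles[1L] + 2 * pi))
      if (all(gaps > 2 * phi + 0.05) || n_branches == 1L) break
      if (try == 10L) {
        # merge overlapping strand roots into single strands
        keep <- c(TRUE, gaps[-length(gaps)] > 2 * phi + 0.05)
        angles <- angles[keep]
      }
    }
  }

  # outline traversed counterclockwise: body arcs interleaved with strands
  arc <- function(a0, a1, n = max(2L, ceiling((a1 - a0) / (2 * pi) * 256L))) {
    t <- seq(a0, a1, length.out = n)
    cbind(R * cos(t), R * sin(t))
  }
  if (length(angles) == 0L) {
    poly <- arc(0, 2 * pi, 257L)[-257L, ]
  } else {
    pieces <- list()
    for (k in seq_along(angles)) {
      th <- angles[k]
      u <- c(cos(th), sin(th))
      p1 <- R * c(cos(th - phi), sin(th - phi))
      p4 <- R * c(cos(th + phi), sin(th + phi))
      strand <- rbind(p1, p1 + branch_length_um * u,
                      p4 + branch_length_um * u, p4)
      a_next <- if (k < length(angles)) angles[k + 1L] - phi else angles[1L] - phi + 2 * pi
      pieces[[length(pieces) + 1L]] <- strand
      pieces[[length(pieces) + 1L]] <- arc(th + phi, a_next)
    }
    poly <- do.call(rbind, pieces)
    poly <- poly[!duplicated(round(poly, 9L)), , drop = FALSE]
  }
  if (polyline_self_intersects(rbind(poly, poly[1L, ])))
    stop("silhouette polygon is non-simple; retry with another seed")

  extent <- R + branch_length_um + 2
  poly <- sweep(poly, 2L, c(extent, extent), "+")  # shift into the raster frame
  per <- polygon_perimeter(poly)
  area <- abs(polygon_area(poly))
  n_px <- ceiling(2 * extent / pixel_size_um)
  mask <- rasterize_polygon(poly, c(n_px, n_px), pixel_size_um)
  list(polygon = poly, perimeter_um = per, area_um2 = area,
       complexity = complexity(per, area), mask = mask,
       pixel_size_um = pixel_size_um)
}
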