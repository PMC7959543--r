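# Shared in-code fixtures for the test suite.

# Two straight parallel edges `gap_um` apart: invasive at x = 0, nuclear at
# x = gap_um, both spanning y in [0, span_um].
parallel_edges <- function(gap_um = 10, span_um = 20) {
  edge_annotation(
    invasive_edge = cbind(0, seq(0, span_um, length.out = 5L)),
    nuclear_edge = cbind(gap_um, seq(0, span_um, length.out = 5L)))
}

# A small, quick-to-render scene configuration used across tests.
small_scene_config <- function(seed = 1L, ...) {
  scene_config(protrusion_length_um = 15, protrusion_width_um = 8,
               n_spots_per_species = c(target = 25, control = 25),
               seed = seed, ...)
}

# Independent brute-force nearest distance from one point to a polyline by
# dense sampling of each segment (oracle for the projection formula).
dense_polyline_distance <- function(point, polyline, n_per_segment = 1e4L) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1L)) {
    t <- seq(0, 1, length.out = n_per_segment)
    sx <- polyline[i, 1L] + t * (polyline[i + 1L, 1L] - polyline[i, 1L])
    sy <- polyline[i, 2L] + t * (polyline[i + 1L, 2L] - polyline[i, 2L])
    best <- min(best, min(sqrt((sx - point[1L])^2 + (sy - point[2L])^2)))
  }
  best
}

# Independent shoelace area + segment-sum perimeter (oracle for the
# polygon measurements recorded by the silhouette generator).
shoelace_oracle <- function(poly) {
  n <- nrow(poly)
  if (!all(poly[1L, ] == poly[n, ])) {
    poly <- rbind(poly, poly[1L, ])
    n <- n + 1L
  }
  a <- 0; p <- 0
  for (i in seq_len(n - 1L)) {
    a <- a + poly[i, 1L] * poly[i + 1L, 2L] - poly[i + 1L, 1L] * poly[i, 2L]
    p <- p + sqrt(sum((poly[i + 1L, ] - poly[i, ])^2))
  }
  list(area = as.numeric(abs(a) / 2), perimeter = as.numeric(p))
}

# Exact two-sided signed-rank p-value by enumerating every sign assignment
# (oracle for the paired test on small samples without ties).
enumerate_signed_rank <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_two <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  list(statistic = v_obs, p_value = p_two)
}

# A straight horizontal contour through a synthetic image makes profile
# positions easy to reason about: arc length equals x displacement.
straight_contour_fixture <- function(nx = 200, ny = 60, px = 0.5) {
  contour <- cbind(seq(5, nx * px - 5, by = 2), ny * px / 2)
  tip <- contour[nrow(contour) %/% 2, ]
  list(contour = contour, tip = tip, px = px, nx = nx, ny = ny)
}

# Elliptical cell with an offset disk nucleus, as a realistic single-cell
# geometry for the distribution index.
pdi_fixture <- function(px = 0.25) {
  nx <- 240; ny <- 160
  xc <- outer(rep(1, ny), (seq_len(nx) - 0.5) * px)
  yc <- outer((seq_len(ny) - 0.5) * px, rep(1, nx))
  cell <- ((xc - 30) / 25)^2 + ((yc - 20) / 15)^2 <= 1
  nuc <- ((xc - 26) / 6)^2 + ((yc - 20) / 5)^2 <= 1
  list(cell = cell, nuc = nuc, px = px, xc = xc, yc = yc)
}

# Run a full scene through detection -> distances -> per-cell summary for
# one species; returns the per-cell mean normalized distance.
recover_mean_d <- function(scene, species) {
  cfg <- scene$config
  det <- detect_spots(scene$rendered[[species]],
                      spot_params(scale_um = cfg$psf_sigma_um),
                      mask = scene$cell_mask)
  rec <- spot_edge_distances(det, scene$edge_annotation)
  mean(rec$d)
}
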