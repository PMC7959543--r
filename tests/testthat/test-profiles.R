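test_that("uniform images give constant profiles; a tip bump peaks at arc length 0", {
  fx <- straight_contour_fixture()
  flat <- planar_image(matrix(3.5, fx$ny, fx$nx), "ecm", fx$px)
  prof <- perimeter_intensity_profile(flat, fx$contour, fx$tip)
  expect_true(all(abs(prof$intensity - 3.5) < 1e-9))
  expect_true(all(diff(prof$arclength_um) > 0))
  expect_lte(min(abs(prof$arclength_um)), 0.25)  # 0 lies on the grid

  # Gaussian intensity bump centered on the tip: maximum at arc length 0
  xc <- outer(rep(1, fx$ny), (seq_len(fx$nx) - 0.5) * fx$px)
  yc <- outer((seq_len(fx$ny) - 0.5) * fx$px, rep(1, fx$nx))
  bump <- planar_image(10 * exp(-((xc - fx$tip[1])^2 + (yc - fx$tip[2])^2) / (2 * 9)),
                       "ecm", fx$px)
  prof_b <- perimeter_intensity_profile(bump, fx$contour, fx$tip)
  expect_lt(abs(prof_b$arclength_um[which.max(prof_b$intensity)]), 0.75)

  # reversing the traversal direction mirrors the profile about 0
  prof_r <- perimeter_intensity_profile(bump, fx$contour[nrow(fx$contour):1, ],
                                        fx$tip)
  expect_equal(prof_r$intensity, rev(prof_b$intensity), tolerance = 1e-9)
  expect_equal(prof_r$arclength_um, rev(-prof_b$arclength_um), tolerance = 1e-9)

  expect_error(perimeter_intensity_profile(flat, fx$contour, fx$tip + c(0, 5)),
               "farther than")
})

test_that("aggregation averages, truncates sparse grid ends, and honors normalization", {
  fx <- straight_contour_fixture()
  flat <- planar_image(matrix(2, fx$ny, fx$nx), "ecm", fx$px)
  base <- perimeter_intensity_profile(flat, fx$contour, fx$tip)
  profiles <- lapply(1:5, function(i) transform(base, cell_id = paste0("c", i)))

  agg <- aggregate_profiles(profiles, normalize = FALSE)
  expect_true(all(abs(agg$mean_intensity - 2) < 1e-9))
  expect_true(all(agg$ci_high - agg$ci_low < 1e-9))  # identical profiles
  expect_true(all(agg$n_cells >= 3))

  # per-cell exposure differences vanish under normalization
  scaled <- profiles
  scaled[[2]]$intensity <- scaled[[2]]$intensity * 13
  agg_n <- aggregate_profiles(scaled, normalize = TRUE)
  expect_true(all(abs(agg_n$mean_intensity - 1) < 1e-9))

  # non-overlapping ranges are an error
  shifted <- transform(base, arclength_um = arclength_um + 1e4)
  expect_error(aggregate_profiles(c(profiles[1:2], list(shifted))),
               "non-overlapping")
})

test_that("the t-based band covers a flat truth at >= 93% of grid points", {
  fx <- straight_contour_fixture(nx = 120)
  flat <- planar_image(matrix(1, fx$ny, fx$nx), "ecm", fx$px)
  base <- perimeter_intensity_profile(flat, fx$contour, fx$tip)
  coverage <- vapply(1:100, function(rep) {
    set.seed(300 + rep)
    profiles <- lapply(1:50, function(i) {
      p <- base
      p$intensity <- p$intensity + rnorm(nrow(p), 0, 0.3)
      p$cell_id <- paste0("c", i)
      p
    })
    agg <- aggregate_profiles(profiles, normalize = FALSE)
    mean(agg$ci_low <= 1 & 1 <= agg$ci_high)
  }, numeric(1))
  expect_gte(mean(coverage), 0.93)
})

test_that("a tip-peaked profile family aggregates to a tip maximum", {
  fx <- straight_contour_fixture()
  xc <- outer(rep(1, fx$ny), (seq_len(fx$nx) - 0.5) * fx$px)
  yc <- outer((seq_len(fx$ny) - 0.5) * fx$px, rep(1, fx$nx))
  profiles <- lapply(1:12, function(i) {
    set.seed(400 + i)
    img <- planar_image(1 + 4 * exp(-((xc - fx$tip[1])^2 + (yc - fx$tip[2])^2) / (2 * 16)) +
                          matrix(rnorm(fx$ny * fx$nx, 0, 0.1), fx$ny), "ecm", fx$px)
    p <- perimeter_intensity_profile(img, fx$contour, fx$tip)
    p$cell_id <- paste0("c", i)
    p
  })
  agg <- aggregate_profiles(profiles, normalize = TRUE)
  expect_lt(abs(agg$grid_um[which.max(agg$mean_intensity)]), 1)
  far <- abs(agg$grid_um) > 10
  expect_lt(mean(agg$mean_intensity[far]),
            agg$mean_intensity[which.min(abs(agg$grid_um))])
})

test_that("PDI is 1 for uniform signal, < 1 perinuclear, > 1 peripheral", {
  fx <- pdi_fixture()
  # analytic uniform weights over the cytoplasm: PDI = 1 by construction
  uni <- planar_image(fx$cell * 1.0, "rna", fx$px)
  expect_equal(compute_pdi(uni, fx$cell, fx$nuc)$pdi, 1, tolerance = 1e-6)

  # all signal adjacent to the nucleus centroid: below 1 (moment ordering)
  ctr <- compute_pdi(uni, fx$cell, fx$nuc)$nucleus_centroid_um
  near <- ((fx$xc - ctr[1])^2 + (fx$yc - ctr[2])^2 <= 8^2) & fx$cell & !fx$nuc
  peri_near <- compute_pdi(planar_image(near * 1.0, "rna", fx$px), fx$cell, fx$nuc)
  expect_lt(peri_near$pdi, 1)

  # signal on the boundary ring: above 1, and matches a discrete moment oracle
  ring <- fx$cell & !(((fx$xc - 30) / 23)^2 + ((fx$yc - 20) / 13)^2 <= 1)
  res_ring <- compute_pdi(planar_image(ring * 2.5, "rna", fx$px), fx$cell, fx$nuc)
  expect_gt(res_ring$pdi, 1)
  cyto_xy <- frontfish:::mask_pixel_centers(fx$cell & !fx$nuc, fx$px)
  ring_xy <- frontfish:::mask_pixel_centers(ring, fx$px)
  oracle <- mean(colSums((t(ring_xy) - ctr)^2)) /
    mean(colSums((t(cyto_xy) - ctr)^2))
  expect_equal(res_ring$pdi, oracle, tolerance = 1e-12)

  expect_error(compute_pdi(uni, fx$nuc, fx$cell), "inside")
  expect_error(compute_pdi(uni, fx$nuc, fx$nuc), "cytoplasm")
})

test_that("PDI is invariant to intensity scale and rigid motion, and grows radially", {
  fx <- pdi_fixture()
  sig <- planar_image(fx$cell * runif(length(fx$cell)), "rna", fx$px)
  base <- compute_pdi(sig, fx$cell, fx$nuc)$pdi
  scaled <- planar_image(sig$pixels * 40, "rna", fx$px)
  expect_equal(compute_pdi(scaled, fx$cell, fx$nuc)$pdi, base, tolerance = 1e-12)

  # translate the whole geometry by whole pixels
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  moved <- compute_pdi(planar_image(shift(sig$pixels, 7, 11), "rna", fx$px),
                       shift(fx$cell, 7, 11) > 0, shift(fx$nuc, 7, 11) > 0)
  expect_equal(moved$pdi, base, tolerance = 1e-9)

  # moving a fixed mass outward along rays strictly increases PDI
  ctr <- compute_pdi(sig, fx$cell, fx$nuc)$nucleus_centroid_um
  r2 <- (fx$xc - ctr[1])^2 + (fx$yc - ctr[2])^2
  radii <- c(8, 10, 12, 14)
  pdis <- vapply(radii, function(r) {
    annulus <- fx$cell & !fx$nuc & r2 >= (r - 1)^2 & r2 <= (r + 1)^2
    compute_pdi(planar_image(annulus * 1.0, "rna", fx$px), fx$cell, fx$nuc)$pdi
  }, numeric(1))
  expect_true(all(diff(pdis) > 0))
})
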