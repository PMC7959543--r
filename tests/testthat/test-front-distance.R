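test_that("boundary spots and midline spots get the anchor distances 0, 1, 0.5", {
  edges <- parallel_edges(gap_um = 10)
  spots <- data.frame(species = "t",
                      x_um = c(0, 10, 5), y_um = c(5, 10, 7.5))
  rec <- spot_edge_distances(spots, edges)
  expect_identical(rec$d, c(0, 1, 0.5))
  expect_equal(rec$L_um, rec$Id_um + rec$Nd_um)
  expect_true(all(rec$d >= 0 & rec$d <= 1))
})

test_that("point-to-polyline distances match a dense-sampling brute force", {
  set.seed(77)
  for (rep in 1:25) {
    poly <- cbind(cumsum(runif(5, 0.5, 3)), runif(5, 0, 10))
    pt <- c(runif(1, 0, 12), runif(1, 0, 10))
    fast <- point_polyline_distance(matrix(pt, 1), poly)
    # redraw points that sit closer than the sampling resolution allows
    while (fast < 0.25) {
      pt <- c(runif(1, 0, 12), runif(1, 0, 10))
      fast <- point_polyline_distance(matrix(pt, 1), poly)
    }
    expect_equal(fast, dense_polyline_distance(pt, poly), tolerance = 1e-6)
  }
})

test_that("short protrusion records are dropped with a warning", {
  edges <- edge_annotation(cbind(c(0, 0), c(0, 1)), cbind(c(0.01, 0.01), c(0, 1)))
  spots <- data.frame(species = "t", x_um = c(0.005, 0.005), y_um = c(0.5, 0.9))
  expect_warning(rec <- spot_edge_distances(spots, edges), "dropped")
  expect_identical(nrow(rec), 0L)
})

test_that("cell summaries average per-spot normalized distances by species", {
  edges <- parallel_edges(10)
  spots <- data.frame(species = c("t", "t", "c"),
                      x_um = c(0, 10, 3), y_um = c(5, 5, 5))
  rec <- spot_edge_distances(spots, edges)
  sm <- summarize_cell(rec, "cell1")
  expect_equal(sm$mean_d[sm$species == "t"], 0.5)  # d = {0, 1}
  expect_equal(sm$mean_d[sm$species == "c"], 0.3)  # single record identity
  expect_identical(sm$n_spots[sm$species == "t"], 2L)
  expect_warning(summarize_cell(rec, "cell1", species = c("t", "absent")),
                 "excluded")

  # alternative reading: average raw distances, then normalize once
  alt <- summarize_cell(rec, "cell1", normalization = "average_then_normalize")
  t_rec <- rec[rec$species == "t", ]
  expect_equal(alt$mean_d[alt$species == "t"],
               mean(t_rec$Id_um) / (mean(t_rec$Id_um) + mean(t_rec$Nd_um)))
})

test_that("per-cell means of many Beta(1,3) draws concentrate at 1/4", {
  cfg <- scene_config(n_spots_per_species = c(t = 1e4),
                      bias = list(t = c(1, 3)), seed = 31L)
  sc <- make_leader_scene(cfg, render = FALSE)
  rec <- spot_edge_distances(
    data.frame(species = "t", x_um = sc$true_spots$x_um, y_um = sc$true_spots$y_um),
    sc$edge_annotation)
  expect_equal(mean(rec$d), 0.25, tolerance = 0.02 / 0.25)
})

test_that("boundary-reflected density integrates to one and tracks the sample", {
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

  # uniform fine grid of means: density close to flat on the interior
  s_unif <- data.frame(mean_d = seq(0.005, 0.995, by = 0.005))
  d_unif <- density_of_means(s_unif)
  expect_equal(trapz(d_unif$support, d_unif$density), 1, tolerance = 1e-6)
  interior <- d_unif$support >= 0.1 & d_unif$support <= 0.9
  expect_true(all(abs(d_unif$density[interior] - 1) < 0.1))

  # front-biased means put the mode near the invasive edge
  set.seed(8)
  s_front <- data.frame(mean_d = rbeta(60, 1.2, 10))
  d_front <- density_of_means(s_front)
  expect_equal(trapz(d_front$support, d_front$density), 1, tolerance = 1e-6)
  expect_lte(d_front$support[which.max(d_front$density)], 0.15)

  # degenerate identical means fall back to a narrow kernel, still normalized
  expect_warning(d_deg <- density_of_means(data.frame(mean_d = rep(0.4, 5))),
                 "degenerate")
  expect_equal(trapz(d_deg$support, d_deg$density), 1, tolerance = 1e-6)
  expect_error(density_of_means(data.frame(mean_d = c(0.1, 0.2))), "at least 3")
})

test_that("paired signed-rank test matches an exhaustive sign-assignment oracle", {
  target <- data.frame(cell_id = 1:8,
                       mean_d = c(0.21, 0.35, 0.17, 0.44, 0.29, 0.38, 0.12, 0.55))
  control <- data.frame(cell_id = 1:8,
                        mean_d = c(0.44, 0.31, 0.42, 0.58, 0.21, 0.60, 0.33, 0.49))
  res <- paired_shift_test(target, control)
  oracle <- enumerate_signed_rank(target$mean_d - control$mean_d)
  expect_equal(res$statistic, oracle$statistic)
  expect_equal(res$p_value, oracle$p_value)
  expect_equal(res$median_paired_difference,
               median(target$mean_d - control$mean_d))

  # identical samples: all differences zero, p = 1 by convention
  expect_warning(null_res <- paired_shift_test(target, target), "zero")
  expect_equal(null_res$p_value, 1)

  # strict pairing by cell id
  expect_error(paired_shift_test(target, data.frame(cell_id = 3:10,
                                                    mean_d = control$mean_d)),
               "unmatched")
  expect_error(paired_shift_test(target[1:4, ], control[1:4, ]), "at least 6")
})

test_that("a true target-vs-control separation is detected in nearly all replicates", {
  # per-cell means: target Beta(2,6) vs control Beta(4,4), 40 cells
  rejected <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    target <- data.frame(cell_id = 1:40, mean_d = rbeta(40, 2, 6))
    control <- data.frame(cell_id = 1:40, mean_d = rbeta(40, 4, 4))
    paired_shift_test(target, control)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("group comparisons flag real shifts and stay silent on identical groups", {
  # identical groups through the rank path: mid-ranked ties, adjusted p = 1
  same <- list(ref = c(0.3, 0.3, 0.3, 0.3), a = c(0.3, 0.3, 0.3, 0.3))
  res_same <- compare_groups(same, method = "kruskal_dunn", reference = "ref")
  expect_equal(res_same$p_adjusted, 1)

  # 0.3 vs 0.5 with sd 0.1, n = 30: both procedures reject nearly always
  for (m in c("anova_dunnett", "kruskal_dunn")) {
    hits <- vapply(1:60, function(s) {
      set.seed(2000 + s)
      g <- list(ref = rnorm(30, 0.3, 0.1), shifted = rnorm(30, 0.5, 0.1))
      compare_groups(g, method = m, reference = "ref")$p_adjusted < 0.01
    }, logical(1))
    expect_gte(mean(hits), 0.95)
  }

  expect_error(compare_groups(list(a = 1:3), method = "anova_dunnett"),
               "at least 2 conditions")
  expect_error(compare_groups(list(a = 1:5, b = 2), method = "anova_dunnett",
                              reference = "a"),
               "fewer than 2")
  expect_error(compare_groups(list(a = 1:5, b = 1:5), reference = "zz"),
               "not present")
})

test_that("distances are scale invariant and antisymmetric under edge swap", {
  set.seed(55)
  edges <- parallel_edges(10)
  spots <- data.frame(species = "t", x_um = runif(30, 0, 10),
                      y_um = runif(30, 2, 18))
  rec <- spot_edge_distances(spots, edges)

  # multiplying all coordinates by c > 0 leaves every d unchanged
  c_ <- 3.7
  edges_c <- edge_annotation(edges$invasive_edge * c_, edges$nuclear_edge * c_)
  rec_c <- spot_edge_distances(transform(spots, x_um = x_um * c_, y_um = y_um * c_),
                               edges_c)
  expect_equal(rec_c$d, rec$d, tolerance = 1e-12)

  # swapping the two edges maps d to 1 - d
  swapped <- edge_annotation(edges$nuclear_edge, edges$invasive_edge)
  rec_s <- spot_edge_distances(spots, swapped)
  expect_equal(rec_s$d, 1 - rec$d, tolerance = 1e-12)
})
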