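test_that("pairwise correlations match the Pearson definition", {
  set.seed(1)
  series <- matrix(rnorm(5 * 10), 5, 10)
  series[2, ] <- -series[1, ]
  b <- tiny_bold(series, nx = 5)
  cs <- pairwise_correlations(b)
  expect_equal(diag(cs$full), rep(1, 5))
  expect_equal(cs$full[1, 2], -1)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    x <- series[i, ]; y <- series[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cs$full[i, j], r, tolerance = 1e-12)
  }
})

test_that("constant voxels are flagged and zeroed, and sampled pairs match the full form", {
  set.seed(2)
  series <- matrix(rnorm(6 * 12), 6, 12)
  series[3, ] <- 4 # constant voxel
  b <- tiny_bold(series, nx = 6)
  cs <- pairwise_correlations(b)
  expect_true(cs$constant[3])
  expect_true(all(cs$full[3, -3] == 0))

  pairs <- rbind(c(1L, 2L), c(3L, 5L), c(4L, 6L))
  sub <- pairwise_correlations(b, pairs = pairs)
  expect_equal(sub$sampled$r[1], cs$full[1, 2], tolerance = 1e-12)
  expect_equal(sub$sampled$r[2], 0)
  expect_equal(sub$sampled$r[3], cs$full[4, 6], tolerance = 1e-12)
  expect_error(pairwise_correlations(b, pairs = rbind(c(1L, 9L))), "out of mask")
})

test_that("edge sampling is exhaustive, deterministic, and duplicate-free", {
  all3 <- sample_edges(3, 3, seed = 1)
  expect_equal(nrow(all3), 3)
  expect_setequal(paste(all3[, 1], all3[, 2]), c("1 2", "1 3", "2 3"))

  expect_identical(sample_edges(100, 500, seed = 9), sample_edges(100, 500, seed = 9))

  big <- sample_edges(100, 1000, seed = 3)
  expect_true(all(big[, 1] < big[, 2]))
  expect_equal(anyDuplicated(paste(big[, 1], big[, 2])), 0L)
  expect_true(all(big >= 1 & big <= 100))
  expect_error(sample_edges(3, 4, seed = 1), "cannot sample")
})

test_that("graph thresholding is strict and respects the mode", {
  xyz <- cbind(c(-10, 10, 10), 0, 0)
  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 0.71
  cc[1, 3] <- cc[3, 1] <- -0.9
  cs <- correlation_structure(cc, xyz_vox = xyz / 10, xyz_mm = xyz)
  g_raw <- build_graph(cs, 0.7, "raw")
  expect_equal(g_raw$edges, matrix(c(1L, 2L), 1))
  g_abs <- build_graph(cs, 0.7, "absolute")
  expect_equal(nrow(g_abs$edges), 2)
  # strictness: r exactly at the threshold is excluded
  cc2 <- diag(2); cc2[1, 2] <- cc2[2, 1] <- 0.7
  cs2 <- correlation_structure(cc2, xyz_vox = cbind(1:2, 0, 0))
  expect_equal(nrow(build_graph(cs2, 0.7)$edges), 0)
  expect_error(build_graph(cs, 1.2), "threshold")

  # exhaustive scan on a random structure
  set.seed(5)
  A <- matrix(runif(100, -1, 1), 10)
  A <- (A + t(A)) / 2; diag(A) <- 1
  cs3 <- correlation_structure(A, xyz_vox = cbind(1:10, 0, 0))
  g <- build_graph(cs3, 0.7, "raw")
  want <- which(A > 0.7 & upper.tri(A), arr.ind = TRUE)
  expect_equal(nrow(g$edges), nrow(want))
})

test_that("degree maps follow the distance and hemisphere rules", {
  empty <- functional_graph(matrix(integer(0), 0, 2), n = 3,
                            xyz_vox = cbind(1:3, 0, 0))
  dm <- degree_maps(empty)
  expect_equal(dm$degree_full$values, rep(0, 3))
  expect_equal(dm$degree_long$values, rep(0, 3))
  expect_equal(dm$degree_interhemi$values, rep(0, 3))

  # chain of 3 adjacent voxels: all distances below 5 voxels
  chain <- functional_graph(rbind(c(1L, 2L), c(2L, 3L)), n = 3,
                            xyz_vox = cbind(1:3, 1, 1),
                            xyz_mm = cbind(c(10, 20, 30), 0, 0))
  dmc <- degree_maps(chain)
  expect_equal(dmc$degree_full$values, c(1, 2, 1))
  expect_equal(dmc$degree_long$values, c(0, 0, 0))
  expect_equal(dmc$degree_interhemi$values, c(0, 0, 0))

  # one edge across the midline
  cross <- functional_graph(rbind(c(1L, 2L)), n = 2,
                            xyz_vox = cbind(c(1, 3), 0, 0),
                            xyz_mm = cbind(c(-10, 10), 0, 0))
  expect_equal(degree_maps(cross)$degree_interhemi$values, c(1, 1))

  # midline voxels never count as inter-hemispheric
  mid <- functional_graph(rbind(c(1L, 2L)), n = 2,
                          xyz_vox = cbind(c(1, 3), 0, 0),
                          xyz_mm = cbind(c(0, 10), 0, 0))
  expect_equal(degree_maps(mid)$degree_interhemi$values, c(0, 0))

  # long-distance rule: exactly 5 voxels apart counts
  far <- functional_graph(rbind(c(1L, 2L)), n = 2,
                          xyz_vox = cbind(c(0, 5), 0, 0),
                          xyz_mm = cbind(c(0, 50), 0, 0))
  expect_equal(degree_maps(far)$degree_long$values, c(1, 1))
})

test_that("strength maps sum correlations with the stated variants and ordering", {
  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 0.5
  cc[1, 3] <- cc[3, 1] <- -0.3
  cs <- correlation_structure(cc, xyz_vox = cbind(1:3, 0, 0))
  sm <- strength_maps(cs)
  expect_equal(sm$strength$values[1], 0.2)
  expect_equal(sm$strength_abs$values[1], 0.8)
  expect_equal(sm$strength_pos$values[1], 0.5)

  set.seed(8)
  A <- matrix(runif(64, -1, 1), 8); A <- (A + t(A)) / 2; diag(A) <- 1
  smr <- strength_maps(correlation_structure(A, cbind(1:8, 0, 0)))
  expect_true(all(smr$strength$values <= smr$strength_pos$values + 1e-12))
  expect_true(all(smr$strength_pos$values <= smr$strength_abs$values + 1e-12))
})

test_that("clustering and local efficiency match brute-force oracles", {
  tri <- functional_graph(rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L)), n = 3,
                          xyz_vox = cbind(1:3, 0, 0))
  expect_equal(clustering_map(tri)$values, rep(1, 3))
  path <- functional_graph(rbind(c(1L, 2L), c(2L, 3L)), n = 3,
                           xyz_vox = cbind(1:3, 0, 0))
  expect_equal(clustering_map(path)$values, rep(0, 3))

  k4 <- t(combn(4L, 2L))
  g4 <- functional_graph(k4, n = 4, xyz_vox = cbind(1:4, 0, 0))
  expect_equal(local_efficiency_map(g4)$values, rep(1, 4))
  star <- functional_graph(rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)), n = 4,
                           xyz_vox = cbind(1:4, 0, 0))
  expect_equal(local_efficiency_map(star)$values[1], 0)

  for (seed in 1:10) {
    g <- random_test_graph(n = sample(10:25, 1), p_edge = runif(1, 0.1, 0.5),
                           seed = seed)
    A <- adjacency_from_graph(g)
    expect_equal(clustering_map(g)$values, oracle_clustering(A))
    expect_equal(local_efficiency_map(g)$values, oracle_local_efficiency(A))
  }
})

test_that("global features match exhaustive oracles and handle disconnection", {
  k5 <- functional_graph(t(combn(5L, 2L)), n = 5, xyz_vox = cbind(1:5, 0, 0))
  gf <- global_features(k5)
  expect_equal(gf$mean_degree, 4)
  expect_equal(gf$mean_geodesic, 1)
  expect_equal(gf$mean_clustering, 1)
  expect_equal(gf$giant_component_size, 5)
  expect_equal(gf$giant_component_ratio, 1)
  expect_equal(gf$total_links, 10)

  # two disjoint edges: connected pairs only enter the geodesic mean
  disj <- functional_graph(rbind(c(1L, 2L), c(3L, 4L)), n = 4,
                           xyz_vox = cbind(1:4, 0, 0))
  gfd <- global_features(disj)
  expect_equal(gfd$mean_degree, 1)
  expect_equal(gfd$mean_geodesic, 1)
  expect_equal(gfd$giant_component_size, 2)
  expect_equal(gfd$giant_component_ratio, 0.5)
  expect_equal(gfd$total_links, 2)

  empty <- functional_graph(matrix(integer(0), 0, 2), n = 3,
                            xyz_vox = cbind(1:3, 0, 0))
  expect_true(is.na(global_features(empty)$mean_geodesic))

  for (seed in 1:10) {
    g <- random_test_graph(n = 30, p_edge = runif(1, 0.03, 0.3), seed = 100 + seed)
    A <- adjacency_from_graph(g)
    want <- oracle_global(A)
    got <- global_features(g)
    for (nm in names(want)) {
      expect_equal(unname(got[[nm]]), unname(want[[nm]]), label = nm)
    }
  }
})
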