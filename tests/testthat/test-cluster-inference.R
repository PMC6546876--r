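test_that("binomial tail matches the exact big-integer oracle (n <= 64)", {
  for (n in c(1, 2, 7, 13, 29, 30, 47, 64)) {
    for (k in 0:n) {
      expect_equal(binomial_tail_p(k, n), binom_tail_oracle(k, n),
                   tolerance = 1e-12,
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("binomial tail endpoints and monotonicity", {
  expect_equal(binomial_tail_p(0, 29), 1.0)
  expect_equal(binomial_tail_p(29, 29), 2^-29)
  # frozen from the exact integer oracle: sum(C(29, 23:29)) / 2^29
  expect_equal(binomial_tail_p(23, 29), 621616 / 2^29, tolerance = 1e-12)
  for (n in c(5, 29, 47)) {
    p <- binomial_tail_p(0:n, n)
    expect_true(all(diff(p) < 0))
  }
  # at n = 64 the extreme upper tail saturates double precision near 1,
  # so only non-increase is representable there
  expect_true(all(diff(binomial_tail_p(0:64, 64)) <= 0))
  # strict tail convention P(X > k)
  expect_equal(binomial_tail_p(28, 29, strict = TRUE), 2^-29)
  expect_error(binomial_tail_p(30, 29), "0 <= k <= n")
  expect_error(binomial_tail_p(-1, 29), "0 <= k <= n")
})

test_that("accuracy maps convert pointwise to p maps", {
  grid <- iso_grid(6)
  acc <- structure(list(accuracy = array(1, c(6, 6, 6)), grid = grid,
                        n_subjects = 29L), class = "accuracy_map")
  pm <- accuracy_to_pmap(acc)
  expect_true(all(pm$p == 2^-29))
  acc$accuracy[] <- 0
  expect_true(all(accuracy_to_pmap(acc)$p == 1))
  # NA outside the defined region stays NA; multiples of 1/n round exactly
  acc$accuracy[] <- NA
  acc$accuracy[1, 1, 1] <- 23 / 29
  pm <- accuracy_to_pmap(acc)
  expect_identical(sum(!is.na(pm$p)), 1L)
  expect_equal(pm$p[1, 1, 1], binomial_tail_p(23, 29))
  acc$accuracy[1, 1, 1] <- 1.5
  expect_error(accuracy_to_pmap(acc), "0, 1")
})

make_pmap <- function(p, grid) {
  structure(list(p = p, grid = grid, n_subjects = 29L, accuracy = 1 - p),
            class = "p_map")
}

test_that("a suprathreshold cube is one cluster; size filter applies", {
  grid <- iso_grid(12)
  p <- array(0.5, c(12, 12, 12))
  p[4:7, 4:7, 4:7] <- 1e-6 # 64 voxels
  cl <- label_clusters(make_pmap(p, grid), inference_config(min_size = 50))
  expect_identical(nrow(cl$clusters), 1L)
  expect_identical(cl$clusters$size, 64L)
  expect_identical(sum(cl$labels > 0), 64L)
  # 49 voxels fail a min_size of 50
  p2 <- array(0.5, c(12, 12, 12))
  p2[4:10, 4:10, 4] <- 1e-6 # 49 voxels
  cl2 <- label_clusters(make_pmap(p2, grid), inference_config(min_size = 50))
  expect_identical(nrow(cl2$clusters), 0L)
  cl3 <- label_clusters(make_pmap(p2, grid), inference_config(min_size = 49))
  expect_identical(cl3$clusters$size, 49L)
})

test_that("corner-touching blocks split under 18 but join under 26", {
  grid <- iso_grid(10)
  p <- array(0.5, c(10, 10, 10))
  p[2:3, 2:3, 2:3] <- 1e-6
  p[4:5, 4:5, 4:5] <- 1e-6 # touches only through the (3,3,3)-(4,4,4) corner
  cl18 <- label_clusters(make_pmap(p, grid),
                         inference_config(min_size = 1, connectivity = 18))
  cl26 <- label_clusters(make_pmap(p, grid),
                         inference_config(min_size = 1, connectivity = 26))
  expect_identical(nrow(cl18$clusters), 2L)
  expect_identical(nrow(cl26$clusters), 1L)
  # edge-touching blocks join already under 18 but not under 6
  p2 <- array(0.5, c(10, 10, 10))
  p2[2, 2, 2] <- 1e-6
  p2[3, 3, 2] <- 1e-6 # shares an edge
  expect_identical(nrow(label_clusters(
    make_pmap(p2, grid), inference_config(min_size = 1, connectivity = 18))
    $clusters), 1L)
  expect_identical(nrow(label_clusters(
    make_pmap(p2, grid), inference_config(min_size = 1, connectivity = 6))
    $clusters), 2L)
})

test_that("clusters are ordered by size with deterministic peaks", {
  grid <- iso_grid(14)
  p <- array(0.5, c(14, 14, 14))
  p[2:5, 2:5, 2:5] <- 1e-5          # 64 voxels
  p[9:12, 9:12, 9:11] <- 1e-5       # 48 voxels
  p[10, 10, 10] <- 1e-8             # the small cluster's peak
  cl <- label_clusters(make_pmap(p, grid), inference_config(min_size = 10))
  expect_identical(cl$clusters$size, c(64L, 48L))
  expect_identical(unlist(cl$clusters[2, c("peak_x", "peak_y", "peak_z")],
                          use.names = FALSE), c(10L, 10L, 10L))
  # tie on p: lexicographically (column-major) smallest voxel wins
  expect_identical(unlist(cl$clusters[1, c("peak_x", "peak_y", "peak_z")],
                          use.names = FALSE), c(2L, 2L, 2L))
  # suprathreshold voxel count is conserved
  expect_identical(sum(p < 1e-4), sum(cl$clusters$size))
})

test_that("permutation p-values are calibrated, seeded, and bounded", {
  sc <- separated_clouds(V = 30)
  res <- permutation_test_cluster(sc$X, sc$y, n_perm = 200, seed = 5)
  expect_equal(res$observed, 1.0)
  expect_equal(res$p, 1 / 201) # no permutation matches a perfect score
  # reproducibility
  res2 <- permutation_test_cluster(sc$X, sc$y, n_perm = 200, seed = 5)
  expect_identical(res$p, res2$p)
  expect_identical(res$permuted, res2$permuted)
  expect_false(identical(
    permutation_test_cluster(sc$X, sc$y, n_perm = 200, seed = 6)$permuted,
    res$permuted))
  expect_error(permutation_test_cluster(sc$X, sc$y, n_perm = 0), "n_perm")
})

test_that("null permutation p-values are roughly uniform", {
  y <- rep(c("A", "B"), c(7, 8))
  ps <- vapply(1:20, function(r) {
    X <- with_test_seed(100 + r, matrix(rnorm(15 * 20), 15))
    permutation_test_cluster(X, y, n_perm = 100, seed = r)$p
  }, numeric(1))
  expect_equal(mean(ps), 0.5, tolerance = 0.2)
  expect_gt(min(ps), 0.005)
})
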