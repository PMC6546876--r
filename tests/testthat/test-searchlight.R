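test_that("extract_features returns subjects x sphere-voxels", {
  coh <- generate_cohort(cohort_spec(14, 15, iso_grid(16), seed = 2))
  off <- sphere_offsets(5)
  X <- extract_features(coh, c(8, 8, 8), off)
  expect_identical(dim(X), c(29L, 171L))
  # constant volumes give constant features
  coh$volumes[] <- 3.14
  expect_true(all(extract_features(coh, c(8, 8, 8), off) == 3.14))
  # single-voxel mask gives the center column only
  msk <- array(FALSE, c(16, 16, 16)); msk[8, 8, 8] <- TRUE
  coh2 <- generate_cohort(cohort_spec(4, 4, iso_grid(16, mask = msk),
                                      seed = 1))
  X1 <- extract_features(coh2, c(8, 8, 8), off)
  expect_identical(dim(X1), c(8L, 1L))
  expect_equal(X1[, 1], coh2$volumes[8, 8, 8, ])
})

test_that("feature columns line up across subjects", {
  coh <- generate_cohort(cohort_spec(3, 3, iso_grid(12), seed = 3))
  off <- sphere_offsets(3)
  X <- extract_features(coh, c(6, 6, 6), off)
  mem <- in_mask_sphere(c(6, 6, 6), off, coh$grid)
  for (s in c(1, 4)) {
    expect_equal(X[s, ], coh$volumes[cbind(mem, s)])
  }
})

test_that("searchlight over a single-voxel mask is single-voxel LOOCV", {
  msk <- array(FALSE, c(12, 12, 12)); msk[6, 6, 6] <- TRUE
  coh <- generate_cohort(cohort_spec(6, 6, iso_grid(12, mask = msk),
                                     seed = 4))
  am <- searchlight_map(coh, radius_mm = 5)
  expect_identical(sum(!is.na(am$accuracy)), 1L)
  X <- matrix(coh$volumes[6, 6, 6, ], ncol = 1)
  expect_equal(am$accuracy[6, 6, 6],
               loocv_accuracy(X, coh$subjects$group))
})

test_that("radius-0 searchlight equals voxel-wise classification", {
  msk <- array(FALSE, c(8, 8, 8)); msk[4:5, 4, 4] <- TRUE
  coh <- generate_cohort(cohort_spec(5, 5, iso_grid(8, mask = msk), seed = 5))
  am <- searchlight_map(coh, radius_mm = 0)
  for (v in list(c(4L, 4L, 4L), c(5L, 4L, 4L))) {
    expect_equal(am$accuracy[v[1], v[2], v[3]],
                 loocv_accuracy(matrix(coh$volumes[v[1], v[2], v[3], ],
                                       ncol = 1),
                                coh$subjects$group))
  }
})

test_that("searchlight map is invariant to subject order and joint scaling", {
  coh <- generate_cohort(cohort_spec(5, 5, iso_grid(8), seed = 6))
  am <- searchlight_map(coh, radius_mm = 3)
  perm <- with_test_seed(7, sample(10))
  coh2 <- coh
  coh2$volumes <- coh$volumes[, , , perm]
  coh2$subjects <- coh$subjects[perm, ]
  expect_equal(searchlight_map(coh2, radius_mm = 3)$accuracy, am$accuracy)
  coh3 <- coh
  coh3$volumes <- 2.5 * coh$volumes - 7
  expect_equal(searchlight_map(coh3, radius_mm = 3)$accuracy, am$accuracy)
})

test_that("all searchlight accuracies are multiples of 1/N inside the mask", {
  coh <- generate_cohort(cohort_spec(5, 6, iso_grid(8), seed = 8))
  am <- searchlight_map(coh, radius_mm = 3)
  a <- am$accuracy[!is.na(am$accuracy)]
  expect_identical(length(a), sum(coh$grid$mask))
  expect_equal(a * 11, round(a * 11))
})

test_that("drop_partial leaves truncated spheres undefined", {
  coh <- generate_cohort(cohort_spec(4, 4, iso_grid(10), seed = 9))
  am <- searchlight_map(coh, radius_mm = 5, drop_partial = TRUE)
  # only centers whose full 171-voxel sphere fits are defined
  defined <- !is.na(am$accuracy)
  expect_true(all(which(defined, arr.ind = TRUE) >= 4))
  expect_true(all(which(defined, arr.ind = TRUE) <= 7))
  expect_gt(sum(defined), 0)
})

test_that("the blob's neighborhood carries the signal", {
  sp <- blob_spec(n = 16, d = 3, radius_mm = 6, seed = 10)
  coh <- generate_cohort(sp)
  am <- searchlight_map(coh)
  blob <- effect_indicator_for_tests(sp)
  expect_gt(mean(am$accuracy[blob]), mean(am$accuracy[!blob]) + 0.1)
})

test_that("regressing out a signal-carrying covariate removes the signal", {
  # strong blob: high accuracy near it; regressing the voxel values on the
  # group indicator itself (as a numeric covariate) removes all group
  # information, so the high accuracies must disappear
  sp <- blob_spec(n = 12, d = 4, radius_mm = 6, seed = 12, n1 = 7L, n2 = 7L)
  coh <- generate_cohort(sp)
  base <- searchlight_map(coh)
  grp_num <- data.frame(g = as.integer(coh$subjects$group == "MRP"))
  reg <- searchlight_map(coh, covariates = grp_num)
  blob <- effect_indicator_for_tests(sp)
  expect_gt(mean(base$accuracy[blob]), 0.8)
  expect_lt(mean(reg$accuracy[blob]), mean(base$accuracy[blob]) - 0.3)
})
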