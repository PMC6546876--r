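# closed-form pooled-variance two-sample t, the oracle for the GLM route
pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

test_that("glm_tmap without covariates equals the two-sample t", {
  coh <- generate_cohort(cohort_spec(7, 8, iso_grid(8), seed = 21))
  tm <- glm_tmap(coh)
  grp <- coh$subjects$group == "MRP"
  for (v in list(c(2, 3, 4), c(5, 5, 5), c(8, 1, 7))) {
    y <- coh$volumes[v[1], v[2], v[3], ]
    expect_equal(tm$t[v[1], v[2], v[3]], pooled_t(y[grp], y[!grp]),
                 tolerance = 1e-8)
  }
  expect_identical(tm$df, 13L)
})

test_that("covariates orthogonal to group and response leave beta and RSS", {
  # With a covariate z orthogonal to span{intercept, group} and to every
  # voxel's response, the group coefficient and residual sum of squares are
  # untouched; t only rescales through the lost residual degree of freedom
  # (sigma^2 = RSS/df), so t_cov = t_base * sqrt(df_base / df_cov) inverted:
  coh <- generate_cohort(cohort_spec(6, 6, iso_grid(6), seed = 22))
  grp <- as.integer(coh$subjects$group == "MRP")
  z <- with_test_seed(1, rnorm(12))
  Zg <- cbind(1, grp)
  z <- z - Zg %*% solve(crossprod(Zg), crossprod(Zg, z)) # z | {1, group}
  z <- as.vector(z)
  coh2 <- coh
  flat <- matrix(coh$volumes, ncol = 12) # voxels x subjects
  flat <- flat - outer(as.vector(flat %*% z) / sum(z * z), z)
  coh2$volumes <- array(flat, dim = dim(coh$volumes))
  with_cov <- glm_tmap(coh2, covariates = data.frame(z = z))
  base2 <- glm_tmap(coh2)
  expect_identical(base2$df, 10L)
  expect_identical(with_cov$df, 9L)
  expect_equal(with_cov$t[coh$grid$mask] * sqrt(10 / 9),
               base2$t[coh$grid$mask], tolerance = 1e-8)
})

test_that("degenerate designs error, zero-variance covariates drop", {
  coh <- generate_cohort(cohort_spec(5, 5, iso_grid(6), seed = 23))
  grp <- as.integer(coh$subjects$group == "MRP")
  expect_error(glm_tmap(coh, covariates = data.frame(g2 = grp)),
               "rank deficient")
  expect_warning(tm <- glm_tmap(coh, covariates = data.frame(c0 = rep(1, 10))),
                 "zero variance")
  expect_equal(tm$t, glm_tmap(coh)$t)
})

test_that("t sign convention is group1 (MRP) minus group2 (MSP)", {
  coh <- generate_cohort(cohort_spec(6, 6, iso_grid(6), seed = 24))
  coh$volumes[3, 3, 3, coh$subjects$group == "MRP"] <-
    coh$volumes[3, 3, 3, coh$subjects$group == "MRP"] + 10
  tm <- glm_tmap(coh)
  expect_gt(tm$t[3, 3, 3], 5)
})

test_that("Monte-Carlo extent threshold is monotone on shared seeds", {
  grid <- iso_grid(16)
  base <- mc_extent_threshold(grid, voxel_p = 0.01, alpha = 0.05,
                              fwhm_mm = 8, n_iterations = 200, seed = 31)
  rough <- mc_extent_threshold(grid, voxel_p = 0.01, alpha = 0.05,
                               fwhm_mm = 0, n_iterations = 200, seed = 31)
  expect_lt(rough, base) # smoothness inflates null cluster sizes, strictly
  strict_p <- mc_extent_threshold(grid, voxel_p = 0.001, alpha = 0.05,
                                  fwhm_mm = 8, n_iterations = 200, seed = 31)
  expect_lte(strict_p, base)
  lax_alpha <- mc_extent_threshold(grid, voxel_p = 0.01, alpha = 0.2,
                                   fwhm_mm = 8, n_iterations = 200, seed = 31)
  expect_lte(lax_alpha, base)
  expect_identical(as.integer(mc_extent_threshold(
    grid, voxel_p = 0.01, alpha = 1, fwhm_mm = 0, n_iterations = 100,
    seed = 31)), 1L)
  expect_warning(mc_extent_threshold(grid, n_iterations = 50, seed = 1),
                 "unstable")
  expect_error(mc_extent_threshold(grid, voxel_p = 1.2), "voxel_p")
})

test_that("apply_correction filters by extent and splits by sign", {
  grid <- iso_grid(12)
  tmap <- structure(list(t = array(0, c(12, 12, 12)), df = 25L, grid = grid),
                    class = "t_map")
  # null map: empty result
  expect_identical(nrow(apply_correction(tmap, 40)), 0L)
  # a 45-voxel negative block survives threshold 40, direction group1<group2
  tmap$t[3:7, 3:5, 3:5] <- -6 # 45 voxels
  out <- apply_correction(tmap, 40)
  expect_identical(nrow(out), 1L)
  expect_identical(out$direction, "group1<group2")
  expect_identical(out$size, 45L)
  expect_lt(out$peak_t, 0)
  # same block fails threshold 46
  expect_identical(nrow(apply_correction(tmap, 46)), 0L)
  # opposite-sign blocks are separate clusters even when adjacent
  tmap$t[8, 3:5, 3:5] <- 6
  out2 <- apply_correction(tmap, 1)
  expect_identical(sort(out2$direction),
                   c("group1<group2", "group1>group2"))
})

test_that("posthoc recovers a negative blob through the full sub-pipeline", {
  hits <- vapply(1:6, function(s) {
    sp <- blob_spec(n = 16, d = -1.5, radius_mm = 6, seed = 300 + s)
    coh <- generate_cohort(sp)
    tm <- glm_tmap(coh, covariates = coh$subjects[c("age", "gender")])
    thr <- mc_extent_threshold(coh$grid, n_iterations = 200,
                               seed = 400 + s)
    out <- apply_correction(tm, thr)
    if (!nrow(out)) return(FALSE)
    supp <- effect_support(sp)
    neg <- out[out$direction == "group1<group2", ]
    if (!nrow(neg)) return(FALSE)
    members <- attr(out, "members")
    dice <- max(vapply(neg$id, function(i) {
      B <- array(FALSE, coh$grid$shape)
      B[members[[i]]] <- TRUE
      2 * sum(supp & B) / (sum(supp) + sum(B))
    }, numeric(1)))
    dice >= 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("spearman correlation handles monotone, null, and tied data", {
  expect_equal(spearman_cluster_dvas(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cluster_dvas(1:8, -(1:8))$rho, -1)
  expect_lt(spearman_cluster_dvas(1:8, (1:8)^3)$p, 0.01)
  # ties use average ranks (t-approximation path)
  r <- spearman_cluster_dvas(c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9),
                             c(2, 1, 3, 3, 5, 4, 7, 6, 9, 8))
  expect_gt(r$rho, 0.7)
  expect_error(spearman_cluster_dvas(rep(1, 6), 1:6), "constant")
  expect_error(spearman_cluster_dvas(1:3, 1:3), "at least 4")
})

test_that("null spearman p-values reject at the nominal rate", {
  rej <- with_test_seed(41, {
    vapply(1:400, function(i) {
      spearman_cluster_dvas(rnorm(15), rnorm(15))$p < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
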