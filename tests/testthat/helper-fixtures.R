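# Shared fixture builders. Everything is generated in code; no binary files.

iso_grid <- function(n = 16, voxel = 1.5, mask = NULL) {
  volume_grid(rep(n, 3), rep(voxel, 3), mask = mask)
}

# small null cohort for fast end-to-end tests
tiny_null_spec <- function(n = 12, n1 = 6L, n2 = 6L, seed = 1L, fwhm = 8) {
  cohort_spec(n1, n2, iso_grid(n), smoothing_fwhm_mm = fwhm, seed = seed)
}

blob_spec <- function(n = 24, d = 2, radius_mm = 6, seed = 1L,
                      n1 = 14L, n2 = 15L) {
  ctr <- rep(n %/% 2, 3)
  cohort_spec(n1, n2, iso_grid(n),
              effect = effect_spec(ctr, radius_mm = radius_mm, d = d),
              seed = seed)
}

# two well-separated Gaussian clouds; 1-nearest-neighbor (the independent
# margin oracle) scores 1.0 on them by construction
separated_clouds <- function(n1 = 14, n2 = 15, V = 20, gap = 10, seed = 1) {
  with_test_seed(seed, {
    X <- rbind(matrix(rnorm(n1 * V, gap / 2), n1, V),
               matrix(rnorm(n2 * V, -gap / 2), n2, V))
    list(X = X, y = rep(c("MRP", "MSP"), c(n1, n2)))
  })
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# logical blob membership computed independently of the package's
# sphere/offset machinery (direct distance scan)
effect_indicator_for_tests <- function(spec) {
  g <- spec$grid
  out <- array(FALSE, g$shape)
  idx <- arrayInd(seq_len(prod(g$shape)), g$shape)
  for (b in seq_along(spec$effect$radius_mm)) {
    ctr <- spec$effect$centers[b, ]
    d <- sqrt(((idx[, 1] - ctr[1]) * g$voxel_size[1])^2 +
                ((idx[, 2] - ctr[2]) * g$voxel_size[2])^2 +
                ((idx[, 3] - ctr[3]) * g$voxel_size[3])^2)
    out[idx[d <= spec$effect$radius_mm[b] + 1e-9, , drop = FALSE]] <- TRUE
  }
  out
}

# leave-one-out 1-nearest-neighbor accuracy: independent margin-classifier
# oracle for clearly separable data
loocv_1nn <- function(X, y) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) y[which.min(D[i, ])] == y[i],
              logical(1)))
}
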