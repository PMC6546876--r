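#' Build a group + covariate design matrix
#'
#' Intercept, a 0/1 group indicator (1 = first level of `group`, i.e. MRP in
#' the default coding), and numeric covariates. Gender is coded 0/1
#' (`M` = 0, `F` = 1) when passed as character/factor; zero-variance
#' covariates are dropped with a warning.
#'
#' @param group Binary group labels.
#' @param covariates Optional data.frame of per-subject covariates.
#' @return List with `X` (design matrix), `group_col` (column index of the
#'   group effect) and `df` (residual degrees of freedom given n rows).
#' @export
design_matrix <- function(group, covariates = NULL) {
  lb <- as_binary_labels(group)
  X <- cbind(intercept = 1, group = 1 - lb$y) # first level = 1
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.factor(v)) {
        v <- as.integer(factor(v)) - 1
      }
      v <- as.numeric(v)
      if (stats::var(v) == 0) {
        warning(sprintf("covariate '%s' has zero variance; dropped", nm))
        next
      }
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_invalid("design matrix is rank deficient (a covariate is collinear %s",
                 "with the group indicator or intercept)")
  }
  list(X = X, group_col = 2L, df = nrow(X) - ncol(X))
}

#' Covariate-adjusted voxel-wise group t-map
#'
#' Ordinary least squares of GM value on intercept + group + covariates at
#' every voxel (optionally restricted to given clusters); the reported t is
#' the group coefficient over its standard error with `N - p` degrees of
#' freedom. With no covariates this equals the classical pooled-variance
#' two-sample t.
#'
#' @param cohort A `cohort`.
#' @param covariates Optional covariate data.frame (e.g.
#'   `cohort$subjects[c("age", "gender")]`).
#' @param restrict_to Optional `cluster_set`; only its voxels are tested.
#' @param group Labels; defaults to `cohort$subjects$group`. The t sign
#'   follows first-level minus second-level (MRP minus MSP).
#' @return A `t_map`: list with `t` (3D array, NA where untested), `df`,
#'   `grid`, `design`.
#' @export
glm_tmap <- function(cohort, covariates = NULL, restrict_to = NULL,
                     group = NULL) {
  if (is.null(group)) group <- cohort$subjects$group
  des <- design_matrix(group, covariates)
  grid <- cohort$grid
  sel <- if (is.null(restrict_to)) grid$mask else restrict_to$labels > 0
  lin <- which(sel)
  n <- dim(cohort$volumes)[4]
  nvox <- prod(grid$shape)
  Y <- matrix(0, n, length(lin))
  for (s in seq_len(n)) Y[s, ] <- cohort$volumes[lin + (s - 1) * nvox]

  X <- des$X
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  xtxinv_gg <- chol2inv(qr.R(qx))[des$group_col, des$group_col]
  tval <- beta[des$group_col, ] / sqrt(sigma2 * xtxinv_gg)

  tmap <- array(NA_real_, dim = grid$shape)
  tmap[lin] <- tval
  structure(list(t = tmap, df = df, grid = grid, design = des),
            class = "t_map")
}

#' Monte-Carlo cluster-extent threshold
#'
#' AlphaSim-style estimation of the minimum cluster size controlling the
#' family-wise error: simulate smooth Gaussian null fields on the grid,
#' standardize within the mask, threshold at the two-tailed `voxel_p`
#' quantile, and record the maximum connected-component size per iteration.
#' The returned extent is the smallest integer s such that the fraction of
#' iterations whose maximum cluster reaches s is at most `alpha`.
#'
#' @param grid A [volume_grid()].
#' @param voxel_p Two-tailed voxel-wise p threshold (default 0.01).
#' @param alpha Target family-wise error rate (default 0.05).
#' @param fwhm_mm Smoothness of the null fields in mm (default 8, the applied
#'   smoothing kernel; residual-based smoothness estimation is out of scope).
#' @param n_iterations Monte-Carlo iterations (default 1000; fewer than 100
#'   warns).
#' @param connectivity 6, 18 or 26 (default 18, matching the MVPA stage).
#' @param seed Integer seed.
#' @return Integer cluster-size threshold, with attribute `max_sizes` (the
#'   simulated maxima).
#' @export
mc_extent_threshold <- function(grid, voxel_p = 0.01, alpha = 0.05,
                                fwhm_mm = 8, n_iterations = 1000L,
                                connectivity = 18L, seed = 1L) {
  if (voxel_p <= 0 || voxel_p >= 1) stop_invalid("voxel_p must be in (0, 1)")
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha must be in (0, 1]")
  if (n_iterations < 100L) {
    warning("fewer than 100 Monte-Carlo iterations gives an unstable extent")
  }
  crit <- qnorm(1 - voxel_p / 2)
  msk <- which(grid$mask)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_iterations), function(i) {
      z <- array(rnorm(prod(grid$shape)), dim = grid$shape)
      if (fwhm_mm > 0) z <- smooth_volume(z, grid, fwhm_mm)
      v <- z[msk]
      v <- (v - mean(v)) / sd(v)
      flag <- array(FALSE, dim = grid$shape)
      flag[msk] <- abs(v) > crit
      sizes <- label_binary(flag, grid$shape, connectivity)$sizes
      if (length(sizes)) max(sizes) else 0L
    }, numeric(1))
  })
  # smallest s with P(max >= s) <= alpha
  s <- 1L
  while (mean(maxima >= s) > alpha) s <- s + 1L
  structure(s, max_sizes = maxima)
}

#' Apply the cluster-extent correction to a t-map
#'
#' Voxels with two-tailed `p < voxel_p` are split by the sign of t, labeled
#' by connectivity, and components reaching the extent threshold survive.
#'
#' @param tmap A `t_map` from [glm_tmap()].
#' @param min_cluster_size Extent threshold from [mc_extent_threshold()].
#' @param voxel_p Two-tailed voxel threshold (must match the one the extent
#'   was estimated for).
#' @param connectivity 6, 18 or 26.
#' @return A data.frame of surviving clusters (id, direction, size, peak t,
#'   peak voxel index and mm), plus attributes `labels` (3D signed-direction
#'   label array) and `members`.
#' @export
apply_correction <- function(tmap, min_cluster_size, voxel_p = 0.01,
                             connectivity = 18L) {
  pv <- 2 * pt(-abs(tmap$t), tmap$df)
  rows <- list()
  members <- list()
  labels <- array(0L, dim = tmap$grid$shape)
  nxt <- 0L
  for (sgn in c(1, -1)) {
    flag <- !is.na(tmap$t) & pv < voxel_p & sign(tmap$t) == sgn
    comp <- label_binary(flag, tmap$grid$shape, connectivity)
    keep <- which(comp$sizes >= min_cluster_size)
    keep <- keep[order(comp$sizes[keep], decreasing = TRUE)]
    for (k in keep) {
      nxt <- nxt + 1L
      lin <- which(comp$labels == k)
      labels[lin] <- nxt
      tv <- tmap$t[lin]
      peak <- lin[order(-abs(tv), lin)[1]]
      pk <- arrayInd(peak, tmap$grid$shape)[1, ]
      mm <- voxel_to_world(tmap$grid, pk)
      rows[[nxt]] <- data.frame(
        id = nxt,
        direction = if (sgn > 0) "group1>group2" else "group1<group2",
        size = length(lin), peak_t = tmap$t[peak],
        peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
        peak_mm_x = mm[1], peak_mm_y = mm[2], peak_mm_z = mm[3])
      members[[nxt]] <- arrayInd(lin, tmap$grid$shape)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = integer(), direction = character(), size = integer(),
    peak_t = numeric(), peak_x = integer(), peak_y = integer(),
    peak_z = integer(), peak_mm_x = numeric(), peak_mm_y = numeric(),
    peak_mm_z = numeric())
  attr(out, "labels") <- labels
  attr(out, "members") <- members
  out
}

#' Spearman correlation of cluster mean GM volume with treatment response
#'
#' Rank correlation (average ranks on ties) between per-subject mean GM
#' volume in a cluster and the VAS change; two-tailed p, exact for n <= 9
#' with untied data, t-approximation otherwise.
#'
#' @param cluster_mean_gm Per-subject mean GM volume in the cluster.
#' @param dvas Per-subject `delta_vas` values.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cluster_dvas <- function(cluster_mean_gm, dvas) {
  x <- as.numeric(cluster_mean_gm)
  y <- as.numeric(dvas)
  n <- length(x)
  if (n != length(y) || n < 4L) {
    stop_invalid("need at least 4 paired observations")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_invalid("correlation undefined for a constant input vector")
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9L && !ties) {
    ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    return(list(rho = unname(ct$estimate), p = ct$p.value, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Per-subject mean GM volume inside a cluster
#'
#' @param cohort A `cohort`.
#' @param members Integer matrix of 1-based member voxel indices (as stored
#'   in a `cluster_set`'s `members`).
#' @param subjects Optional row indices (e.g. one group only).
#' @return Numeric vector, one value per selected subject.
#' @export
cluster_mean_gm <- function(cohort, members, subjects = NULL) {
  if (is.null(subjects)) subjects <- seq_len(dim(cohort$volumes)[4])
  nvox <- prod(cohort$grid$shape)
  lin <- members[, 1] + cohort$grid$shape[1] *
    ((members[, 2] - 1) + cohort$grid$shape[2] * (members[, 3] - 1))
  vapply(subjects,
         function(s) mean(cohort$volumes[lin + (s - 1) * nvox]),
         numeric(1))
}
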