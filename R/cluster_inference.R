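#' Exact binomial tail probability under the chance null
#'
#' Under the null of indistinguishable groups the number of correctly
#' classified subjects follows Bi(n, 1/2); the p-value of observing `k`
#' correct is the upper tail `P(X >= k)` (the observed count included, the
#' exact-test convention; set `strict = TRUE` for `P(X > k)`).
#'
#' @param k Number of correct classifications, `0 <= k <= n` (vectorized).
#' @param n Number of subjects.
#' @param strict Exclude the observed count from the tail.
#' @return Tail probability in `(0, 1]`.
#' @export
binomial_tail_p <- function(k, n, strict = FALSE) {
  if (any(n < 1) || any(k < 0) || any(k > n) ||
      any(k != floor(k)) || any(n != floor(n))) {
    stop_invalid("need integers 0 <= k <= n, n >= 1")
  }
  k <- k + strict
  if (all(n <= 52)) {
    # sum of C(n, k..n) is < 2^53 for n <= 52, so the integer sum and the
    # power-of-two division are both exact in doubles
    kn <- cbind(k, n)
    apply(kn, 1, function(r) {
      if (r[1] > r[2]) return(0)
      sum(choose(r[2], r[1]:r[2])) / 2^r[2]
    })
  } else {
    pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  }
}

#' Convert an accuracy map to a binomial p-value map
#'
#' Per voxel, `p = binomial_tail_p(round(accuracy * n), n)`; the rounding is
#' exact because LOOCV accuracies are multiples of 1/n.
#'
#' @param acc An `accuracy_map` from [searchlight_map()].
#' @param strict Tail convention, see [binomial_tail_p()].
#' @return A `p_map`: list with `p` (3D array, NA outside the accuracy map),
#'   `grid`, `n_subjects`.
#' @export
accuracy_to_pmap <- function(acc, strict = FALSE) {
  a <- acc$accuracy
  defined <- !is.na(a)
  if (any(a[defined] < 0 | a[defined] > 1)) {
    stop_invalid("accuracies must lie in [0, 1]")
  }
  p <- array(NA_real_, dim = dim(a))
  k <- round(a[defined] * acc$n_subjects)
  p[defined] <- binomial_tail_p(k, acc$n_subjects, strict = strict)
  structure(list(p = p, grid = acc$grid, n_subjects = acc$n_subjects,
                 accuracy = a),
            class = "p_map")
}

#' Cluster inference configuration
#'
#' Defaults follow the published procedure: voxel-wise `p < 1e-4`, clusters
#' of at least 50 contiguous voxels under 18-connectivity (6 faces + 12
#' edges), and 1000 label permutations at one-tailed alpha 0.05.
#'
#' @param voxel_alpha Voxel-wise p threshold (suprathreshold means
#'   `p < voxel_alpha`).
#' @param min_size Minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @param n_permutations Label permutations per cluster.
#' @param perm_alpha One-tailed permutation significance level.
#' @param seed Seed for the permutation draws.
#' @return An `inference_config` object.
#' @export
inference_config <- function(voxel_alpha = 1e-4, min_size = 50L,
                             connectivity = 18L, n_permutations = 1000L,
                             perm_alpha = 0.05, seed = 1L) {
  if (voxel_alpha <= 0 || voxel_alpha >= 1) {
    stop_invalid("voxel_alpha must lie in (0, 1)")
  }
  if (min_size < 1L) stop_invalid("min_size must be >= 1")
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop_invalid("connectivity must be 6, 18 or 26")
  }
  structure(list(voxel_alpha = voxel_alpha, min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity),
                 n_permutations = as.integer(n_permutations),
                 perm_alpha = perm_alpha, seed = as.integer(seed)),
            class = "inference_config")
}

# components of a logical array; returns list(labels = 3D int array,
# sizes = per-label voxel counts)
label_binary <- function(flag, shape, connectivity) {
  lab <- cpp_label_components(as.logical(flag), shape, connectivity)
  lab <- array(lab, dim = shape)
  list(labels = lab, sizes = tabulate(lab[lab > 0]))
}

#' Extract suprathreshold clusters from a p-value map
#'
#' Voxels with `p < voxel_alpha` are partitioned into maximal connected
#' components; components with at least `min_size` voxels are returned in
#' decreasing size order. The peak voxel is the member with minimal p
#' (maximal accuracy), ties broken by smallest column-major linear index.
#'
#' @param pmap A `p_map` from [accuracy_to_pmap()].
#' @param config An [inference_config()].
#' @return A `cluster_set`: list with `labels` (3D integer array, 0 =
#'   background, clusters renumbered 1.. by decreasing size) and `clusters`
#'   (data.frame: id, size, peak index/world coordinates, peak_accuracy,
#'   peak_p) plus `members` (list of index matrices).
#' @export
label_clusters <- function(pmap, config = inference_config()) {
  supra <- !is.na(pmap$p) & pmap$p < config$voxel_alpha
  comp <- label_binary(supra, pmap$grid$shape, config$connectivity)
  keep <- which(comp$sizes >= config$min_size)
  keep <- keep[order(comp$sizes[keep], decreasing = TRUE)]

  labels <- array(0L, dim = pmap$grid$shape)
  members <- list()
  rows <- list()
  for (i in seq_along(keep)) {
    lin <- which(comp$labels == keep[i])
    labels[lin] <- i
    idx <- arrayInd(lin, pmap$grid$shape)
    pv <- pmap$p[lin]
    peak <- lin[order(pv, lin)[1]]
    pk <- arrayInd(peak, pmap$grid$shape)[1, ]
    rows[[i]] <- data.frame(
      id = i, size = length(lin),
      peak_x = pk[1], peak_y = pk[2], peak_z = pk[3],
      peak_mm_x = NA_real_, peak_mm_y = NA_real_, peak_mm_z = NA_real_,
      peak_accuracy = if (is.null(pmap$accuracy)) NA_real_ else
        pmap$accuracy[peak],
      peak_p = pmap$p[peak], perm_p = NA_real_
    )
    rows[[i]][, c("peak_mm_x", "peak_mm_y", "peak_mm_z")] <-
      as.list(voxel_to_world(pmap$grid, pk))
    members[[i]] <- idx
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else data.frame(
    id = integer(), size = integer(), peak_x = integer(), peak_y = integer(),
    peak_z = integer(), peak_mm_x = numeric(), peak_mm_y = numeric(),
    peak_mm_z = numeric(), peak_accuracy = numeric(), peak_p = numeric(),
    perm_p = numeric())
  structure(list(labels = labels, clusters = clusters, members = members,
                 grid = pmap$grid, config = config),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s)\n", nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Label-permutation test for one cluster
#'
#' The observed statistic is the LOOCV accuracy of the cluster's full voxel
#' set; for each permutation the group labels are shuffled (preserving group
#' sizes) and the LOOCV accuracy recomputed. The add-one p-value
#' `(1 + #\{permuted >= observed\}) / (n_perm + 1)` never returns 0 and its
#' smallest achievable value at 1000 permutations is 1/1001.
#'
#' @param features Subjects-by-voxels matrix of the cluster's voxels.
#' @param labels Binary group labels.
#' @param config An [svm_config()].
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed for the shuffles.
#' @return List with `p`, `observed` accuracy, and the vector of
#'   permutation accuracies.
#' @export
permutation_test_cluster <- function(features, labels,
                                     config = svm_config(),
                                     n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) stop_invalid("n_perm must be >= 1")
  features <- as.matrix(features)
  lb <- as_binary_labels(labels)
  n <- length(lb$y)
  observed <- cpp_loocv_accuracy(features, lb$y, config$C, config$gamma)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n) - 1L, integer(n)))
  })
  acc <- cpp_loocv_perm(features, lb$y, config$C, config$gamma, perms)
  list(p = (1 + sum(acc >= observed)) / (n_perm + 1), observed = observed,
       permuted = acc)
}

#' Permutation-test every cluster of a cluster set
#'
#' @param clusters A `cluster_set` from [label_clusters()].
#' @param cohort The cohort the clusters came from.
#' @param config An [svm_config()].
#' @param n_perm,seed See [permutation_test_cluster()]; each cluster uses a
#'   seed derived from `seed` and its id.
#' @param labels Group labels; defaults to `cohort$subjects$group`.
#' @return The `cluster_set` with the `perm_p` column filled in.
#' @export
permutation_test_clusters <- function(clusters, cohort,
                                      config = svm_config(),
                                      n_perm = 1000L, seed = 1L,
                                      labels = NULL) {
  if (is.null(labels)) labels <- cohort$subjects$group
  nvox <- prod(cohort$grid$shape)
  for (i in seq_len(nrow(clusters$clusters))) {
    idx <- clusters$members[[i]]
    lin <- idx[, 1] + cohort$grid$shape[1] *
      ((idx[, 2] - 1) + cohort$grid$shape[2] * (idx[, 3] - 1))
    n <- dim(cohort$volumes)[4]
    X <- t(matrix(vapply(seq_len(n),
                         function(s) cohort$volumes[lin + (s - 1) * nvox],
                         numeric(length(lin))),
                  nrow = length(lin), ncol = n))
    res <- permutation_test_cluster(X, labels, config, n_perm,
                                    seed = seed + i)
    clusters$clusters$perm_p[i] <- res$p
  }
  clusters
}
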