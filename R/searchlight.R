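#' SVM configuration
#'
#' The classifier is fixed to a C-SVC with radial-basis-function kernel, the
#' "default parameters" convention of the classical libsvm tooling: `C = 1`
#' and `gamma = 1/V` where V is the number of features in the sphere.
#' Features are standardized per column on the training fold only
#' (zero-variance training columns map to 0), and the training parameters are
#' applied to the held-out subject.
#'
#' @param C Soft-margin cost, positive.
#' @param gamma RBF width; a positive number, or the string `"1/V"`
#'   (default) to resolve to 1/number-of-features per sphere.
#' @return An `svm_config` object.
#' @export
svm_config <- function(C = 1, gamma = "1/V") {
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop_invalid("`C` must be a single positive number")
  }
  if (identical(gamma, "1/V")) {
    gamma <- -1 # resolved per sphere in the C++ core
  } else if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
             gamma <= 0) {
    stop_invalid("`gamma` must be positive or \"1/V\"")
  }
  structure(list(C = C, gamma = gamma), class = "svm_config")
}

as_binary_labels <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) {
    stop_invalid("labels must have exactly 2 classes (got %d)", nlevels(f))
  }
  if (min(table(f)) < 2L) {
    stop_invalid("each class needs at least 2 subjects")
  }
  list(y = as.integer(f) - 1L, levels = levels(f))
}

#' Extract sphere feature matrix
#'
#' The subjects-by-voxels matrix of GM values inside the (mask-clipped)
#' sphere centered at `center`, with a consistent column order across
#' subjects (center first, then by distance).
#'
#' @param volumes 4D array (x, y, z, subject) or a `cohort`.
#' @param center 1-based voxel index (3-vector) inside the mask.
#' @param offsets An `offset_set` from [sphere_offsets()].
#' @param grid A [volume_grid()]; taken from the cohort if omitted.
#' @return Numeric matrix, one row per subject, one column per sphere voxel.
#' @export
extract_features <- function(volumes, center, offsets, grid = NULL) {
  if (inherits(volumes, "cohort")) {
    grid <- volumes$grid
    volumes <- volumes$volumes
  }
  stopifnot(!is.null(grid))
  members <- in_mask_sphere(center, offsets, grid)
  n <- dim(volumes)[4]
  lin <- members[, 1] + grid$shape[1] *
    ((members[, 2] - 1) + grid$shape[2] * (members[, 3] - 1))
  nvox <- prod(grid$shape)
  X <- matrix(0, n, nrow(members))
  for (s in seq_len(n)) {
    X[s, ] <- volumes[lin + (s - 1) * nvox]
  }
  X
}

#' Leave-one-out cross-validated SVM-RBF accuracy
#'
#' For each of the N folds the remaining N-1 subjects are standardized per
#' feature, an SVM-RBF is fit on them, and the held-out subject is predicted
#' with the training fold's standardization; accuracy is the fraction of
#' correctly predicted held-out subjects. Deterministic; prediction ties go
#' to the class with the lower label index.
#'
#' @param features Subjects-by-voxels numeric matrix.
#' @param labels Binary label vector (factor, character or 0/1).
#' @param config An [svm_config()].
#' @return Accuracy in `[0, 1]` (a multiple of 1/N).
#' @export
loocv_accuracy <- function(features, labels, config = svm_config()) {
  features <- as.matrix(features)
  if (anyNA(features)) stop_invalid("features must not contain NA")
  lb <- as_binary_labels(labels)
  if (length(lb$y) != nrow(features)) {
    stop_invalid("labels length (%d) != feature rows (%d)", length(lb$y),
                 nrow(features))
  }
  cpp_loocv_accuracy(features, lb$y, config$C, config$gamma)
}

# residual-maker matrix I - Z (Z'Z)^-1 Z' for covariate regression
residual_projector <- function(covariates) {
  Z <- cbind(1, as.matrix(covariates))
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop_invalid("covariate design is rank deficient")
  diag(nrow(Z)) - Z %*% chol2inv(qr.R(qz)) %*% t(Z)
}

#' Whole-mask searchlight accuracy map
#'
#' Sweeps a sphere of `radius_mm` over every mask voxel of the cohort's grid
#' and assigns the sphere's LOOCV SVM-RBF accuracy to its center. Spheres
#' clipped by the mask or grid edge keep their in-mask voxels (set
#' `drop_partial = TRUE` to skip them). If `covariates` are supplied, every
#' voxel's values are first replaced by the residuals of a regression on the
#' covariates across subjects (the covariate-regression variant; default
#' off).
#'
#' @param cohort A `cohort` (or list with `volumes`, `grid`, `subjects`).
#' @param radius_mm Searchlight radius in mm (default 5).
#' @param config An [svm_config()].
#' @param labels Group labels; defaults to `cohort$subjects$group`.
#' @param covariates Optional data.frame/matrix of nuisance covariates
#'   (numeric; code gender 0/1 first, see [design_matrix()]).
#' @param drop_partial Drop mask-truncated spheres instead of shortening
#'   their feature vectors.
#' @return An `accuracy_map`: list with `accuracy` (3D array, NA outside
#'   mask), `grid`, `n_subjects`, `radius_mm`.
#' @export
searchlight_map <- function(cohort, radius_mm = 5, config = svm_config(),
                            labels = NULL, covariates = NULL,
                            drop_partial = FALSE) {
  grid <- cohort$grid
  if (is.null(labels)) labels <- cohort$subjects$group
  lb <- as_binary_labels(labels)
  n <- dim(cohort$volumes)[4]
  if (length(lb$y) != n) stop_invalid("labels do not match subject count")
  off <- sphere_offsets(radius_mm, grid$voxel_size)
  proj <- if (is.null(covariates)) NULL else residual_projector(covariates)
  acc <- cpp_searchlight(as.numeric(cohort$volumes),
                         c(grid$shape, n), as.logical(grid$mask),
                         off$offsets, lb$y, config$C, config$gamma,
                         drop_partial, proj)
  structure(list(accuracy = array(acc, dim = grid$shape), grid = grid,
                 n_subjects = n, radius_mm = radius_mm,
                 levels = lb$levels),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x$accuracy[!is.na(x$accuracy)]
  cat(sprintf(
    "<accuracy_map> n=%d, %d voxels, mean %.3f, max %.3f\n",
    x$n_subjects, length(v), mean(v), max(v)))
  invisible(x)
}
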