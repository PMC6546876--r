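#' Gaussian-smooth a volume
#'
#' Separable Gaussian filtering with per-axis sigma
#' `fwhm_mm / (2 * sqrt(2 * log(2)))` converted to voxel units by the grid
#' spacing. The kernel is truncated at 4 sigma and normalized, so a constant
#' map stays constant.
#'
#' @param data 3D numeric array on `grid`.
#' @param grid A [volume_grid()].
#' @param fwhm_mm Full width at half maximum of the kernel, in mm;
#'   `0` is the identity.
#' @param boundary `"reflect"` (default) mirrors the data at the grid edges;
#'   `"constant"` treats outside values as zero.
#' @return Smoothed 3D array.
#' @export
smooth_volume <- function(data, grid, fwhm_mm, boundary = c("reflect",
                                                            "constant")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm < 0) {
    stop_invalid("`fwhm_mm` must be a single non-negative number")
  }
  data <- as.array(data)
  if (!identical(dim(data), grid$shape)) {
    stop_invalid("data shape does not match grid shape")
  }
  if (fwhm_mm == 0) return(data)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / grid$voxel_size
  out <- cpp_gaussian_smooth(as.numeric(data), grid$shape, sigma_vox,
                             if (boundary == "reflect") 0L else 1L)
  array(out, dim = grid$shape)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) {
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Group-difference effect specification
#'
#' Spherical regions in which group 1 (MRP) differs from group 2 (MSP) by a
#' standardized mean shift applied before smoothing. Positive `d` means
#' group 1 minus group 2 is positive.
#'
#' @param centers Integer matrix (one row per blob) or 3-vector of 1-based
#'   voxel indices.
#' @param radius_mm Blob radii in mm (recycled).
#' @param d Standardized effect sizes (Cohen's d against the unsmoothed
#'   voxel noise sd; recycled).
#' @return An `effect_spec` object.
#' @export
effect_spec <- function(centers, radius_mm, d) {
  centers <- if (is.matrix(centers)) centers else matrix(centers, ncol = 3)
  nb <- nrow(centers)
  radius_mm <- rep_len(as.numeric(radius_mm), nb)
  d <- rep_len(as.numeric(d), nb)
  if (any(radius_mm <= 0)) stop_invalid("blob radii must be positive")
  structure(list(centers = centers, radius_mm = radius_mm, d = d),
            class = "effect_spec")
}

# Printed per-group clinical moments of the study cohort (mean, sd) and
# gender counts; used as the generator's defaults.
default_clinical_moments <- function() {
  list(
    MRP = list(age = c(61.0, 7.0), pre_vas = c(6.9, 1.1),
               post_vas = c(6.9, 1.5), pre_psqi = c(8.9, 3.7),
               post_psqi = c(7.4, 3.9), males = 8L, females = 6L),
    MSP = list(age = c(62.6, 8.3), pre_vas = c(6.1, 1.4),
               post_vas = c(2.4, 0.6), pre_psqi = c(8.4, 5.7),
               post_psqi = c(3.7, 1.6), males = 5L, females = 10L)
  )
}

#' Synthetic cohort specification
#'
#' Describes the world the generator draws from: two groups of smoothed,
#' spatially correlated gray-matter-like maps with localized group-difference
#' blobs, plus clinical covariates matched to stated per-group moments.
#'
#' @param n1,n2 Subjects in group 1 (MRP) and group 2 (MSP); defaults 14/15.
#' @param grid A [volume_grid()].
#' @param baseline_mean,baseline_sd Mean and voxel noise sd of the unsmoothed
#'   GM-volume field (arbitrary modulated-GM units).
#' @param smoothing_fwhm_mm Gaussian smoothing applied to every map
#'   (default 8 mm, the standard VBM kernel).
#' @param effect An [effect_spec()] or `NULL` for a null cohort.
#' @param clinical Per-group clinical moments; see
#'   `slpattern:::default_clinical_moments()` for the layout and defaults.
#' @param vas_coupling If non-zero, each subject's post-treatment VAS is
#'   shifted by `vas_coupling` times the subject's standardized mean blob
#'   intensity, coupling image effect and clinical response (for correlation
#'   testing; default 0 = independent).
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n1 = 14L, n2 = 15L, grid,
                        baseline_mean = 0.5, baseline_sd = 0.1,
                        smoothing_fwhm_mm = 8, effect = NULL,
                        clinical = default_clinical_moments(),
                        vas_coupling = 0, seed = 1L) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 2L || n2 < 2L) stop_invalid("group sizes must be at least 2")
  if (baseline_sd < 0) stop_invalid("baseline_sd must be non-negative")
  if (smoothing_fwhm_mm < 0) stop_invalid("smoothing fwhm must be >= 0")
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "effect_spec"))
    for (b in seq_along(effect$radius_mm)) {
      ctr <- effect$centers[b, ]
      if (any(ctr < 1) || any(ctr > grid$shape) ||
          !grid$mask[ctr[1], ctr[2], ctr[3]]) {
        stop_invalid("effect blob %d center (%s) is outside the mask", b,
                     paste(ctr, collapse = ","))
      }
    }
  }
  structure(list(n1 = n1, n2 = n2, grid = grid,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 smoothing_fwhm_mm = smoothing_fwhm_mm, effect = effect,
                 clinical = clinical, vas_coupling = vas_coupling,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Factor by which separable Gaussian smoothing shrinks the sd of iid voxel
# noise: prod over axes of sqrt(sum(w^2)) with the same truncated normalized
# kernel the filter uses.
smoothed_noise_factor <- function(grid, fwhm_mm) {
  if (fwhm_mm <= 0) return(1)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / grid$voxel_size
  prod(vapply(sigma_vox, function(s) {
    r <- as.integer(4 * s + 0.5)
    w <- exp(-0.5 * ((-r:r) / s)^2)
    w <- w / sum(w)
    sqrt(sum(w^2))
  }, numeric(1)))
}

# indicator of the union of effect blobs (unsmoothed hard spheres)
effect_indicator <- function(effect, grid) {
  ind <- array(0, dim = grid$shape)
  if (is.null(effect)) return(ind)
  for (b in seq_along(effect$radius_mm)) {
    off <- sphere_offsets(effect$radius_mm[b], grid$voxel_size)
    mem <- in_mask_sphere(effect$centers[b, ], off, grid)
    ind[mem] <- ind[mem] + effect$d[b]
  }
  ind
}

#' Support of the smoothed effect
#'
#' The set of voxels where the smoothed blob indicator reaches at least
#' `threshold` of its own maximum — the soft-edged region a recovered cluster
#' is scored against (via Dice overlap).
#'
#' @param spec A [cohort_spec()] with a non-null effect.
#' @param threshold Fraction of the smoothed indicator's maximum
#'   (default 0.5, an FWHM-style support).
#' @return Logical array over the grid.
#' @export
effect_support <- function(spec, threshold = 0.5) {
  ind <- abs(effect_indicator(spec$effect, spec$grid))
  sm <- smooth_volume(ind, spec$grid, spec$smoothing_fwhm_mm)
  sm >= threshold * max(sm) & sm > 0
}

# Truncated-normal sampler calibrated so the *truncated* distribution has the
# requested mean/sd (the printed summaries are moments of data already inside
# the plausible range, so naive clipping would deflate the sd; the age range
# in particular sits asymmetrically around its mean). The parent (mu, sigma)
# is solved from the truncated-moment equations, then sampling is exact
# inverse-CDF.
truncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  tn_moments <- function(mu, sigma) {
    a <- (lower - mu) / sigma
    b <- (upper - mu) / sigma
    Z <- pnorm(b) - pnorm(a)
    da <- stats::dnorm(a)
    db <- stats::dnorm(b)
    m <- mu + sigma * (da - db) / Z
    v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mom <- tn_moments(par[1], exp(par[2]))
    if (any(!is.finite(mom))) return(1e10)
    (mom[1] - mean)^2 + (mom[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj)
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  plo <- pnorm((lower - mu) / sigma)
  phi <- pnorm((upper - mu) / sigma)
  qnorm(plo + stats::runif(n) * (phi - plo)) * sigma + mu
}

#' Generate a synthetic cohort
#'
#' Per subject: a baseline plus independent Gaussian voxel noise, group-1
#' subjects shifted inside each effect blob so the smoothed maps carry the
#' stated peak Cohen's d, then smoothed at the spec FWHM (which induces the
#' spatial correlation of real VBM maps) and masked. Clinical columns are
#' drawn from truncated normals calibrated so the *truncated* moments equal
#' the stated ones (ages on a plausible 40-95 range, VAS on 0-10, PSQI on
#' 0-21); gender gets exact per-group counts in shuffled order. The result
#' is a pure function of the spec, including its seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` object: list with `subjects` (data.frame: id, group,
#'   age, gender, pre_vas, post_vas, pre_psqi, post_psqi), `volumes`
#'   (4D array, subject last) and `grid`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- spec$grid
  n <- spec$n1 + spec$n2
  groups <- rep(c("MRP", "MSP"), c(spec$n1, spec$n2))
  # The blob shift is added before smoothing (smoothing then soft-edges it),
  # but d is the *realized* peak Cohen's d of the smoothed group difference
  # against the smoothed between-subject noise sd: the shift amplitude
  # compensates both the noise-sd shrinkage of the filter and the blob-edge
  # attenuation of the smoothed indicator.
  signal <- effect_indicator(spec$effect, grid)
  if (any(signal != 0)) {
    smoothed_peak <- max(abs(smooth_volume(signal, grid,
                                           spec$smoothing_fwhm_mm)))
    target_peak <- max(abs(spec$effect$d)) * spec$baseline_sd *
      smoothed_noise_factor(grid, spec$smoothing_fwhm_mm)
    signal <- signal * (target_peak / smoothed_peak)
  }

  with_seed(spec$seed, {
    vols <- array(0, dim = c(grid$shape, n))
    blob_mean <- numeric(n)
    blob_vox <- which(signal != 0)
    for (s in seq_len(n)) {
      field <- array(rnorm(prod(grid$shape), spec$baseline_mean,
                           spec$baseline_sd), dim = grid$shape)
      if (groups[s] == "MRP") field <- field + signal
      field <- smooth_volume(field, grid, spec$smoothing_fwhm_mm)
      field[!grid$mask] <- 0
      vols[, , , s] <- field
      if (length(blob_vox)) blob_mean[s] <- mean(field[blob_vox])
    }

    subjects <- do.call(rbind, lapply(c("MRP", "MSP"), function(g) {
      m <- spec$clinical[[g]]
      ng <- if (g == "MRP") spec$n1 else spec$n2
      gender <- sample(rep(c("M", "F"),
                           round(c(m$males, m$females) *
                                 ng / (m$males + m$females))))
      gender <- rep_len(gender, ng) # guard vs rounding of scaled counts
      data.frame(
        group = g,
        # plausible elderly-cohort range; the study inclusion window
        # (55-79) cannot carry the printed sd 7 in a truncated family
        age = round(truncnorm(ng, m$age[1], m$age[2], 40, 95), 1),
        gender = gender,
        pre_vas = round(truncnorm(ng, m$pre_vas[1], m$pre_vas[2], 0, 10), 1),
        post_vas = round(truncnorm(ng, m$post_vas[1], m$post_vas[2], 0, 10), 1),
        pre_psqi = round(truncnorm(ng, m$pre_psqi[1], m$pre_psqi[2], 0, 21), 1),
        post_psqi = round(truncnorm(ng, m$post_psqi[1], m$post_psqi[2],
                                    0, 21), 1),
        stringsAsFactors = FALSE
      )
    }))
    if (spec$vas_coupling != 0 && length(blob_vox)) {
      z <- (blob_mean - mean(blob_mean)) / stats::sd(blob_mean)
      subjects$post_vas <- pmin(pmax(
        subjects$post_vas + spec$vas_coupling * z, 0), 10)
    }
    subjects <- cbind(id = sprintf("S%02d", seq_len(n)), subjects)
    rownames(subjects) <- NULL
    structure(list(subjects = subjects, volumes = vols, grid = grid,
                   spec = spec),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), grid %s\n",
              nrow(x$subjects),
              paste(table(x$subjects$group), collapse = "/"),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Treatment response of pain intensity
#'
#' `delta_vas` is the pre-scanning VAS minus the post-treatment VAS; positive
#' values mean pain relief.
#'
#' @param pre_vas,post_vas Scores on the 10-point visual analog scale.
#' @return `pre_vas - post_vas`.
#' @export
delta_vas <- function(pre_vas, post_vas) {
  if (any(!is.finite(pre_vas)) || any(!is.finite(post_vas)) ||
      any(pre_vas < 0 | pre_vas > 10) || any(post_vas < 0 | post_vas > 10)) {
    stop_invalid("VAS scores must lie in [0, 10]")
  }
  pre_vas - post_vas
}

#' Write a cohort to disk
#'
#' Volumes as one 4D NIfTI (subject order = table order), the mask as a 3D
#' NIfTI, and the subject table as CSV.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(volumes = file.path(dir, "volumes.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"),
             subjects = file.path(dir, "subjects.csv"))
  write_volume(cohort$volumes, cohort$grid, paths[["volumes"]])
  write_volume(array(as.numeric(cohort$grid$mask), dim = cohort$grid$shape),
               cohort$grid, paths[["mask"]])
  write.csv(cohort$subjects, paths[["subjects"]], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort from disk
#'
#' @param volumes_path 4D NIfTI of subject maps.
#' @param mask_path 3D NIfTI mask (non-zero = in mask).
#' @param subjects_path Subject table CSV as written by [write_cohort()].
#' @return A `cohort` object.
#' @export
read_cohort <- function(volumes_path, mask_path, subjects_path) {
  msk <- read_volume(mask_path)
  vols <- read_volume(volumes_path)
  grid <- volume_grid(msk$grid$shape, msk$grid$voxel_size, msk$grid$affine,
                      mask = msk$data != 0)
  subjects <- read.csv(subjects_path, stringsAsFactors = FALSE)
  if (length(dim(vols$data)) != 4L ||
      dim(vols$data)[4] != nrow(subjects)) {
    stop_invalid("subject table (%d rows) does not match 4D volume count",
                 nrow(subjects))
  }
  structure(list(subjects = subjects, volumes = vols$data, grid = grid,
                 spec = NULL),
            class = "cohort")
}
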