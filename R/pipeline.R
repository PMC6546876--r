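#' Derive a stage seed from the global seed
#'
#' Stage seeds are a deterministic function of the global seed and the stage
#' name, so any stage can be re-run in isolation with identical results.
#' The derivation is `(seed * 97 + stage index) mod (2^31 - 1)`, with stages
#' indexed in pipeline order.
#'
#' @param seed Global integer seed.
#' @param stage One of `"cohort"`, `"permutation"`, `"mc_extent"`.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(cohort = 1L, permutation = 2L, mc_extent = 3L)
  if (!stage %in% names(stages)) stop_invalid("unknown stage '%s'", stage)
  as.integer((as.double(seed) * 97 + stages[[stage]]) %% (2^31 - 1))
}

#' Pipeline configuration
#'
#' One place for every analysis constant, with the published procedure's
#' values as defaults: 5-mm searchlight, voxel-wise p < 1e-4 with 50-voxel
#' 18-connected clusters, 1000 label permutations at alpha 0.05, post-hoc
#' voxel p < 0.01 with a Monte-Carlo extent threshold at alpha 0.05 under
#' 8-mm smoothness.
#'
#' @param input A [cohort_spec()] (synthetic source) or a list with
#'   `volumes`, `mask`, `subjects` file paths (NIfTI/CSV source).
#' @param radius_mm Searchlight radius.
#' @param svm An [svm_config()].
#' @param inference An [inference_config()].
#' @param posthoc_voxel_p,posthoc_alpha,posthoc_fwhm_mm,mc_iterations
#'   Post-hoc correction settings.
#' @param regress_covariates Character vector of covariate columns to
#'   regress out of the voxel values before classification (default none).
#' @param spearman_group Group whose cluster-mean GM is correlated with
#'   delta-VAS (default `"MSP"`).
#' @param seed Global seed; stage seeds derive from it via [derive_seed()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input, radius_mm = 5, svm = svm_config(),
                            inference = inference_config(),
                            posthoc_voxel_p = 0.01, posthoc_alpha = 0.05,
                            posthoc_fwhm_mm = 8, mc_iterations = 1000L,
                            regress_covariates = character(),
                            spearman_group = "MSP", seed = 1L) {
  structure(list(input = input, radius_mm = radius_mm, svm = svm,
                 inference = inference, posthoc_voxel_p = posthoc_voxel_p,
                 posthoc_alpha = posthoc_alpha,
                 posthoc_fwhm_mm = posthoc_fwhm_mm,
                 mc_iterations = as.integer(mc_iterations),
                 regress_covariates = regress_covariates,
                 spearman_group = spearman_group, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full searchlight analysis pipeline
#'
#' Generate or load the cohort, sweep the searchlight, convert accuracy to
#' binomial p-values, extract and permutation-test clusters, run the
#' covariate-adjusted post-hoc comparison with Monte-Carlo extent
#' correction, correlate cluster mean GM with delta-VAS, and tabulate the
#' clinical comparison. Identical config and seed give an identical report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, maps are written as NIfTI,
#'   tables as CSV and the report as JSON.
#' @param verbose Print per-stage progress.
#' @return A `pipeline_report` list with all stage outputs.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  if (inherits(config$input, "cohort_spec")) {
    spec <- config$input
    spec$seed <- derive_seed(config$seed, "cohort")
    cohort <- generate_cohort(spec)
    say("cohort: generated %d subjects on %s grid", nrow(cohort$subjects),
        paste(cohort$grid$shape, collapse = "x"))
  } else if (inherits(config$input, "cohort")) {
    cohort <- config$input
  } else {
    cohort <- read_cohort(config$input$volumes, config$input$mask,
                          config$input$subjects)
    say("cohort: loaded %d subjects", nrow(cohort$subjects))
  }

  covars <- if (length(config$regress_covariates)) {
    cohort$subjects[config$regress_covariates]
  } else {
    NULL
  }
  acc <- searchlight_map(cohort, radius_mm = config$radius_mm,
                         config = config$svm, covariates = covars)
  say("searchlight: %d mask voxels, mean accuracy %.3f",
      sum(!is.na(acc$accuracy)), mean(acc$accuracy, na.rm = TRUE))

  pmap <- accuracy_to_pmap(acc)
  clusters <- label_clusters(pmap, config$inference)
  say("inference: %d cluster(s) at p < %g, extent >= %d",
      nrow(clusters$clusters), config$inference$voxel_alpha,
      config$inference$min_size)
  clusters <- permutation_test_clusters(
    clusters, cohort, config$svm,
    n_perm = config$inference$n_permutations,
    seed = derive_seed(config$seed, "permutation"))

  posthoc <- NULL
  if (nrow(clusters$clusters) > 0) {
    tmap <- glm_tmap(cohort, covariates = cohort$subjects[c("age", "gender")],
                     restrict_to = clusters)
    extent <- mc_extent_threshold(
      cohort$grid, voxel_p = config$posthoc_voxel_p,
      alpha = config$posthoc_alpha, fwhm_mm = config$posthoc_fwhm_mm,
      n_iterations = config$mc_iterations,
      connectivity = config$inference$connectivity,
      seed = derive_seed(config$seed, "mc_extent"))
    surviving <- apply_correction(tmap, extent,
                                  voxel_p = config$posthoc_voxel_p,
                                  connectivity = config$inference$connectivity)
    say("posthoc: extent threshold %d voxels, %d surviving cluster(s)",
        as.integer(extent), nrow(surviving))
    grp <- cohort$subjects$group == config$spearman_group
    spearman <- lapply(seq_along(clusters$members), function(i) {
      gm <- cluster_mean_gm(cohort, clusters$members[[i]], which(grp))
      dv <- delta_vas(cohort$subjects$pre_vas[grp],
                      cohort$subjects$post_vas[grp])
      c(cluster = i, spearman_cluster_dvas(gm, dv))
    })
    posthoc <- list(tmap = tmap, extent_threshold = as.integer(extent),
                    surviving = surviving, spearman = spearman)
  } else {
    say("posthoc: skipped (no MVPA clusters)")
  }

  table1 <- clinical_table(
    cohort$subjects,
    measures = intersect(c("age", "pre_vas", "post_vas", "pre_psqi",
                           "post_psqi"), names(cohort$subjects)))

  report <- structure(list(
    cohort = cohort, accuracy_map = acc, p_map = pmap, clusters = clusters,
    posthoc = posthoc, clinical_table = table1,
    provenance = list(
      seed = config$seed,
      stage_seeds = list(cohort = derive_seed(config$seed, "cohort"),
                         permutation = derive_seed(config$seed, "permutation"),
                         mc_extent = derive_seed(config$seed, "mc_extent")),
      radius_mm = config$radius_mm,
      voxel_alpha = config$inference$voxel_alpha,
      min_size = config$inference$min_size,
      connectivity = config$inference$connectivity,
      n_permutations = config$inference$n_permutations,
      package_version = as.character(utils::packageVersion("slpattern")))),
    class = "pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  say("pipeline: done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  report
}

report_json <- function(report) {
  list(
    provenance = report$provenance,
    n_subjects = nrow(report$cohort$subjects),
    mask_voxels = sum(report$cohort$grid$mask),
    mean_accuracy = mean(report$accuracy_map$accuracy, na.rm = TRUE),
    clusters = report$clusters$clusters,
    posthoc = if (is.null(report$posthoc)) NULL else list(
      extent_threshold = report$posthoc$extent_threshold,
      surviving = report$posthoc$surviving,
      spearman = lapply(report$posthoc$spearman, function(s) {
        s[c("cluster", "rho", "p", "n")]
      })),
    clinical_table = report$clinical_table)
}

#' Write pipeline artifacts
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- report$cohort$grid
  paths <- c(accuracy = file.path(dir, "accuracy.nii.gz"),
             pmap = file.path(dir, "pmap.nii.gz"),
             labels = file.path(dir, "clusters.nii.gz"),
             table1 = file.path(dir, "clinical_table.csv"),
             report = file.path(dir, "report.json"))
  write_volume(report$accuracy_map$accuracy, grid, paths[["accuracy"]])
  write_volume(report$p_map$p, grid, paths[["pmap"]])
  write_volume(array(as.numeric(report$clusters$labels), dim = grid$shape),
               grid, paths[["labels"]])
  write.csv(report$clinical_table, paths[["table1"]], row.names = FALSE)
  jsonlite::write_json(report_json(report), paths[["report"]],
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, %d MVPA cluster(s)%s\n",
              nrow(x$cohort$subjects), nrow(x$clusters$clusters),
              if (is.null(x$posthoc)) "" else
                sprintf(", %d surviving post-hoc", nrow(x$posthoc$surviving))))
  invisible(x)
}
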