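#' Run the full alignment pipeline on a cohort
#'
#' Orchestrates the analysis stages in order: per-clip ISC (pre and post),
#' change matrices, the group-membership change regression with subject-wise
#' permutation inference, cluster-extent correction, directed neural
#' influence and its centrality regression, whole-brain alignment and
#' influence summaries, network centrality, and the behavioral survey model.
#' The run is a pure function of `(cohort, config)`: the same inputs and
#' seed give byte-identical summary tables.
#'
#' @param cohort a `synthetic_cohort` or the result of [load_cohort()].
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, summary tables are written
#'   as CSV, beta/p maps as NIfTI, and a markdown report with provenance
#'   (config hash, seed) is produced.
#' @param verbose print per-stage progress.
#' @return list (class `pipeline_result`): `isc_pre`, `isc_post`, `change`,
#'   `change_fit`, `change_perm`, `clusters`, `influence`, `influence_fit`,
#'   `whole_brain_alignment`, `whole_brain_influence`, `centrality`,
#'   `survey_model`, `config`, `config_hash`.
#' @export
run_full_pipeline <- function(cohort, config = run_config(),
                              out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[neuralign] ", ...)
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(name, " done in ",
        sprintf("%.2fs", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }
  labels <- cohort$bold_pre[[1]]$group_labels
  clips <- seq_along(cohort$bold_pre)

  isc_pre <- stage("isc_pre", lapply(cohort$bold_pre, isc_matrix,
                                     session_tag = "pre",
                                     fisher_z = config$fisher_z))
  isc_post <- stage("isc_post", lapply(cohort$bold_post, isc_matrix,
                                       session_tag = "post",
                                       fisher_z = config$fisher_z))
  change <- stage("change", Map(change_stack, isc_pre, isc_post))

  design <- build_design(labels, mode = config$mode, clips = clips,
                         subject_ids = cohort$bold_pre[[1]]$subject_ids)
  change_fit <- stage("change_fit", fit_pairwise_regression(change, design))
  change_perm <- stage("change_perm", subjectwise_permutation(
    change, design, n_perm = config$n_perm, seed = config$seed,
    smoothing = config$smoothing,
    keep_null = config$cluster_null == "max_cluster"))
  clusters <- stage("clusters", cluster_correct(
    change_fit, change_perm, cluster_forming_p = config$cluster_p,
    min_size = config$min_cluster, connectivity = config$connectivity,
    null = config$cluster_null, seed = config$seed))

  influence <- stage("influence",
                     Map(influence_stack, cohort$bold_pre, cohort$bold_post))
  centrality <- stage("centrality", centrality_table(
    cohort$network, mode = config$centrality_mode,
    ties = config$constraint_ties))
  cent_named <- setNames(centrality$pca_centrality, centrality$node)
  inf_design <- centrality_design(
    labels, cent_named[cohort$bold_pre[[1]]$subject_ids], clips = clips,
    subject_ids = cohort$bold_pre[[1]]$subject_ids)
  influence_fit <- stage("influence_fit",
                         fit_influence_regression(influence, inf_design))

  wba <- stage("whole_brain_alignment", whole_brain_alignment(change))
  wbi <- stage("whole_brain_influence", whole_brain_influence(influence))

  survey_model <- NULL
  if (!is.null(cohort$surveys_pre))
    survey_model <- stage("survey_model", survey_session_model(
      cohort$surveys_pre, cohort$surveys_post, labels,
      n_perm = config$survey_n_perm, seed = config$seed))

  res <- structure(list(isc_pre = isc_pre, isc_post = isc_post,
                        change = change, change_fit = change_fit,
                        change_perm = change_perm, clusters = clusters,
                        influence = influence,
                        influence_fit = influence_fit,
                        whole_brain_alignment = wba,
                        whole_brain_influence = wbi,
                        centrality = centrality,
                        survey_model = survey_model,
                        config = config, config_hash = config_hash(config)),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  say("pipeline done in ",
      sprintf("%.2fs", as.numeric(Sys.time() - t_all, units = "secs")))
  res
}

#' Summary tables of a pipeline run
#'
#' Deterministic, text-serializable tables used for reporting and for the
#' byte-identity reproducibility check: cluster table, per-voxel betas and
#' p-values, whole-brain alignment and influence, centrality, and the
#' survey-model coefficients.
#'
#' @param result a `pipeline_result`.
#' @return named list of data.frames.
#' @export
pipeline_tables <- function(result) {
  drop_list_cols <- function(d) d[!vapply(d, is.list, logical(1))]
  tabs <- list(
    clusters = drop_list_cols(result$clusters),
    change_betas = data.frame(voxel = seq_len(nrow(result$change_fit$betas)),
                              result$change_fit$betas,
                              check.names = FALSE),
    change_p = data.frame(voxel = seq_len(nrow(result$change_perm$p)),
                          result$change_perm$p, check.names = FALSE),
    whole_brain_alignment = result$whole_brain_alignment,
    whole_brain_influence = result$whole_brain_influence,
    centrality = result$centrality)
  if (!is.null(result$survey_model))
    tabs$survey_coefficients <- result$survey_model$coefficients
  tabs
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- pipeline_tables(result)
  for (nm in names(tabs))
    write.csv(tabs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  grid <- result$change_fit$grid
  if (!is.null(grid)) {
    for (k in seq_along(result$change_fit$predictors)) {
      pr <- gsub("[^a-zA-Z0-9]+", "_", result$change_fit$predictors[k])
      RNifti::writeNifti(
        RNifti::asNifti(array(result$change_fit$betas[, k], dim = grid)),
        file.path(out_dir, paste0("beta_", pr, ".nii.gz")))
      RNifti::writeNifti(
        RNifti::asNifti(array(result$change_perm$p[, k], dim = grid)),
        file.path(out_dir, paste0("p_", pr, ".nii.gz")))
    }
  }
  lines <- c("# neuralign pipeline report", "",
             paste0("- config hash: ", result$config_hash),
             paste0("- seed: ", result$config$seed),
             paste0("- permutations: ", result$config$n_perm),
             paste0("- significant clusters: ", nrow(result$clusters)),
             "", "## Cluster table", "",
             if (nrow(result$clusters)) {
               utils::capture.output(print(
                 pipeline_tables(result)$clusters, row.names = FALSE))
             } else "(none at the corrected threshold)")
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (config", x$config_hash, "):",
      length(x$change), "clip(s),", nrow(x$clusters),
      "significant cluster(s)\n")
  invisible(x)
}
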