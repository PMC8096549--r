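#' Pipeline configuration
#'
#' Collects every stage's options and the global seed. With
#' `mask_method = "template"` the network mask is the supplied (or
#' ground-truth) template and BOLD simulation can be restricted to region
#' voxels (`active = "regions"`), which is statistically identical
#' downstream of a fixed mask; with `"ica"` full-grid runs are simulated
#' and the mask is built by group ICA plus template matching.
#'
#' @param cohort a [cohort_spec()].
#' @param preprocess a [preprocess_config()].
#' @param mask_method `"template"` or `"ica"`.
#' @param n_components ICA component count (ICA mask only).
#' @param z_threshold,match_threshold mask binarization and component-match
#'   thresholds (ICA mask only).
#' @param voxel_p,cluster_p,connectivity GRF inference settings.
#' @param covariates GLM covariate column names.
#' @param scores clinical scores entered into the correlation analysis.
#' @param classify_max_size largest feature-combination size searched.
#' @param active BOLD simulation mode; NULL picks `"regions"` for the
#'   template mask and `"all"` for ICA.
#' @param seed global seed fanned out per stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            preprocess = preprocess_config(),
                            mask_method = c("template", "ica"),
                            n_components = 20L, z_threshold = 1,
                            match_threshold = 0.3,
                            voxel_p = 0.001, cluster_p = 0.05,
                            connectivity = 26L,
                            covariates = c("age", "education", "mean_fd"),
                            scores = c("hrsd17", "bai", "shapsc",
                                       "teps_total",
                                       "teps_abstract_anticipatory",
                                       "teps_contextual_anticipatory",
                                       "teps_abstract_consummatory",
                                       "teps_contextual_consummatory"),
                            classify_max_size = 2L, active = NULL,
                            seed = 1L) {
  mask_method <- match.arg(mask_method)
  active <- active %||% if (mask_method == "template") "regions" else "all"
  structure(list(cohort = cohort, preprocess = preprocess,
                 mask_method = mask_method, n_components = n_components,
                 z_threshold = z_threshold,
                 match_threshold = match_threshold, voxel_p = voxel_p,
                 cluster_p = cluster_p, connectivity = connectivity,
                 covariates = covariates, scores = scores,
                 classify_max_size = classify_max_size, active = active,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full NH analysis pipeline
#'
#' simulate -> preprocess (with motion exclusion) -> network mask ->
#' NH maps (smoothed) -> ANCOVA + pairwise t with GRF cluster correction ->
#' clinical comparisons and NH-symptom correlations -> leave-one-out SVM
#' over cluster-NH feature combinations. Subjects failing the motion rule
#' are dropped from every downstream stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for cluster tables and a JSON summary.
#' @return list of class `nh_pipeline` with elements `subjects` (retained,
#'   with mean FD), `qc`, `mask`, `stack`, `ancova`, `contrasts` (named
#'   cluster reports), `clinical`, `correlations`, `classification`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  spec <- config$cohort
  spec$seed <- stage_seed(config$seed, "cohort")
  cohort <- generate_cohort(spec, active = config$active,
                            coupling_preprocess = config$preprocess)

  # --- preprocessing + motion QC -------------------------------------------
  kept <- list()
  qc_rows <- list()
  tissue <- default_tissue_masks(spec$grid_shape)
  for (s in cohort$subjects) {
    pp <- preprocess_run(s$bold, s$motion, config$preprocess, tissue)
    qc_rows[[s$subject_id]] <- dplyr::mutate(pp$qc, subject_id = s$subject_id,
                                             group = s$group)
    if (!pp$qc$keep) next
    s$bold <- pp$run
    s$mean_fd <- pp$qc$mean_fd
    kept[[s$subject_id]] <- s
  }
  qc <- dplyr::bind_rows(qc_rows)
  subjects <- cohort$table[match(names(kept), cohort$table$subject_id), ]
  subjects$mean_fd <- vapply(kept, `[[`, numeric(1), "mean_fd")
  groups <- vapply(kept, `[[`, character(1), "group")
  if (any(table(groups) < 2))
    abort("stage inference: fewer than 2 retained subjects in a group")

  # --- network mask ---------------------------------------------------------
  template <- cohort_template(spec)
  if (config$mask_method == "ica") {
    ica <- group_ica(lapply(kept, `[[`, "bold"), config$n_components,
                     seed = stage_seed(config$seed, "ica"))
    sel <- select_dmn_components(ica, template, config$match_threshold)
    mask <- build_mask(ica, sel, groups = unname(groups),
                       z_threshold = config$z_threshold)
    mask$region_labels <- template$region_labels
    mask$region_names <- template$region_names
  } else {
    mask <- template
  }

  # --- NH maps --------------------------------------------------------------
  maps <- purrr::imap(kept, function(s, id) {
    m <- compute_nh(s$bold, mask, subject_id = id)
    smooth_nh(m, config$preprocess$fwhm_mm)
  })
  stack <- nh_stack(unname(maps))

  # --- group inference ------------------------------------------------------
  gl <- names(spec$group_sizes)
  ancova_fit <- voxelwise_glm(stack, subjects, config$covariates)
  smooth_est <- estimate_smoothness(ancova_fit$residuals, mask)
  ancova_clusters <- grf_cluster_correct(ancova_fit, smooth_est,
                                         config$voxel_p, config$cluster_p,
                                         config$connectivity)
  pairs <- list(c(gl[1], gl[3]), c(gl[2], gl[3]), c(gl[1], gl[2]))
  contrasts <- list()
  for (pr in pairs) {
    fit <- voxelwise_glm(stack, subjects, config$covariates, contrast = pr)
    sm <- estimate_smoothness(fit$residuals, mask)
    cl <- grf_cluster_correct(fit, sm, config$voxel_p, config$cluster_p,
                              config$connectivity)
    contrasts[[paste(pr, collapse = "_vs_")]] <-
      list(clusters = cl, report = cluster_report(cl, spec$affine, template))
  }

  # --- clinical comparisons and correlations --------------------------------
  clin_cols <- intersect(c("subject_id", "group", "sex", "age", "education",
                           "illness_duration", config$scores, "mean_fd"),
                         names(subjects))
  clinical <- summarize_clinical(subjects[, clin_cols],
                                 patient_groups = gl[1:2])
  correlations <- list()
  for (pg in gl[1:2]) {
    cl <- contrasts[[paste0(pg, "_vs_", gl[3])]]$clusters
    if (!nrow(cl)) next
    idx <- which(subjects$group == pg)
    cluster_nh <- tibble::tibble(
      cluster = paste0("c", cl$cluster),
      nh = lapply(cl$voxels, function(v)
        extract_cluster_nh(stack, v)[idx]))
    correlations[[pg]] <- nh_score_correlations(
      cluster_nh, subjects[idx, ], config$scores)
  }

  # --- classification -------------------------------------------------------
  classification <- NULL
  mm_cl <- contrasts[[paste0(gl[1], "_vs_", gl[2])]]
  if (nrow(mm_cl$clusters)) {
    pat <- which(subjects$group %in% gl[1:2])
    feat_names <- ifelse(is.na(mm_cl$report$location),
                         paste0("c", mm_cl$clusters$cluster),
                         mm_cl$report$location)
    feats <- vapply(mm_cl$clusters$voxels, function(v)
      extract_cluster_nh(stack, v)[pat], numeric(length(pat)))
    colnames(feats) <- make.unique(feat_names)
    set.seed(stage_seed(config$seed, "classify"))
    classification <- enumerate_combinations(
      feats, subjects$group[pat],
      max_size = config$classify_max_size, positive = gl[1])
  }

  out <- structure(list(subjects = subjects, qc = qc, mask = mask,
                        stack = stack, ancova = list(fit = ancova_fit,
                                                     clusters = ancova_clusters,
                                                     smoothness = smooth_est),
                        contrasts = contrasts, clinical = clinical,
                        correlations = correlations,
                        classification = classification, config = config),
                   class = "nh_pipeline")
  if (!is.null(out_dir)) write_pipeline_summary(out, out_dir)
  out
}

write_pipeline_summary <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("cannot create output directory '%s'", out_dir))
  for (nm in names(result$contrasts))
    readr::write_tsv(result$contrasts[[nm]]$report,
                     file.path(out_dir, paste0("clusters_", nm, ".tsv")))
  summary <- list(
    seed = result$config$seed,
    n_retained = as.list(table(result$subjects$group)),
    n_excluded = sum(!result$qc$keep),
    clusters = lapply(result$contrasts, function(x) nrow(x$clusters)),
    best_combination = if (!is.null(result$classification))
      result$classification$combination[result$classification$best])
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.nh_pipeline <- function(x, ...) {
  cat("<nh_pipeline>\n")
  cat("  retained subjects:",
      paste(sprintf("%s=%d", names(table(x$subjects$group)),
                    table(x$subjects$group)), collapse = ", "), "\n")
  cat("  excluded for motion:", sum(!x$qc$keep), "\n")
  for (nm in names(x$contrasts))
    cat(sprintf("  %s: %d cluster(s)\n", nm, nrow(x$contrasts[[nm]]$clusters)))
  if (!is.null(x$classification))
    cat("  best combination:",
        x$classification$combination[x$classification$best],
        sprintf("(%.2f%% accuracy)\n",
                x$classification$accuracy[x$classification$best]))
  invisible(x)
}
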