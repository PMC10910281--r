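#' Full-analysis run configuration
#'
#' Bundles every setting of the end-to-end analysis. Defaults mirror the
#' published protocol: voxels damaged in at least 10 subjects enter the
#' multivariate mapping and at least 5 the Bayesian mapping; FDR at
#' `q = 0.1`; 10,000 permutations; Bayes-factor cuts 3, 1/3 and 50.
#'
#' Exactly one input mode is used: a simulation scenario (`n_subjects`,
#' `territory`, `truth`) or file paths (`lesion_paths`, `behaviour_path`).
#'
#' @param n_subjects cohort size for the simulation scenario.
#' @param territory a [territory_model()] for the simulation scenario.
#' @param truth optional [simulation_truth()]; default built by
#'   [default_truth()].
#' @param lesion_paths character vector of NIfTI lesion files (file mode).
#' @param behaviour_path behaviour CSV (file mode; columns `subject_id`,
#'   `ext_score`, `coc`, optional `ext_index`).
#' @param min_overlap_svr,min_overlap_bldi voxel overlap thresholds.
#' @param svr an [svr_config()].
#' @param run_grid_search if TRUE, select `C`/`gamma` by [grid_search()]
#'   before the permutation test; otherwise use `svr$C`, `svr$gamma`.
#' @param bf_h1_cut,bf_h0_cut,bf_peak_cut Bayes-factor category and peak
#'   thresholds.
#' @param rois named list of probabilistic ROI arrays to summarise (optional).
#' @param min_cluster_voxels,min_region_voxels cluster-table suppression
#'   thresholds.
#' @param seed master seed.
#' @export
run_config <- function(n_subjects = 108L, territory = territory_model(),
                       truth = NULL, lesion_paths = NULL,
                       behaviour_path = NULL,
                       min_overlap_svr = 10L, min_overlap_bldi = 5L,
                       svr = svr_config(), run_grid_search = FALSE,
                       bf_h1_cut = 3, bf_h0_cut = 1 / 3, bf_peak_cut = 50,
                       rois = list(),
                       min_cluster_voxels = 100L, min_region_voxels = 15L,
                       seed = 1L) {
  structure(list(n_subjects = n_subjects, territory = territory,
                 truth = truth, lesion_paths = lesion_paths,
                 behaviour_path = behaviour_path,
                 min_overlap_svr = as.integer(min_overlap_svr),
                 min_overlap_bldi = as.integer(min_overlap_bldi),
                 svr = svr, run_grid_search = run_grid_search,
                 bf_h1_cut = bf_h1_cut, bf_h0_cut = bf_h0_cut,
                 bf_peak_cut = bf_peak_cut, rois = rois,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 min_region_voxels = as.integer(min_region_voxels),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the complete lesion-symptom analysis
#'
#' Sequences scoring (assessability screen, nuisance regression), SVR-based
#' lesion-symptom mapping (optional grid search, permutation inference, FDR
#' thresholding, cluster table) and Bayesian lesion-deficit inference
#' (Bayes-factor map with CoC covariate, categories, peak map, ROI
#' summaries). Each stage failure aborts with a stage-named error. With a
#' fixed seed the run is fully reproducible.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, maps (NIfTI),
#'   tables (CSV) and a JSON run manifest with file checksums are written.
#' @return A list of class `run_result` with elements `behaviour`,
#'   `regression`, `svr` (beta/p maps, fdr, clusters, optionally grid) and
#'   `bldi` (bf map, categories, peak, roi summaries), plus `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  stages <- character(0)

  # --- inputs ---------------------------------------------------------------
  inputs <- stage("inputs", {
    if (!is.null(config$lesion_paths)) {
      lesions <- load_lesion_maps(config$lesion_paths)
      behaviour <- read_behaviour_csv(config$behaviour_path)
      if (!all(behaviour$subject_id %in% lesions$subject_ids))
        stop("behaviour table contains subjects without lesion maps")
      if (!"assessable" %in% names(behaviour)) behaviour$assessable <- TRUE
      list(lesions = lesions, behaviour = behaviour)
    } else {
      cohort <- simulate_cohort(config$n_subjects, config$territory,
                                truth = config$truth, seed = config$seed)
      list(lesions = cohort$lesions, behaviour = cohort$behaviour,
           cohort = cohort)
    }
  })
  stages <- c(stages, "inputs")

  # --- scoring --------------------------------------------------------------
  scored <- stage("score", {
    beh <- inputs$behaviour
    excluded <- !beh$assessable | is.na(beh$ext_score)
    if (any(excluded))
      message(sum(excluded), " subject(s) not assessable; excluded")
    beh <- beh[!excluded, , drop = FALSE]
    if (nrow(beh) < 3) stop("fewer than 3 assessable subjects")
    res <- residualize_extinction(beh$ext_score, beh$coc)
    beh$ext_residual <- res$residuals
    keep <- match(beh$subject_id, inputs$lesions$subject_ids)
    lesions <- lesion_dataset(inputs$lesions$masks[keep],
                              subject_ids = beh$subject_id,
                              affine = inputs$lesions$affine)
    list(behaviour = beh, regression = res$summary, lesions = lesions,
         n_excluded = sum(excluded))
  })
  stages <- c(stages, "score")

  # --- SVR-LSM --------------------------------------------------------------
  svr_out <- stage("svrlsm", {
    mask <- build_analysis_mask(scored$lesions, config$min_overlap_svr)
    if (mask$n_included_voxels == 0)
      stop("empty analysis mask at min_overlap = ", config$min_overlap_svr)
    fm <- feature_matrix(scored$lesions, mask)
    y <- scored$behaviour$ext_residual
    cfg <- config$svr
    grid <- NULL
    if (config$run_grid_search) {
      grid <- grid_search(fm$X, y, cfg)
      cfg$C <- grid$selected$C
      cfg$gamma <- grid$selected$gamma
    }
    perm <- permutation_test(fm$X, y, cfg)
    fdr <- fdr_threshold(perm$p, cfg$fdr_q)
    sig_map <- map_to_grid(as.numeric(fdr$significant), mask,
                           kind = "fdr-significant", fill = 0)
    clusters <- cluster_table(sig_map,
                              min_cluster_voxels = config$min_cluster_voxels,
                              min_region_voxels = config$min_region_voxels)
    list(mask = mask, voxels = fm$voxels, grid = grid,
         C = cfg$C, gamma = cfg$gamma,
         beta_map = map_to_grid(perm$beta, mask, kind = "pseudo-beta"),
         p_map = map_to_grid(perm$p, mask, kind = "permutation-p"),
         sig_map = sig_map, fdr = fdr, clusters = clusters)
  })
  stages <- c(stages, "svrlsm")

  # --- BLDI -----------------------------------------------------------------
  bldi_out <- stage("bldi", {
    mask <- build_analysis_mask(scored$lesions, config$min_overlap_bldi)
    if (mask$n_included_voxels == 0)
      stop("empty analysis mask at min_overlap = ", config$min_overlap_bldi)
    fm <- feature_matrix(scored$lesions, mask)
    res <- bldi_map(fm$X, scored$behaviour$ext_score,
                    covariate = scored$behaviour$coc,
                    min_overlap = config$min_overlap_bldi)
    cats <- categorize_bf(res$bf, config$bf_h1_cut, config$bf_h0_cut)
    bf_map <- map_to_grid(res$bf, mask, kind = "bayes-factor")
    # grid-level categories: voxels outside the mask are not-analysed
    grid_cats <- array("not-analysed", dim(mask$included))
    grid_cats[which(mask$included)] <- as.character(cats)
    peak <- map_to_grid(as.numeric(peak_bf_map(res$bf, config$bf_peak_cut)),
                        mask, kind = "bf-peak", fill = 0)
    roi_summaries <- lapply(config$rois, function(roi) {
      roi_bf_summary(grid_cats, threshold_prob_roi(roi, mode = "max-extent"))
    })
    list(mask = mask, bf_map = bf_map, categories = grid_cats,
         peak_map = peak, roi_summaries = roi_summaries)
  })
  stages <- c(stages, "bldi")

  result <- structure(list(behaviour = scored$behaviour,
                           regression = scored$regression,
                           n_excluded = scored$n_excluded,
                           lesions = scored$lesions,
                           svr = svr_out, bldi = bldi_out),
                      class = "run_result")

  # --- report ---------------------------------------------------------------
  manifest <- stage("report", {
    outputs <- character(0)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_behaviour_csv(scored$behaviour,
                          file.path(out_dir, "behaviour.csv"))
      write_stat_map(svr_out$beta_map, file.path(out_dir, "svr_beta.nii.gz"))
      write_stat_map(svr_out$p_map, file.path(out_dir, "svr_p.nii.gz"),
                     fill = 1)
      write_stat_map(svr_out$sig_map,
                     file.path(out_dir, "svr_fdr_significant.nii.gz"))
      write_stat_map(bldi_out$bf_map, file.path(out_dir, "bldi_bf.nii.gz"),
                     fill = 1)
      log_bf <- bldi_out$bf_map
      log_bf$values <- log10(log_bf$values)
      write_stat_map(log_bf, file.path(out_dir, "bldi_log10_bf.nii.gz"))
      write_stat_map(bldi_out$peak_map,
                     file.path(out_dir, "bldi_peak.nii.gz"))
      utils::write.csv(svr_out$clusters$clusters,
                       file.path(out_dir, "svr_clusters.csv"),
                       row.names = FALSE)
      if (!is.null(svr_out$grid))
        utils::write.csv(svr_out$grid$table,
                         file.path(out_dir, "grid_search.csv"),
                         row.names = FALSE)
      outputs <- list.files(out_dir, full.names = TRUE)
    }
    man <- list(
      package_version = as.character(utils::packageVersion("extmap")),
      seed = config$seed,
      settings = list(min_overlap_svr = config$min_overlap_svr,
                      min_overlap_bldi = config$min_overlap_bldi,
                      C = svr_out$C, gamma = svr_out$gamma,
                      epsilon = config$svr$epsilon,
                      n_permutations = config$svr$n_permutations,
                      fdr_q = config$svr$fdr_q,
                      bf_cuts = c(config$bf_h1_cut, config$bf_h0_cut,
                                  config$bf_peak_cut)),
      n_subjects_analysed = nrow(scored$behaviour),
      n_excluded = scored$n_excluded,
      fdr_p_threshold = svr_out$fdr$p_threshold,
      n_significant_voxels = svr_out$fdr$n_significant,
      stages = stages,
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
      outputs = if (length(outputs))
        data.frame(file = basename(outputs),
                   md5 = unname(tools::md5sum(outputs)))
      else NULL)
    if (!is.null(out_dir))
      jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    man
  })
  result$manifest <- manifest
  result
}

#' @export
print.run_result <- function(x, ...) {
  cat("Lesion-symptom analysis of", nrow(x$behaviour), "subjects",
      sprintf("(%d excluded as not assessable)\n", x$n_excluded))
  cat("  nuisance regression: slope", signif(x$regression$slope, 4),
      "R^2", signif(x$regression$r_squared, 3), "\n")
  cat("  SVR-LSM: C =", x$svr$C, "gamma =", x$svr$gamma, "|",
      x$svr$fdr$n_significant, "FDR-significant voxels of",
      x$svr$mask$n_included_voxels, "analysed")
  if (!is.na(x$svr$fdr$p_threshold))
    cat(" (p <=", signif(x$svr$fdr$p_threshold, 3), ")")
  cat("\n")
  bf <- x$bldi$bf_map$values[x$bldi$mask$included]
  cat("  BLDI:", x$bldi$mask$n_included_voxels, "analysed voxels, BF range",
      signif(min(bf, na.rm = TRUE), 3), "-",
      signif(max(bf, na.rm = TRUE), 3), "\n")
  invisible(x)
}
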