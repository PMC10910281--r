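#' SVR-LSM configuration
#'
#' Hyperparameters and inference settings of the multivariate lesion-symptom
#' mapping. Defaults follow the published protocol: candidate grids
#' `C = 1, 10, 20, ..., 80` and `gamma = 0.1, 1, 2, ..., 10, 15, 20, 25, 30`,
#' fivefold cross-validation, 10,000 permutations and FDR at `q = 0.1`.
#' `epsilon` is the width of the insensitivity tube of the epsilon-SVR on the
#' SD-standardised behavioural score.
#'
#' @param C,gamma regularisation cost and RBF kernel width used when fitting
#'   with fixed hyperparameters (e.g. in the permutation test after the grid
#'   search has selected them).
#' @param epsilon epsilon-tube half-width (on the standardised score scale).
#' @param C_grid,gamma_grid candidate values for [grid_search()].
#' @param k_folds number of cross-validation folds.
#' @param n_permutations number of label permutations for inference.
#' @param fdr_q false-discovery-rate level.
#' @param seed integer seed for fold assignment and permutations.
#' @export
svr_config <- function(C = 40, gamma = 2, epsilon = 0.1,
                       C_grid = c(1, 10, 20, 30, 40, 50, 60, 70, 80),
                       gamma_grid = c(0.1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                                      15, 20, 25, 30),
                       k_folds = 5L, n_permutations = 10000L,
                       fdr_q = 0.1, seed = 1L) {
  stopifnot(C > 0, gamma > 0, epsilon >= 0,
            length(C_grid) >= 1, length(gamma_grid) >= 1,
            all(C_grid > 0), all(gamma_grid > 0),
            k_folds >= 2, fdr_q > 0, fdr_q < 1)
  structure(list(C = C, gamma = gamma, epsilon = epsilon,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 k_folds = as.integer(k_folds),
                 n_permutations = as.integer(n_permutations),
                 fdr_q = fdr_q, seed = as.integer(seed)),
            class = "svr_config")
}

#' Direct total lesion volume control
#'
#' Scales each subject's binary lesion vector to unit Euclidean norm (i.e.
#' divides by the square root of the in-mask lesion size), so that total
#' lesion volume cannot drive the multivariate fit. All-zero rows are left
#' unchanged.
#'
#' @param matrix binary subjects-by-voxels matrix.
#' @return A real-valued matrix with rows of Euclidean norm 1 (or 0).
#' @export
dtlvc_normalize <- function(matrix) {
  rn <- sqrt(rowSums(matrix^2))
  rn[rn == 0] <- 1
  matrix / rn
}

# --- internal SVR engine -----------------------------------------------------
# The RBF kernel depends only on the (dTLVC-normalised) features, never on the
# behavioural scores, so one kernel matrix serves the observed fit and every
# permutation refit.

# Squared Euclidean distances between rows.
row_sqdist <- function(Xn) {
  G <- tcrossprod(Xn)
  n2 <- diag(G)
  D2 <- outer(n2, n2, `+`) - 2 * G
  D2[D2 < 0] <- 0
  D2
}

svr_kernel <- function(Xn, gamma, kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  if (kernel == "linear") tcrossprod(Xn) else exp(-gamma * row_sqdist(Xn))
}

# Fit an eps-SVR on a precomputed kernel; return signed dual coefficients,
# their sample indices, and the offset.
svr_fit_kernel <- function(K, y, C, epsilon) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                     kernel = "matrix", C = C, epsilon = epsilon,
                     scaled = FALSE)
  list(coefs = as.numeric(unlist(kernlab::coef(m))),
       index = as.integer(unlist(kernlab::alphaindex(m))),
       b = kernlab::b(m))
}

# Decision values for rows of Ktest (test x train kernel block).
svr_predict_kernel <- function(fit, Ktest) {
  as.vector(Ktest[, fit$index, drop = FALSE] %*% fit$coefs) - fit$b
}

# Pseudo-beta back-projection: beta_j = sum_i alpha_i x_ij over support
# vectors, the linear approximation of the non-linear model's voxel weights.
# For a linear kernel this *is* the primal weight vector.
svr_beta <- function(fit, Xn) {
  drop(crossprod(fit$coefs, Xn[fit$index, , drop = FALSE]))
}

#' Fit the epsilon-SVR and back-project pseudo-beta weights
#'
#' Applies direct total lesion volume control, standardises the behavioural
#' score by its SD, fits a non-linear epsilon-SVR with RBF kernel
#' (`exp(-gamma * ||u - v||^2)`) on all analysed voxels at once, and
#' back-projects the fitted dual coefficients onto the voxels:
#' `beta_j = sum_i alpha_i x_ij`. Positive beta means damage at the voxel is
#' associated with a worse (higher) score.
#'
#' @param matrix binary subjects-by-voxels feature matrix.
#' @param y behavioural scores (typically neglect-residualised extinction
#'   scores); must not be constant.
#' @param config an [svr_config()]; `C`, `gamma`, `epsilon` are used.
#' @param kernel `"radial"` (default) or `"linear"` (diagnostic kernel for
#'   which the back-projection is exact).
#' @return A list with `beta` (per-voxel pseudo-beta vector), `fit` (dual
#'   solution) and `y_scale` (the SD used for standardisation).
#' @export
fit_svr_betas <- function(matrix, y, config = svr_config(),
                          kernel = "radial") {
  stopifnot(nrow(matrix) == length(y))
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0)
    stop("behavioural scores are constant: no variance to model")
  ys <- y / s
  Xn <- dtlvc_normalize(matrix)
  K <- svr_kernel(Xn, config$gamma, kernel)
  fit <- svr_fit_kernel(K, ys, config$C, config$epsilon)
  list(beta = svr_beta(fit, Xn), fit = fit, y_scale = s)
}

#' Dual-criterion cross-validated grid search
#'
#' For every `(C, gamma)` candidate pair, k-fold cross-validation yields
#' (a) *prediction accuracy*: the mean over folds of the Pearson correlation
#' between held-out predictions and held-out scores, and (b)
#' *reproducibility*: the mean Pearson correlation between the pseudo-beta
#' maps of all pairs of fold models. The selected pair maximises the sum of
#' the ranks of the two criteria (high reproducibility at decent accuracy);
#' ties are broken towards smaller `C`, then smaller `gamma`. Folds are fixed
#' by `config$seed` and shared across all pairs.
#'
#' @inheritParams fit_svr_betas
#' @return A list of class `grid_search_result`: `table` (one row per pair
#'   with `C`, `gamma`, `accuracy`, `reproducibility`) and `selected` (row
#'   with the chosen pair).
#' @export
grid_search <- function(matrix, y, config = svr_config()) {
  n <- nrow(matrix)
  stopifnot(n == length(y), n >= config$k_folds)
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("behavioural scores are constant")
  ys <- y / s
  Xn <- dtlvc_normalize(matrix)
  D2 <- row_sqdist(Xn)
  folds <- with_rng(config$seed, {
    shuffled <- sample.int(n)
    split(shuffled, cut(seq_len(n), config$k_folds, labels = FALSE))
  })
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- rep <- numeric(nrow(grid))
  for (g in unique(grid$gamma)) {
    K <- exp(-g * D2)
    rows <- which(grid$gamma == g)
    for (r in rows) {
      C <- grid$C[r]
      fold_r <- numeric(length(folds))
      betas <- vector("list", length(folds))
      for (f in seq_along(folds)) {
        te <- folds[[f]]; tr <- setdiff(seq_len(n), te)
        fit <- svr_fit_kernel(K[tr, tr, drop = FALSE], ys[tr], C,
                              config$epsilon)
        pred <- svr_predict_kernel(fit, K[te, tr, drop = FALSE])
        fold_r[f] <- if (stats::sd(ys[te]) == 0 || stats::sd(pred) == 0) {
          warning("fold ", f, " has constant held-out scores or predictions; ",
                  "its accuracy correlation is excluded")
          NA_real_
        } else stats::cor(pred, ys[te])
        betas[[f]] <- svr_beta(fit, Xn[tr, , drop = FALSE])
      }
      acc[r] <- mean(fold_r, na.rm = TRUE)
      pairs <- utils::combn(length(folds), 2)
      rep[r] <- mean(apply(pairs, 2, function(p)
        stats::cor(betas[[p[1]]], betas[[p[2]]])))
    }
  }
  tab <- data.frame(C = grid$C, gamma = grid$gamma,
                    accuracy = acc, reproducibility = rep)
  score <- rank(tab$accuracy, ties.method = "average") +
    rank(tab$reproducibility, ties.method = "average")
  best <- which(score == max(score))
  best <- best[order(tab$C[best], tab$gamma[best])][1]
  structure(list(table = tab, selected = tab[best, , drop = FALSE]),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat("Grid search over", nrow(x$table), "candidate (C, gamma) pairs\n")
  cat("  selected: C =", x$selected$C, ", gamma =", x$selected$gamma,
      "| accuracy r =", signif(x$selected$accuracy, 3),
      "| reproducibility r =", signif(x$selected$reproducibility, 3), "\n")
  invisible(x)
}

#' Permutation inference on pseudo-beta maps
#'
#' Refits the SVR with the behavioural scores randomly permuted
#' (`n_permutations` times, hyperparameters held fixed at `config$C`,
#' `config$gamma`, `config$epsilon`) and computes the one-tailed add-one
#' voxel-wise p-value `p_j = (1 + #\{beta_perm_j >= beta_obs_j\}) /
#' (n_permutations + 1)` in the damage-associated-with-worse-score
#' direction. The kernel matrix is computed once and reused for every refit.
#'
#' @inheritParams fit_svr_betas
#' @return A list with `p` (per-voxel p-values in `[1/(N+1), 1]`), `beta`
#'   (observed pseudo-beta) and `n_permutations`.
#' @export
permutation_test <- function(matrix, y, config = svr_config()) {
  if (config$n_permutations < 1)
    stop("at least one permutation is required")
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("behavioural scores are constant")
  ys <- y / s
  Xn <- dtlvc_normalize(matrix)
  K <- svr_kernel(Xn, config$gamma, "radial")
  obs_fit <- svr_fit_kernel(K, ys, config$C, config$epsilon)
  beta_obs <- svr_beta(obs_fit, Xn)
  exceed <- integer(length(beta_obs))
  with_rng(config$seed, {
    for (b in seq_len(config$n_permutations)) {
      yp <- sample(ys)
      fit <- svr_fit_kernel(K, yp, config$C, config$epsilon)
      exceed <- exceed + (svr_beta(fit, Xn) >= beta_obs)
    }
  })
  list(p = (1 + exceed) / (config$n_permutations + 1),
       beta = beta_obs, n_permutations = config$n_permutations)
}

#' Benjamini-Hochberg FDR thresholding
#'
#' Step-up FDR control over the analysed voxels at level `q`, returning the
#' significance mask and the equivalent uncorrected p threshold (the largest
#' p-value that still passes).
#'
#' @param p numeric vector of per-voxel p-values.
#' @param q FDR level in (0, 1).
#' @return A list with `significant` (logical vector), `p_threshold`
#'   (largest passing p, `NA` if nothing passes) and `n_significant`.
#' @export
fdr_threshold <- function(p, q = 0.1) {
  stopifnot(length(p) >= 1, q > 0, q < 1)
  sig <- stats::p.adjust(p, method = "BH") <= q
  list(significant = sig,
       p_threshold = if (any(sig)) max(p[sig]) else NA_real_,
       n_significant = sum(sig))
}

#' Labelled atlas for cluster reporting
#'
#' @param name atlas name.
#' @param regions named list of 3-D arrays: probabilistic maps (`type =
#'   "max_prob"`, voxels assigned to the region with the highest probability)
#'   or binary maps (`type = "binary"`, overlap counted per region).
#' @param type assignment rule.
#' @export
atlas_map <- function(name, regions, type = c("max_prob", "binary")) {
  type <- match.arg(type)
  stopifnot(is.list(regions), length(regions) >= 1,
            !is.null(names(regions)))
  structure(list(name = name, regions = regions, type = type),
            class = "atlas_map")
}

#' Cluster and atlas table of significant voxels
#'
#' Finds 26-connected components of the significance mask, drops components
#' with `min_cluster_voxels` voxels or fewer, and assigns each surviving
#' cluster's voxels to atlas regions: by maximum probability for
#' probabilistic grey-matter atlases, by binary overlap for thresholded
#' white-matter maps. Region rows with `min_region_voxels` voxels or fewer
#' are suppressed. Volumes are reported in voxels and in mm^3 via the voxel
#' volume `|det(A[1:3,1:3])|` of the affine.
#'
#' @param sig_mask logical 3-D array (or [voxel_stat_map()]) of significant
#'   voxels.
#' @param affine 4x4 voxel-to-world transform.
#' @param atlases list of [atlas_map()] objects (may be empty).
#' @param min_cluster_voxels clusters must exceed this size (default 100).
#' @param min_region_voxels region rows must exceed this count (default 15).
#' @return A list of class `cluster_table`: `clusters` (cluster id, size in
#'   voxels and mm^3, centre of mass) and `regions` (per cluster x atlas
#'   region voxel counts), both data frames (possibly empty).
#' @export
cluster_table <- function(sig_mask, affine = diag(4), atlases = list(),
                          min_cluster_voxels = 100L, min_region_voxels = 15L) {
  if (inherits(sig_mask, "voxel_stat_map")) {
    affine <- sig_mask$affine
    sig_mask <- sig_mask$values != 0 & !is.na(sig_mask$values)
  }
  vox_mm3 <- abs(det(affine[1:3, 1:3]))
  labels <- label_components_26(sig_mask)
  k <- max(labels)
  sizes <- if (k > 0) tabulate(labels[labels > 0], k) else integer(0)
  keep <- which(sizes > min_cluster_voxels)
  clusters <- data.frame(cluster = integer(0), n_voxels = integer(0),
                         volume_mm3 = numeric(0),
                         com_i = numeric(0), com_j = numeric(0),
                         com_k = numeric(0))
  regions <- data.frame(cluster = integer(0), atlas = character(0),
                        region = character(0), n_voxels = integer(0),
                        volume_mm3 = numeric(0))
  if (length(keep) == 0)
    return(structure(list(clusters = clusters, regions = regions),
                     class = "cluster_table"))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  for (ci in seq_along(keep)) {
    vox <- which(labels == keep[ci])
    ijk <- arrayInd(vox, dim(sig_mask))
    clusters <- rbind(clusters, data.frame(
      cluster = ci, n_voxels = length(vox),
      volume_mm3 = length(vox) * vox_mm3,
      com_i = mean(ijk[, 1]), com_j = mean(ijk[, 2]), com_k = mean(ijk[, 3])))
    for (atl in atlases) {
      counts <- atlas_assign_counts(atl, vox, dim(sig_mask))
      counts <- counts[counts > min_region_voxels]
      if (length(counts))
        regions <- rbind(regions, data.frame(
          cluster = ci, atlas = atl$name, region = names(counts),
          n_voxels = as.integer(counts),
          volume_mm3 = as.numeric(counts) * vox_mm3))
    }
  }
  structure(list(clusters = clusters, regions = regions),
            class = "cluster_table")
}

# Voxel counts of one cluster per atlas region under the atlas's rule.
atlas_assign_counts <- function(atlas, vox, dim3) {
  if (atlas$type == "binary") {
    counts <- vapply(atlas$regions, function(r) sum(r[vox] != 0), 0)
  } else {
    probs <- vapply(atlas$regions, function(r) as.numeric(r[vox]),
                    numeric(length(vox)))
    probs <- matrix(probs, nrow = length(vox))
    best <- max.col(probs, ties.method = "first")
    best[apply(probs, 1, max) <= 0] <- NA
    counts <- vapply(seq_along(atlas$regions),
                     function(j) sum(best == j, na.rm = TRUE), 0)
    names(counts) <- names(atlas$regions)
  }
  counts
}

#' @export
print.cluster_table <- function(x, ...) {
  cat("Cluster table:", nrow(x$clusters), "clusters\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  if (nrow(x$regions)) {
    cat("Atlas assignment:\n")
    print(x$regions, row.names = FALSE)
  }
  invisible(x)
}
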