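# Bayesian lesion-deficit inference: voxel-wise Bayes-factor mapping with a
# behavioural covariate, evidence categorisation and probabilistic-ROI
# summaries.

# --- JZS Bayes factor engine -------------------------------------------------
# Model-vs-intercept Bayes factor for a linear model with p regressors and
# coefficient of determination R2, under a Zellner-Siow prior: Cauchy with
# scale `rscale` on the standardised coefficients, i.e. g ~ InvGamma(1/2,
# n * rscale^2 / 2) mixed over the g-prior (Liang et al. framework):
#
#   BF = int_0^inf (1+g)^((n-1-p)/2) (1 + g(1-R2))^(-(n-1)/2) pi(g) dg
#
# Integration is over t = log(g) with adaptive quadrature after shifting by
# the integrand's maximum, which keeps the computation stable for the very
# large Bayes factors strong lesion-deficit associations produce.
jzs_log_integrand <- function(t, n, p, R2, rscale) {
  b <- n * rscale^2 / 2
  # log1p(exp(u)) without overflow at large |u|
  softplus <- function(u) ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u)))
  # log InvGamma(1/2, b) density in g = exp(t), plus log-Jacobian dg/dt = g
  ((n - 1 - p) / 2) * softplus(t) -
    ((n - 1) / 2) * softplus(t + log(1 - R2)) +
    0.5 * log(b) - lgamma(0.5) - 1.5 * t - b * exp(-t) + t
}

jzs_bf_model_vs_null <- function(n, p, R2, rscale = sqrt(2) / 2,
                                 rel.tol = 1e-8) {
  stopifnot(n > p + 1, R2 >= 0, R2 < 1)
  opt <- stats::optimize(function(t) jzs_log_integrand(t, n, p, R2, rscale),
                         interval = c(-25, 35), maximum = TRUE)
  shift <- opt$objective
  val <- stats::integrate(function(t)
    exp(jzs_log_integrand(t, n, p, R2, rscale) - shift),
    lower = -Inf, upper = Inf, rel.tol = rel.tol)$value
  list(log_bf = shift + log(val), bf = exp(shift + log(val)))
}

#' JZS Bayes factor for one tested regressor with a covariate
#'
#' Compares the linear model `y ~ covariate + x` (H1) against `y ~ covariate`
#' (H0) by the ratio of their Zellner-Siow (JZS, Cauchy scale `rscale`)
#' model-vs-intercept Bayes factors, each obtained by adaptive numerical
#' integration over the g-prior mixing parameter. With `covariate = NULL` the
#' comparison is `y ~ x` against the intercept-only model.
#'
#' @param y outcome vector.
#' @param x tested regressor (e.g. a voxel's lesion status).
#' @param covariate optional nuisance regressor.
#' @param rscale Cauchy prior scale on the standardised coefficient
#'   (default `sqrt(2)/2`).
#' @return The Bayes factor BF10 (positive scalar).
#' @export
bf_lesion_covariate <- function(y, x, covariate = NULL,
                                rscale = sqrt(2) / 2) {
  n <- length(y)
  stopifnot(length(x) == n, is.null(covariate) || length(covariate) == n)
  r2 <- function(X) {
    f <- stats::lm.fit(cbind(1, X), y)
    min(max(0, 1 - sum(f$residuals^2) / sum((y - mean(y))^2)), 1 - 1e-12)
  }
  if (is.null(covariate)) {
    jzs_bf_model_vs_null(n, 1, r2(cbind(x)), rscale)$bf
  } else {
    full <- jzs_bf_model_vs_null(n, 2, r2(cbind(covariate, x)), rscale)
    red <- jzs_bf_model_vs_null(n, 1, r2(cbind(covariate)), rscale)
    exp(full$log_bf - red$log_bf)
  }
}

#' Voxel-wise Bayesian lesion-deficit inference
#'
#' Fits, in every voxel lesioned in at least `min_overlap` subjects, a
#' Bayesian general linear model of the behavioural score on the voxel's
#' lesion status with the neglect score (CoC) as covariate, and maps the
#' Bayes factor BF10 of the lesion effect. Unlike frequentist mapping, the
#' Bayes factor can also quantify evidence *for* the null (no lesion-deficit
#' association) and exposes voxels where the data are simply insufficient.
#'
#' Voxels lesioned in fewer than `min_overlap` subjects are tagged
#' not-analysed (`NA` in the returned vector), as are degenerate voxels whose
#' lesion status is collinear with the covariate/intercept.
#'
#' @param matrix binary subjects-by-voxels feature matrix.
#' @param y behavioural scores (raw extinction scores, not residuals: the
#'   covariate enters the model itself).
#' @param covariate nuisance covariate (average CoC), or NULL.
#' @param min_overlap minimum lesion count for a voxel to be analysed
#'   (default 5).
#' @param rscale JZS prior scale.
#' @return A list with `bf` (per-column BF10, `NA` where not analysed),
#'   `analysed` (logical per column) and `min_overlap`.
#' @export
bldi_map <- function(matrix, y, covariate = NULL, min_overlap = 5L,
                     rscale = sqrt(2) / 2) {
  n <- nrow(matrix)
  stopifnot(n == length(y), min_overlap >= 1,
            is.null(covariate) || length(covariate) == n)
  if (stats::var(y) == 0)
    stop("behavioural scores are constant: no deficit variance to model")
  analysed <- colSums(matrix != 0) >= min_overlap
  bf <- rep(NA_real_, ncol(matrix))
  p_red <- if (is.null(covariate)) 0L else 1L
  # reduced-model Bayes factor is shared by all voxels
  Xr <- if (is.null(covariate)) NULL else cbind(covariate)
  tss <- sum((y - mean(y))^2)
  r2_of <- function(X) {
    f <- stats::lm.fit(cbind(1, X), y)
    min(max(0, 1 - sum(f$residuals^2) / tss), 1 - 1e-12)
  }
  log_red <- if (p_red == 0) 0 else
    jzs_bf_model_vs_null(n, 1, r2_of(Xr), rscale)$log_bf
  for (j in which(analysed)) {
    xj <- matrix[, j]
    Xf <- cbind(Xr, xj)
    qrf <- qr(cbind(1, Xf))
    if (qrf$rank < ncol(Xf) + 1) {  # collinear with covariate/intercept
      analysed[j] <- FALSE
      next
    }
    r2f <- r2_of(Xf)
    if (r2f >= 1) r2f <- 1 - 1e-12
    log_full <- jzs_bf_model_vs_null(n, p_red + 1L, r2f, rscale)$log_bf
    bf[j] <- exp(log_full - log_red)
  }
  list(bf = bf, analysed = analysed, min_overlap = as.integer(min_overlap))
}

#' Categorise Bayes factors into evidence classes
#'
#' BF10 above `h1_cut` (default 3) is evidence for a lesion-deficit
#' association (H1); below `h0_cut` (default 1/3) evidence for its absence
#' (H0); in between the evidence is insufficient. Voxels that were not
#' analysed keep their own category.
#'
#' @param bf numeric vector of Bayes factors (`NA` where not analysed).
#' @param h1_cut,h0_cut category boundaries, `h0_cut < h1_cut`.
#' @return A factor with levels `H1`, `H0`, `insufficient`, `not-analysed`.
#' @export
categorize_bf <- function(bf, h1_cut = 3, h0_cut = 1 / 3) {
  stopifnot(h0_cut < h1_cut)
  out <- rep("insufficient", length(bf))
  out[is.na(bf)] <- "not-analysed"
  out[!is.na(bf) & bf > h1_cut] <- "H1"
  out[!is.na(bf) & bf < h0_cut] <- "H0"
  factor(out, levels = c("H1", "H0", "insufficient", "not-analysed"))
}

#' Peak-evidence map
#'
#' Binary map of voxels with Bayes factors strictly above `cut` (default 50),
#' a stringency comparable to a multiple-comparison-corrected frequentist
#' map.
#'
#' @param bf numeric vector of Bayes factors (`NA` = not analysed).
#' @param cut strict threshold.
#' @return Logical vector (`FALSE` where not analysed).
#' @export
peak_bf_map <- function(bf, cut = 50) {
  stopifnot(cut > 0)
  !is.na(bf) & bf > cut
}

#' Combine probabilistic ROI subparts
#'
#' Voxel-wise sum of probabilistic maps (e.g. the subparts of the
#' intraparietal sulcus), clipped to 1.
#'
#' @param parts list of 3-D probability arrays on one grid.
#' @return A single probability array.
#' @export
combine_prob_maps <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1)
  d <- dim(parts[[1]])
  for (p in parts)
    if (!identical(dim(p), d)) stop("probabilistic maps are on different grids")
  clip(Reduce(`+`, parts), 0, 1)
}

#' Threshold a probabilistic ROI
#'
#' `mode = "max-extent"` keeps every voxel with non-zero probability (the
#' maximum extent of the map); `mode = "core"` keeps voxels with probability
#' at least `p_min` (inclusive; default 0.4, the conventional core-area
#' threshold).
#'
#' @param prob 3-D probability array.
#' @param p_min core threshold in \[0, 1\].
#' @param mode `"core"` or `"max-extent"`.
#' @return Logical array.
#' @export
threshold_prob_roi <- function(prob, p_min = 0.4,
                               mode = c("core", "max-extent")) {
  mode <- match.arg(mode)
  stopifnot(p_min >= 0, p_min <= 1)
  if (mode == "max-extent") prob > 0 else prob >= p_min
}

#' Four-way evidence summary within an ROI
#'
#' Percentages of ROI voxels with evidence for H1, insufficient evidence,
#' evidence for H0, and voxels lesioned too rarely to be analysed. The four
#' percentages partition the ROI and sum to 100.
#'
#' @param categories factor from [categorize_bf()], one entry per ROI-grid
#'   voxel (or per analysed-map voxel aligned with `roi`).
#' @param roi logical vector/array selecting the ROI voxels (non-empty).
#' @return Named numeric vector `c(H1, insufficient, H0, not_analysed)` in
#'   percent.
#' @export
roi_bf_summary <- function(categories, roi) {
  roi <- as.logical(roi)
  stopifnot(length(categories) == length(roi))
  m <- sum(roi)
  if (m == 0) stop("ROI is empty")
  cats <- categories[roi]
  c(H1 = 100 * sum(cats == "H1") / m,
    insufficient = 100 * sum(cats == "insufficient") / m,
    H0 = 100 * sum(cats == "H0") / m,
    not_analysed = 100 * sum(cats == "not-analysed") / m)
}
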