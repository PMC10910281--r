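#' Assessability screen for confrontation testing
#'
#' A patient who detects fewer than 90% of contralesional movements under
#' unilateral stimulation cannot be meaningfully assessed for extinction
#' (misses in bilateral trials may then reflect a primary detection deficit
#' rather than extinction) and is flagged not assessable.
#'
#' @param record a [confrontation_record()].
#' @return `TRUE` if assessable, `FALSE` otherwise.
#' @export
screen_assessability <- function(record) {
  stopifnot(inherits(record, "confrontation_record"), record$n_uni_left > 0)
  record$hits_uni_left / record$n_uni_left >= 0.90
}

#' Extinction score from a confrontation record
#'
#' Percentage of bilateral trials in which the contralesional movement was
#' missed, among trials where the ipsilesional movement was detected; trials
#' with an ipsilesional miss are excluded since they indicate a lapse rather
#' than extinction.
#'
#' @param record a [confrontation_record()].
#' @return The extinction score in percent (0-100).
#' @export
compute_extinction_score <- function(record) {
  stopifnot(inherits(record, "confrontation_record"))
  bil <- record$bilateral_outcomes
  valid <- bil[, "ipsi"] == 1
  if (!any(valid))
    stop("no bilateral trial with ipsilesional detection: record is unassessable")
  100 * sum(bil[valid, "contra"] == 0) / sum(valid)
}

#' Extinction index from unilateral and bilateral hit proportions
#'
#' Difference of differences contrasting the unilateral-to-bilateral
#' performance drop between the two sides:
#' `(P(hit|uni-left) - P(hit|bil-left)) - (P(hit|uni-right) - P(hit|bil-right))`.
#' An index of +1 reflects complete contralateral (left-sided) extinction and
#' -1 complete ipsilateral extinction; spatial biases that affect unilateral
#' and bilateral trials alike cancel out.
#'
#' @param p_uni_left,p_bil_left,p_uni_right,p_bil_right hit proportions in
#'   \[0, 1\].
#' @return The raw index value.
#' @export
compute_extinction_index <- function(p_uni_left, p_bil_left,
                                     p_uni_right, p_bil_right) {
  p <- c(p_uni_left, p_bil_left, p_uni_right, p_bil_right)
  if (any(p < 0 | p > 1))
    stop("hit proportions must lie in [0, 1]")
  (p_uni_left - p_bil_left) - (p_uni_right - p_bil_right)
}

#' Center of Cancellation
#'
#' Mean normalised horizontal position of the cancelled targets on a
#' cancellation sheet (positions in \[-1, 1\], 0 at the sheet centre). 0
#' indicates symmetrical cancellation; values towards +1 the neglect-typical
#' rightward concentration, +1 being maximal possible neglect (only the
#' rightmost target found).
#'
#' @param sheet a [cancellation_sheet()].
#' @return CoC in \[-1, 1\].
#' @export
compute_coc <- function(sheet) {
  stopifnot(inherits(sheet, "cancellation_sheet"))
  if (!any(sheet$cancelled))
    stop("no cancelled targets: CoC is indeterminate for an empty sheet")
  mean(sheet$target_x[sheet$cancelled])
}

#' Average two CoC scores
#'
#' The CoC values of the two cancellation tasks (bells and letters) are
#' averaged into a single neglect score.
#'
#' @param coc_a,coc_b CoC values in \[-1, 1\].
#' @export
average_coc <- function(coc_a, coc_b) {
  stopifnot(coc_a >= -1, coc_a <= 1, coc_b >= -1, coc_b <= 1)
  (coc_a + coc_b) / 2
}

#' Regress extinction scores on the neglect covariate
#'
#' Ordinary least squares of the extinction score on the CoC. The residuals
#' are a measure of extinction controlled for unilateral attentional bias
#' (neglect affects unilateral and bilateral detection alike, extinction only
#' bilateral detection, so the shared variance is a confound); they are used
#' as the behavioural variable of the multivariate lesion mapping.
#'
#' @param ext_scores numeric vector of extinction scores.
#' @param cocs numeric vector of CoC values (same length, not all equal).
#' @return A list with `residuals` and `summary` (a one-row data frame with
#'   `slope`, `intercept`, `r_squared`, `p_value`).
#' @export
residualize_extinction <- function(ext_scores, cocs) {
  stopifnot(length(ext_scores) == length(cocs), length(cocs) >= 3)
  if (stats::var(cocs) == 0)
    stop("covariate is constant: regression slope is unidentifiable")
  fit <- stats::lm(ext_scores ~ cocs)
  sm <- summary(fit)
  slope_p <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  list(residuals = unname(stats::residuals(fit)),
       summary = data.frame(slope = unname(stats::coef(fit)[2]),
                            intercept = unname(stats::coef(fit)[1]),
                            r_squared = sm$r.squared,
                            p_value = slope_p))
}

#' Validate the covariate-control approach
#'
#' Spearman rank correlation (with two-sided p-value) between the residuals
#' of the nuisance regression and an independently obtained extinction index.
#' A strong positive correlation indicates that regressing out neglect leaves
#' a valid measure of extinction.
#'
#' @param residuals residualised extinction scores.
#' @param ext_indices extinction indices for the same subjects.
#' @return A list with `rho` and `p_value`.
#' @export
validate_covariate_control <- function(residuals, ext_indices) {
  stopifnot(length(residuals) == length(ext_indices), length(residuals) >= 3)
  if (stats::var(rank(residuals)) == 0 || stats::var(rank(ext_indices)) == 0)
    stop("a vector with only ties has no rank ordering to correlate")
  ct <- suppressWarnings(
    stats::cor.test(residuals, ext_indices, method = "spearman",
                    alternative = "two.sided",
                    exact = length(residuals) < 10))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Read or write a behaviour table
#'
#' CSV with columns `subject_id, ext_score, coc, ext_residual, ext_index`;
#' `ext_residual` and `ext_index` may be absent or NA.
#'
#' @param behaviour data frame with at least `subject_id`, `ext_score`, `coc`.
#' @param path file path.
#' @export
write_behaviour_csv <- function(behaviour, path) {
  cols <- c("subject_id", "ext_score", "coc", "ext_residual", "ext_index")
  for (c in setdiff(cols, names(behaviour))) behaviour[[c]] <- NA_real_
  utils::write.csv(behaviour[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour_csv
#' @export
read_behaviour_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "ext_score", "coc")
  if (!all(need %in% names(tab)))
    stop("behaviour table must contain columns: ", paste(need, collapse = ", "))
  tab
}
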