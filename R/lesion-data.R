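#' Lesion dataset container
#'
#' Subject-indexed binary lesion masks on one shared voxel grid, plus the
#' voxel-to-world affine and per-subject lesion volumes (voxel counts).
#'
#' @param masks list of binary 3-D arrays, one per subject, all on the same
#'   grid.
#' @param subject_ids character vector of subject identifiers.
#' @param affine 4x4 voxel-to-world transform (identity by default).
#' @return An object of class `lesion_dataset` with elements `subject_ids`,
#'   `masks`, `affine`, `grid_shape`, `lesion_volumes`.
#' @export
lesion_dataset <- function(masks, subject_ids = NULL, affine = diag(4),
                           grid_shape = NULL) {
  stopifnot(is.list(masks))
  n <- length(masks)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(n))
  stopifnot(length(subject_ids) == n)
  if (n > 0) grid_shape <- dim(masks[[1]])
  for (i in seq_len(n)) {
    if (!identical(dim(masks[[i]]), grid_shape))
      stop("mask for subject ", subject_ids[i],
           " is not on the shared grid")
    if (!all(masks[[i]] %in% c(0, 1)))
      stop("mask for subject ", subject_ids[i], " is not binary")
  }
  structure(list(subject_ids = as.character(subject_ids),
                 masks = lapply(masks, function(m) {
                   storage.mode(m) <- "integer"; m
                 }),
                 affine = affine,
                 grid_shape = if (is.null(grid_shape)) NULL else
                   as.integer(grid_shape),
                 lesion_volumes = vapply(masks, sum, 0)),
            class = "lesion_dataset")
}

#' @export
print.lesion_dataset <- function(x, ...) {
  cat("Lesion dataset:", length(x$subject_ids), "subjects on a",
      paste(x$grid_shape, collapse = "x"), "grid\n")
  if (length(x$lesion_volumes))
    cat("  lesion volume (voxels): median", stats::median(x$lesion_volumes),
        "range", min(x$lesion_volumes), "-", max(x$lesion_volumes), "\n")
  invisible(x)
}

#' Load lesion masks from NIfTI files
#'
#' All files must share one grid and affine (within `tol`). Non-binary
#' positive values are binarised to 1 with a warning.
#'
#' @param paths character vector of NIfTI file paths (may be empty).
#' @param tol tolerance for affine agreement.
#' @return A [lesion_dataset()].
#' @export
load_lesion_maps <- function(paths, tol = 1e-4) {
  if (length(paths) == 0)
    return(lesion_dataset(list(), character(0)))
  ref_dim <- NULL; ref_aff <- NULL
  masks <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    arr <- as.array(img)
    aff <- unclass(RNifti::xform(img))
    if (is.null(ref_dim)) {
      ref_dim <- dim(arr); ref_aff <- aff
    } else {
      if (!identical(dim(arr), ref_dim))
        stop("grid mismatch in ", paths[i], ": expected ",
             paste(ref_dim, collapse = "x"), ", got ",
             paste(dim(arr), collapse = "x"))
      if (max(abs(aff - ref_aff)) > tol)
        stop("affine mismatch in ", paths[i])
    }
    if (!all(arr %in% c(0, 1))) {
      warning("non-binary values in ", basename(paths[i]),
              "; binarising values > 0 to 1")
      arr <- (arr > 0) * 1L
    }
    masks[[i]] <- array(as.integer(arr), ref_dim)
  }
  aff4 <- diag(4)
  aff4[seq_len(nrow(ref_aff)), seq_len(ncol(ref_aff))] <- ref_aff
  lesion_dataset(masks,
                 subject_ids = sub("\\.nii(\\.gz)?$", "", basename(paths)),
                 affine = aff4)
}

#' Write lesion masks as NIfTI files
#'
#' One binary NIfTI-1 file per subject, named `<subject_id>.nii.gz`.
#'
#' @param dataset a [lesion_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_lesion_maps <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(dataset$subject_ids, ".nii.gz"))
  for (i in seq_along(paths))
    RNifti::writeNifti(dataset$masks[[i]], paths[i])
  invisible(paths)
}

#' Voxel-wise statistic map
#'
#' A scalar per-voxel map (overlap count, pseudo-beta, p-value, Bayes factor,
#' category code) together with the mask of analysed voxels.
#'
#' @param values 3-D numeric array.
#' @param mask logical 3-D array of analysed voxels (defaults to all).
#' @param kind character tag describing the statistic.
#' @param affine 4x4 voxel-to-world transform.
#' @export
voxel_stat_map <- function(values, mask = NULL, kind = "statistic",
                           affine = diag(4)) {
  stopifnot(length(dim(values)) == 3L)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  structure(list(values = values, mask = array(as.logical(mask), dim(values)),
                 kind = kind, affine = affine),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat("Voxel map (", x$kind, "): ", sum(x$mask), " analysed voxels, range ",
      signif(min(v), 4), " .. ", signif(max(v), 4), "\n", sep = "")
  invisible(x)
}

#' Lesion overlap map
#'
#' Per-voxel count of subjects whose lesion covers the voxel.
#'
#' @param dataset a [lesion_dataset()] with at least one subject.
#' @return A [voxel_stat_map()] of kind `"overlap"`.
#' @export
overlap_map <- function(dataset) {
  stopifnot(inherits(dataset, "lesion_dataset"))
  if (length(dataset$masks) == 0)
    stop("overlap map of an empty dataset is undefined")
  counts <- Reduce(`+`, dataset$masks)
  voxel_stat_map(counts, kind = "overlap", affine = dataset$affine)
}

#' Build the analysis mask
#'
#' Voxels damaged in at least `min_overlap` subjects are analysed; rarely
#' damaged voxels are excluded because they carry too little statistical
#' power (10 subjects for the multivariate mapping, 5 for the Bayesian
#' analysis).
#'
#' @param dataset a [lesion_dataset()].
#' @param min_overlap minimum lesion count per voxel (>= 1).
#' @return An object of class `analysis_mask` with `included` (logical 3-D
#'   array), `min_overlap`, `n_included_voxels`, `affine`.
#' @export
build_analysis_mask <- function(dataset, min_overlap = 10L) {
  stopifnot(min_overlap >= 1)
  ov <- overlap_map(dataset)
  inc <- ov$values >= min_overlap
  structure(list(included = inc, min_overlap = as.integer(min_overlap),
                 n_included_voxels = sum(inc), affine = dataset$affine),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  cat("Analysis mask: ", x$n_included_voxels, " voxels damaged in >= ",
      x$min_overlap, " subjects\n", sep = "")
  invisible(x)
}

#' Subjects-by-voxels feature matrix
#'
#' Vectorises the lesion masks over the analysis mask. Rows are subjects
#' (all-zero rows are retained: an intact analysis region is informative);
#' columns are analysed voxels, with a voxel index map recording each
#' column's grid coordinate.
#'
#' @param dataset a [lesion_dataset()].
#' @param mask an [build_analysis_mask()] result with at least one voxel.
#' @return A list with `X` (n_subjects x n_voxels binary matrix) and `voxels`
#'   (data frame `voxel_id, i, j, k`).
#' @export
feature_matrix <- function(dataset, mask) {
  stopifnot(inherits(dataset, "lesion_dataset"),
            inherits(mask, "analysis_mask"))
  if (mask$n_included_voxels == 0)
    stop("analysis mask is empty: no voxel reaches the overlap threshold")
  sel <- which(mask$included)
  X <- matrix(0L, length(dataset$masks), length(sel),
              dimnames = list(dataset$subject_ids, NULL))
  for (i in seq_along(dataset$masks)) X[i, ] <- dataset$masks[[i]][sel]
  ijk <- arrayInd(sel, dim(mask$included))
  list(X = X,
       voxels = data.frame(voxel_id = seq_along(sel),
                           i = ijk[, 1], j = ijk[, 2], k = ijk[, 3]))
}

#' Remap per-voxel values into brain space
#'
#' Inverse of [feature_matrix()] for a single statistic vector: places
#' `values[j]` at the grid coordinate of analysed voxel `j` and `fill`
#' elsewhere.
#'
#' @param values numeric vector, one value per analysed voxel.
#' @param mask the [build_analysis_mask()] the values are defined on.
#' @param kind statistic tag for the returned map.
#' @param fill value outside the analysis mask.
#' @return A [voxel_stat_map()].
#' @export
map_to_grid <- function(values, mask, kind = "statistic", fill = NA_real_) {
  stopifnot(inherits(mask, "analysis_mask"),
            length(values) == mask$n_included_voxels)
  out <- array(fill, dim(mask$included))
  out[which(mask$included)] <- values
  voxel_stat_map(out, mask$included, kind = kind, affine = mask$affine)
}

#' Write a voxel map as NIfTI
#'
#' @param map a [voxel_stat_map()].
#' @param path output file.
#' @param fill replacement for NA outside the analysed mask.
#' @export
write_stat_map <- function(map, path, fill = 0) {
  stopifnot(inherits(map, "voxel_stat_map"))
  vals <- map$values
  vals[is.na(vals)] <- fill
  RNifti::writeNifti(vals, path)
  invisible(path)
}
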