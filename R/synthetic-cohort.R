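#' Describe a synthetic vascular territory
#'
#' A territory model captures, in stylised form, where stroke lesions tend to
#' occur on the analysis grid: lesion seeds and growth are biased towards a
#' territory centre, with frequency falling off exponentially with distance.
#' This emulates the strong centre-to-periphery lesion-frequency gradient of
#' middle-cerebral-artery stroke, in which inferior parietal and temporal
#' cortex is damaged often while more superior areas are rarely hit.
#'
#' @param grid_shape integer vector of length 3; voxel dimensions of the grid.
#' @param centre voxel coordinate (length 3) of the territory centre. Defaults
#'   to the middle of the grid.
#' @param decay positive scalar; exponential falloff rate (per voxel of
#'   Euclidean distance) of the lesion-frequency gradient. Larger values give
#'   a steeper, more concentrated territory.
#' @param size_range integer vector `c(min, max)`: admissible lesion volumes
#'   in voxels. Volumes are drawn log-uniformly in this range, giving the
#'   right-skewed lesion-size distribution typical of stroke cohorts.
#' @return An object of class `territory_model`.
#' @export
territory_model <- function(grid_shape = c(20L, 20L, 20L), centre = NULL,
                            decay = 0.2, size_range = c(10L, 300L)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (is.null(centre)) centre <- ceiling(grid_shape / 2)
  centre <- as.numeric(centre)
  stopifnot(length(centre) == 3L)
  if (!(is.numeric(decay) && length(decay) == 1L && decay > 0))
    stop("`decay` must be a positive scalar")
  size_range <- as.integer(round(size_range))
  if (size_range[1] < 1L)
    stop("`size_range` minimum must be at least 1 voxel")
  if (size_range[1] > size_range[2])
    stop("`size_range` minimum must not exceed its maximum")
  if (size_range[2] > prod(grid_shape))
    stop("`size_range` maximum (", size_range[2],
         ") exceeds the number of grid voxels (", prod(grid_shape), ")")
  structure(list(grid_shape = grid_shape, centre = centre,
                 decay = decay, size_range = size_range),
            class = "territory_model")
}

#' @export
print.territory_model <- function(x, ...) {
  cat("Territory model: grid", paste(x$grid_shape, collapse = "x"),
      "| centre", paste(round(x$centre, 1), collapse = ","),
      "| decay", x$decay,
      "| lesion volume", x$size_range[1], "-", x$size_range[2], "voxels\n")
  invisible(x)
}

#' Ground truth for a simulated lesion-behaviour cohort
#'
#' Bundles the critical region(s) whose damage drives visual extinction, the
#' (possibly overlapping) region whose damage drives spatial neglect, and the
#' scalar parameters that map lesion load to behaviour.
#'
#' `critical_masks` may contain two or more disjoint masks to emulate a
#' distributed functional network: the effective extinction load is then the
#' *maximum* of the per-region lesioned fractions, so that complete damage to
#' any one node produces the full deficit (the "partial injury" situation that
#' motivates multivariate mapping).
#'
#' @param territory a [territory_model()]; fixes the grid.
#' @param critical_masks a binary 3-D array or list of such arrays (the
#'   extinction-critical network).
#' @param neglect_mask binary 3-D array driving the neglect covariate (CoC).
#' @param effect_size non-negative scalar: expected bilateral contralesional
#'   miss probability when the critical region is fully destroyed.
#' @param neglect_effect scalar: expected CoC when the neglect region is fully
#'   destroyed.
#' @param noise_sd non-negative scalar: SD of Gaussian noise added to the
#'   latent miss probability and latent CoC before clipping.
#' @param seed integer seed governing the behavioural noise.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(territory, critical_masks, neglect_mask = NULL,
                             effect_size = 2, neglect_effect = 0.8,
                             noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(territory, "territory_model"))
  if (!is.list(critical_masks)) critical_masks <- list(critical_masks)
  gs <- territory$grid_shape
  for (m in critical_masks)
    if (!identical(dim(m), as.integer(gs)))
      stop("critical mask grid does not match the territory grid")
  if (is.null(neglect_mask)) neglect_mask <- array(0L, gs)
  if (!identical(dim(neglect_mask), as.integer(gs)))
    stop("neglect mask grid does not match the territory grid")
  stopifnot(effect_size >= 0, noise_sd >= 0)
  structure(list(territory = territory,
                 critical_masks = lapply(critical_masks, function(m) (m != 0) * 1L),
                 neglect_mask = (neglect_mask != 0) * 1L,
                 effect_size = effect_size, neglect_effect = neglect_effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Spherical region of a given volume
#'
#' The `n_voxels` grid voxels nearest to `centre` (Euclidean distance, ties
#' broken by array order): a deterministic, connected, roughly spherical blob
#' used to define ground-truth regions.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @param centre voxel coordinate of the region centre.
#' @param n_voxels region volume in voxels.
#' @return A binary 3-D array.
#' @export
ball_region <- function(grid_shape, centre, n_voxels) {
  stopifnot(n_voxels >= 1, n_voxels <= prod(grid_shape))
  d <- voxel_distance_map(grid_shape, centre)
  cut <- sort(as.vector(d), partial = n_voxels)[n_voxels]
  sel <- which(d <= cut)
  sel <- sel[order(d[sel])][seq_len(n_voxels)]
  out <- array(0L, as.integer(grid_shape))
  out[sel] <- 1L
  out
}

#' Default coupled extinction + neglect ground truth
#'
#' A 30-voxel critical region slightly lateral to the territory centre and a
#' 30-voxel neglect region displaced so that roughly a third of its voxels
#' overlap the critical region, giving correlated extinction and neglect
#' scores as observed clinically.
#'
#' @inheritParams simulation_truth
#' @export
default_truth <- function(territory, effect_size = 2, neglect_effect = 0.8,
                          noise_sd = 0.1, seed = 1L) {
  ctr <- territory$centre
  crit <- ball_region(territory$grid_shape, ctr + c(2, 0, 0), 30L)
  negl <- ball_region(territory$grid_shape, ctr + c(2, 3, 0), 30L)
  simulation_truth(territory, crit, negl, effect_size = effect_size,
                   neglect_effect = neglect_effect, noise_sd = noise_sd,
                   seed = seed)
}

# Grow one lesion by centre-biased region growing. `weights` is the
# exp(-decay * distance) map; growth samples the frontier proportionally to
# it, so every lesion is a single 26-connected component whose mass leans
# towards the territory centre.
grow_lesion <- function(territory, weights, target_size) {
  dim3 <- territory$grid_shape
  nvox <- prod(dim3)
  lesion <- logical(nvox)
  in_frontier <- logical(nvox)
  seed_vox <- sample.int(nvox, 1L, prob = weights)
  lesion[seed_vox] <- TRUE
  frontier <- neighbours26(seed_vox, dim3)
  in_frontier[frontier] <- TRUE
  size <- 1L
  while (size < target_size && length(frontier)) {
    pick <- if (length(frontier) == 1L) 1L else
      sample.int(length(frontier), 1L, prob = weights[frontier])
    v <- frontier[pick]
    frontier <- frontier[-pick]
    in_frontier[v] <- FALSE
    lesion[v] <- TRUE
    size <- size + 1L
    nb <- neighbours26(v, dim3)
    nb <- nb[!lesion[nb] & !in_frontier[nb]]
    if (length(nb)) {
      in_frontier[nb] <- TRUE
      frontier <- c(frontier, nb)
    }
  }
  array(as.integer(lesion), dim3)
}

#' Simulate a cohort of contiguous lesions
#'
#' Each subject's lesion is grown from a random seed voxel by centre-biased
#' region growing (frontier voxels accepted with probability proportional to
#' `exp(-decay * distance)`), which guarantees a single 26-connected component
#' and reproduces the centre-to-periphery lesion-frequency gradient. Lesion
#' volumes are drawn log-uniformly within the territory's `size_range`.
#'
#' @param n_subjects number of subjects (may be 0).
#' @param territory a [territory_model()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A [lesion_dataset()] with identity affine.
#' @export
simulate_lesions <- function(n_subjects, territory = territory_model(),
                             seed = 1L) {
  stopifnot(n_subjects >= 0, inherits(territory, "territory_model"))
  weights <- as.vector(exp(-territory$decay *
                             voxel_distance_map(territory$grid_shape,
                                                territory$centre)))
  masks <- with_rng(seed, {
    lapply(seq_len(n_subjects), function(i) {
      lo <- log(territory$size_range[1])
      hi <- log(territory$size_range[2])
      target <- as.integer(round(exp(stats::runif(1, lo, hi))))
      grow_lesion(territory, weights, max(1L, target))
    })
  })
  ids <- sprintf("sub-%03d", seq_len(n_subjects))
  lesion_dataset(masks, subject_ids = ids,
                 grid_shape = territory$grid_shape)
}

# Fraction of `region` voxels covered by `mask` (0 if the region is empty).
lesion_load <- function(mask, region) {
  tot <- sum(region != 0)
  if (tot == 0) return(0)
  sum(mask != 0 & region != 0) / tot
}

#' Latent behaviour from lesions and ground truth
#'
#' Maps each subject's lesion to a latent bilateral contralesional miss
#' probability and a latent expected CoC. The extinction load is the maximum
#' lesioned fraction over the critical masks (network semantics); the neglect
#' load is the lesioned fraction of the neglect mask. Gaussian noise of SD
#' `noise_sd` is added before clipping to the valid ranges.
#'
#' @param lesions a [lesion_dataset()].
#' @param truth a [simulation_truth()] on the same grid.
#' @return A data frame with columns `subject_id`, `critical_load`,
#'   `neglect_load`, `miss_prob` (in \[0,1\]) and `coc_expect` (in \[-1,1\]).
#' @export
simulate_behaviour <- function(lesions, truth) {
  stopifnot(inherits(lesions, "lesion_dataset"),
            inherits(truth, "simulation_truth"))
  if (!identical(lesions$grid_shape, truth$territory$grid_shape))
    stop("lesion grid does not match the truth grid")
  n <- length(lesions$subject_ids)
  load_c <- vapply(lesions$masks, function(m)
    max(vapply(truth$critical_masks, function(r) lesion_load(m, r), 0)), 0)
  load_n <- vapply(lesions$masks, function(m)
    lesion_load(m, truth$neglect_mask), 0)
  with_rng(truth$seed, {
    miss <- clip(truth$effect_size * load_c +
                   stats::rnorm(n, 0, truth$noise_sd), 0, 1)
    coc <- clip(truth$neglect_effect * load_n +
                  stats::rnorm(n, 0, truth$noise_sd), -1, 1)
    data.frame(subject_id = lesions$subject_ids,
               critical_load = load_c, neglect_load = load_n,
               miss_prob = miss, coc_expect = coc,
               stringsAsFactors = FALSE)
  })
}

#' Construct a confrontation-testing record
#'
#' Trial-level outcome of the bedside confrontation protocol: unilateral
#' left (contralesional), unilateral right (ipsilesional) and bilateral
#' finger-movement trials.
#'
#' @param hits_uni_left,hits_uni_right detected movements in the unilateral
#'   conditions.
#' @param n_uni_left,n_uni_right,n_bilateral trial counts per condition.
#' @param bilateral_outcomes logical matrix with `n_bilateral` rows and
#'   columns `ipsi`, `contra`: detection of each movement on bilateral trials.
#' @return An object of class `confrontation_record`.
#' @export
confrontation_record <- function(hits_uni_left, hits_uni_right,
                                 bilateral_outcomes,
                                 n_uni_left = 10L, n_uni_right = 10L,
                                 n_bilateral = nrow(bilateral_outcomes)) {
  stopifnot(hits_uni_left >= 0, hits_uni_left <= n_uni_left,
            hits_uni_right >= 0, hits_uni_right <= n_uni_right)
  bilateral_outcomes <- as.matrix(bilateral_outcomes)
  if (nrow(bilateral_outcomes) != n_bilateral)
    stop("`bilateral_outcomes` must have one row per bilateral trial")
  if (n_bilateral > 0) {
    stopifnot(ncol(bilateral_outcomes) == 2L)
    colnames(bilateral_outcomes) <- c("ipsi", "contra")
  }
  structure(list(n_uni_left = as.integer(n_uni_left),
                 n_uni_right = as.integer(n_uni_right),
                 n_bilateral = as.integer(n_bilateral),
                 hits_uni_left = as.integer(hits_uni_left),
                 hits_uni_right = as.integer(hits_uni_right),
                 bilateral_outcomes = bilateral_outcomes),
            class = "confrontation_record")
}

#' Simulate a confrontation assessment
#'
#' Draws the standard protocol (10 unilateral left, 10 unilateral right, 10
#' bilateral trials by default) from per-trial Bernoulli outcomes: bilateral
#' contralesional misses with probability `miss_prob`, unilateral
#' contralesional misses with probability `uni_miss_prob` (spatial neglect
#' affects unilateral performance too; this drives the assessability screen),
#' and ipsilesional misses on bilateral trials with probability
#' `ipsi_miss_prob` (such trials are excluded from the extinction score).
#'
#' @param miss_prob probability of missing the contralesional movement on a
#'   bilateral trial.
#' @param n_trials_per_condition trials per condition (0 gives empty record).
#' @param uni_miss_prob probability of missing a unilateral contralesional
#'   movement.
#' @param ipsi_miss_prob probability of missing the ipsilesional movement on
#'   a bilateral trial.
#' @param seed integer seed (NULL draws from the current RNG stream).
#' @return A [confrontation_record()].
#' @export
simulate_confrontation <- function(miss_prob, n_trials_per_condition = 10L,
                                   uni_miss_prob = 0, ipsi_miss_prob = 0,
                                   seed = NULL) {
  stopifnot(miss_prob >= 0, miss_prob <= 1,
            uni_miss_prob >= 0, uni_miss_prob <= 1,
            ipsi_miss_prob >= 0, ipsi_miss_prob <= 1,
            n_trials_per_condition >= 0)
  n <- as.integer(n_trials_per_condition)
  with_rng(seed, {
    hits_ul <- n - stats::rbinom(1, n, uni_miss_prob)
    hits_ur <- n  # ipsilesional unilateral detection is intact
    bil <- cbind(ipsi = stats::runif(n) >= ipsi_miss_prob,
                 contra = stats::runif(n) >= miss_prob)
    confrontation_record(hits_ul, hits_ur, bil,
                         n_uni_left = n, n_uni_right = n, n_bilateral = n)
  })
}

#' Construct a cancellation sheet
#'
#' @param target_x horizontal target positions normalised to \[-1, 1\] with 0
#'   at the sheet centre.
#' @param cancelled logical vector parallel to `target_x`.
#' @return An object of class `cancellation_sheet`.
#' @export
cancellation_sheet <- function(target_x, cancelled = logical(length(target_x))) {
  stopifnot(length(target_x) >= 1L, length(cancelled) == length(target_x),
            all(target_x >= -1), all(target_x <= 1))
  structure(list(target_x = as.numeric(target_x),
                 cancelled = as.logical(cancelled)),
            class = "cancellation_sheet")
}

#' Evenly spaced symmetric cancellation layout
#'
#' @param n_targets number of targets (35 for a bells-type sheet, 60 for a
#'   letter-type sheet).
#' @export
cancellation_layout <- function(n_targets = 35L) {
  stopifnot(n_targets >= 2L)
  cancellation_sheet(seq(-1, 1, length.out = n_targets))
}

#' Simulate cancellation performance with a target CoC
#'
#' Per-target cancellation probabilities follow a softmax link
#' `p_i = exp(theta * (x_i - max(x)))`, with `theta` solved so that the
#' probability-weighted mean target position equals `expected_coc`. At
#' `expected_coc = 0` every target is cancelled (CoC exactly 0); at
#' `expected_coc = 1` only the rightmost target is cancelled; in between the
#' CoC of the simulated sheet is an approximately unbiased draw around
#' `expected_coc`.
#'
#' @param expected_coc target expectation in \[-1, 1\].
#' @param layout a symmetric [cancellation_sheet()] template (mean target
#'   position 0); its `cancelled` field is ignored.
#' @param seed integer seed (NULL draws from the current RNG stream).
#' @return A [cancellation_sheet()] with the simulated `cancelled` vector.
#' @export
simulate_cancellation <- function(expected_coc, layout = cancellation_layout(),
                                  seed = NULL) {
  stopifnot(inherits(layout, "cancellation_sheet"),
            expected_coc >= -1, expected_coc <= 1)
  x <- layout$target_x
  if (abs(mean(x)) > 1e-8)
    stop("layout must be symmetric about 0 (mean target position is ",
         signif(mean(x), 3), "); expectation calibration is undefined")
  p <- cancellation_link(expected_coc, x)
  with_rng(seed, cancellation_sheet(x, stats::runif(length(x)) < p))
}

# Softmax-link probabilities achieving E[CoC] ~= coc on layout x.
cancellation_link <- function(coc, x) {
  if (coc == 0) return(rep(1, length(x)))
  xr <- if (coc > 0) max(x) else min(x)
  if (abs(coc) >= 1) return(as.numeric(x == xr))
  target_mean <- function(theta) {
    w <- exp(theta * (x - xr))
    sum(x * w) / sum(w)
  }
  # softmax mean is monotone in theta, 0 at theta=0, -> extreme x as |theta|
  # grows; bracket wide enough for near-extreme targets
  sol <- stats::uniroot(function(th) target_mean(th) - coc,
                        interval = if (coc > 0) c(0, 1e4) else c(-1e4, 0),
                        tol = 1e-10)
  exp(sol$root * (x - xr))
}

#' Simulate a complete lesion-behaviour cohort
#'
#' End-to-end generator: lesions, latent behaviour, trial-level confrontation
#' testing, two cancellation sheets (bells-type with 35 targets, letter-type
#' with 60) averaged into one CoC, and a computerised extinction test from
#' which the extinction index is computed. Neglect degrades contralesional
#' detection in unilateral *and* bilateral trials (`uni_miss_prob =
#' neglect_uni_coeff * max(coc, 0)`), whereas extinction adds misses only
#' under bilateral stimulation — the confound structure the nuisance
#' regression is designed to remove.
#'
#' @param n_subjects cohort size.
#' @param territory a [territory_model()].
#' @param truth a [simulation_truth()]; defaults to [default_truth()].
#' @param n_trials trials per condition in both assessments.
#' @param neglect_uni_coeff scaling from latent CoC to unilateral
#'   contralesional miss probability.
#' @param seed master integer seed for the whole cohort.
#' @return A list of class `extinction_cohort`: `lesions`, `truth`, `latents`
#'   and `behaviour` (one row per subject: `subject_id`, `ext_score`, `coc`,
#'   `ext_index`, `assessable`). `ext_score` is `NA` for unassessable
#'   subjects or records with no valid bilateral trial.
#' @export
simulate_cohort <- function(n_subjects = 108L, territory = territory_model(),
                            truth = NULL, n_trials = 10L,
                            neglect_uni_coeff = 0.2, seed = 1L) {
  if (is.null(truth)) truth <- default_truth(territory, seed = seed + 1L)
  lesions <- simulate_lesions(n_subjects, territory, seed = seed)
  lat <- simulate_behaviour(lesions, truth)
  with_rng(seed + 2L, {
    rows <- lapply(seq_len(n_subjects), function(i) {
      p_ext <- lat$miss_prob[i]
      p_uni <- clip(neglect_uni_coeff * max(lat$coc_expect[i], 0), 0, 1)
      p_bil <- 1 - (1 - p_ext) * (1 - p_uni)
      rec <- simulate_confrontation(p_bil, n_trials, uni_miss_prob = p_uni)
      ok <- screen_assessability(rec)
      score <- tryCatch(compute_extinction_score(rec),
                        error = function(e) NA_real_)
      bells <- simulate_cancellation(lat$coc_expect[i], cancellation_layout(35L))
      letters <- simulate_cancellation(lat$coc_expect[i], cancellation_layout(60L))
      coc <- average_coc(compute_coc_or_zero(bells), compute_coc_or_zero(letters))
      # computerised test: unilateral and bilateral proportions correct
      h_ul <- 1 - stats::rbinom(1, n_trials, p_uni) / n_trials
      h_ur <- 1
      h_bl <- 1 - stats::rbinom(1, n_trials, p_bil) / n_trials
      h_br <- 1
      idx <- compute_extinction_index(h_ul, h_bl, h_ur, h_br)
      data.frame(subject_id = lat$subject_id[i],
                 ext_score = if (ok) score else NA_real_,
                 coc = coc, ext_index = idx, assessable = ok,
                 stringsAsFactors = FALSE)
    })
    behaviour <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subject_id = character(0), ext_score = numeric(0),
                 coc = numeric(0), ext_index = numeric(0),
                 assessable = logical(0))
    structure(list(lesions = lesions, truth = truth, latents = lat,
                   behaviour = behaviour),
              class = "extinction_cohort")
  })
}

# CoC of a sheet, 0 when nothing was cancelled (severity indeterminate; a
# blank simulated sheet is treated as uninformative rather than an error).
compute_coc_or_zero <- function(sheet) {
  if (!any(sheet$cancelled)) 0 else compute_coc(sheet)
}
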