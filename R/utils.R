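# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG seed without touching global RNG state.
# seed = NULL draws from the current stream (used when a caller has already
# fixed the stream for a whole cohort).
with_rng <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Euclidean distance (in voxels) of every voxel from `centre` on a grid.
voxel_distance_map <- function(grid_shape, centre) {
  stopifnot(length(grid_shape) == 3L, length(centre) == 3L)
  dx <- (seq_len(grid_shape[1]) - centre[1])^2
  dy <- (seq_len(grid_shape[2]) - centre[2])^2
  dz <- (seq_len(grid_shape[3]) - centre[3])^2
  sqrt(outer(outer(dx, dy, `+`), dz, `+`))
}

# 26-neighbourhood offsets as a 26 x 3 integer matrix.
offsets26 <- local({
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# Linear indices of the 26-neighbours of linear index `idx` on grid `dim`,
# clipped at the grid boundary.
neighbours26 <- function(idx, dim) {
  ijk <- arrayInd(idx, dim)
  nb <- sweep(offsets26, 2L, as.numeric(ijk), `+`)
  ok <- nb[, 1] >= 1 & nb[, 1] <= dim[1] &
    nb[, 2] >= 1 & nb[, 2] <= dim[2] &
    nb[, 3] >= 1 & nb[, 3] <= dim[3]
  nb <- nb[ok, , drop = FALSE]
  nb[, 1] + (nb[, 2] - 1L) * dim[1] + (nb[, 3] - 1L) * dim[1] * dim[2]
}

# Label 26-connected components of a logical 3-D array.
# Returns an integer array: 0 outside, component id (1..k) inside.
label_components_26 <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  dim3 <- dim(mask)
  labels <- array(0L, dim3)
  todo <- which(mask != 0)
  seen <- logical(length(mask))
  current <- 0L
  for (seed in todo) {
    if (seen[seed]) next
    current <- current + 1L
    stack <- seed
    seen[seed] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      labels[v] <- current
      nb <- neighbours26(v, dim3)
      nb <- nb[mask[nb] != 0 & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        stack <- c(stack, nb)
      }
    }
  }
  labels
}

`%||%` <- function(a, b) if (is.null(a)) b else a
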