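# Shared fixture builders; everything is generated in code at test time.

small_territory <- function(grid = c(12L, 12L, 12L), decay = 0.25,
                            size_range = c(5L, 80L)) {
  territory_model(grid_shape = grid, decay = decay, size_range = size_range)
}

# A confrontation record with the given bilateral outcome pattern.
# `ipsi_miss` bilateral trials have the ipsilesional movement missed;
# `contra_miss` of the remaining trials have the contralesional one missed.
make_record <- function(n_bilateral = 10L, contra_miss = 0L, ipsi_miss = 0L,
                        hits_uni_left = 10L, n_uni = 10L) {
  ipsi <- rep(TRUE, n_bilateral)
  if (ipsi_miss > 0) ipsi[seq_len(ipsi_miss)] <- FALSE
  contra <- rep(TRUE, n_bilateral)
  valid <- which(ipsi)
  if (contra_miss > 0) contra[valid[seq_len(contra_miss)]] <- FALSE
  confrontation_record(hits_uni_left, n_uni, cbind(ipsi, contra),
                       n_uni_left = n_uni, n_uni_right = n_uni)
}

# Hand-rolled Benjamini-Hochberg step-up: independent oracle for
# fdr_threshold (largest k with p_(k) <= k q / m; reject the k smallest).
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  sig <- logical(m)
  if (is.finite(k)) sig[ord[seq_len(k)]] <- TRUE
  sig
}

# Fine-grid trapezoid integration of the Zellner-Siow model-vs-null Bayes
# factor: independent oracle for the adaptive-quadrature engine.
jzs_bf_trapezoid <- function(n, p, R2, rscale = sqrt(2) / 2,
                             n_grid = 400000L) {
  b <- n * rscale^2 / 2
  g <- exp(seq(-25, 32, length.out = n_grid))
  f <- (1 + g)^((n - 1 - p) / 2) * (1 + g * (1 - R2))^(-(n - 1) / 2) *
    sqrt(b) / gamma(0.5) * g^(-1.5) * exp(-b / g)
  sum(diff(g) * (head(f, -1) + tail(f, -1)) / 2)
}

r_squared_of <- function(y, X) {
  f <- stats::lm.fit(cbind(1, X), y)
  1 - sum(f$residuals^2) / sum((y - mean(y))^2)
}

# Voxels inside `region` or 26-adjacent to it.
dilate26 <- function(region) {
  out <- region != 0
  for (v in which(region != 0)) {
    nb <- extmap:::neighbours26(v, dim(region))
    out[nb] <- TRUE
  }
  out
}
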