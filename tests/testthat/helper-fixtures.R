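# Small in-code fixtures and statistical helpers shared across test files.

# hand-built track table: one cell per element of `labels`, radial positions
# given per frame (recycled), frame grid of `dt` hours
make_tracks <- function(labels, r = 200, dt = 0.25, r_s = 200) {
  rows <- do.call(rbind, lapply(seq_along(labels), function(i) {
    lab <- labels[[i]]
    rr <- rep_len(if (is.list(r)) r[[i]] else r, length(lab))
    data.frame(cell_id = rep(i, length(lab)),
               t_h = (seq_along(lab) - 1) * dt,
               r_um = rr, phenotype = lab)
  }))
  as_track_table(rows, spheroid_radius = r_s, frame_interval = dt)
}

# an asymmetric, irreducible test matrix (not the calibrated default)
test_rates <- function() {
  m <- matrix(c(0, .2, .3, .1,
                .4, 0, .1, .2,
                .1, .3, 0, .2,
                .2, .1, .4, 0), 4, 4, byrow = TRUE,
              dimnames = list(PHENOTYPES, PHENOTYPES))
  rate_matrix(m)
}

# cluster (per-cell) standard error of a frame-level proportion, honest under
# within-cell autocorrelation of labels
cluster_se_prop <- function(tracks, label) {
  per_cell <- tapply(tracks$phenotype == label, tracks$cell_id, mean)
  w <- tapply(tracks$phenotype, tracks$cell_id, length)
  p <- sum(per_cell * w) / sum(w)
  # weighted cluster SE
  m <- length(per_cell)
  sqrt(sum((w / mean(w))^2 * (per_cell - p)^2) / (m * (m - 1)))
}

expm_oracle <- function(q, t) {
  skip_if_not_installed("pracma")
  pracma::expm(q * t)
}

# e^(q*t) for very large t via scaling and repeated squaring (direct Pade
# evaluation overflows long before t ~ 1e4 for generator-scale entries)
expm_oracle_long <- function(q, t, doublings = 10) {
  m <- expm_oracle(q, t / 2^doublings)
  for (i in seq_len(doublings)) m <- m %*% m
  m
}
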