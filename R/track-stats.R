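#' Count frame-adjacent phenotype label pairs
#'
#' Tabulates every ordered pair of labels on consecutive frames within a cell,
#' including dwell pairs (`from == to`). Pairs touching an INTERMEDIATE frame
#' (on either side) are dropped, as are INTERMEDIATE frames from the
#' per-phenotype frame totals.
#'
#' @param tracks A [as_track_table()] (or data frame with its columns).
#' @return Object of class `transition_counts`: list with `n` (4x4 count
#'   matrix, rows = from), `frames` (frames observed per phenotype) and
#'   `n_pairs_dropped` (pairs touching INTERMEDIATE).
#' @export
count_transitions <- function(tracks) {
  bad <- !tracks$phenotype %in% c(PHENOTYPES, INTERMEDIATE) |
    is.na(tracks$phenotype)
  if (any(bad))
    stop("unlabeled rows for cell_ids: ",
         paste(unique(tracks$cell_id[bad]), collapse = ", "), call. = FALSE)
  pairs <- frame_pairs(tracks)
  keep <- pairs$from != INTERMEDIATE & pairs$to != INTERMEDIATE
  n <- table(factor(pairs$from[keep], PHENOTYPES),
             factor(pairs$to[keep], PHENOTYPES))
  n <- matrix(as.numeric(n), 4, 4, dimnames = list(PHENOTYPES, PHENOTYPES))
  frames <- table(factor(tracks$phenotype[tracks$phenotype != INTERMEDIATE],
                         PHENOTYPES))
  frames <- stats::setNames(as.numeric(frames), PHENOTYPES)
  structure(list(n = n, frames = frames, n_pairs_dropped = sum(!keep)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Frame-pair transition counts (incl. dwell; rows = from):\n")
  print(x$n)
  cat("Frames per phenotype:\n"); print(x$frames)
  if (x$n_pairs_dropped)
    cat(x$n_pairs_dropped, "pairs touching INTERMEDIATE dropped\n")
  invisible(x)
}

#' Estimate a transition-rate matrix from frame-pair counts
#'
#' Discrete-time maximum-likelihood rates: `rate[X, Y] =
#' n[X, Y] / (frames[X] * frame_interval)` for X != Y, the probability of
#' observing the transition per frame divided by the frame interval. For
#' rates well below `1/frame_interval` this approximates the continuous-time
#' rate; the leading bias is of order `rate * frame_interval`.
#'
#' @param counts A [count_transitions()] result.
#' @param frame_interval Frame interval, h.
#' @return Object of class `rate_estimate`: list with `rates` (4x4 matrix,
#'   `NA` rows for phenotypes never observed), `fractions` (share of frames
#'   per phenotype), `unobserved` (labels never seen), `counts`,
#'   `frame_interval`.
#' @export
estimate_rates <- function(counts, frame_interval) {
  stopifnot(inherits(counts, "transition_counts"), frame_interval > 0)
  rates <- matrix(NA_real_, 4, 4, dimnames = list(PHENOTYPES, PHENOTYPES))
  seen <- counts$frames > 0
  rates[seen, ] <- counts$n[seen, , drop = FALSE] /
    (counts$frames[seen] * frame_interval)
  diag(rates) <- 0
  unobserved <- PHENOTYPES[!seen]
  if (length(unobserved) && any(counts$n[!seen, ] > 0))
    stop("counts inconsistent: outgoing pairs from a phenotype with no frames",
         call. = FALSE)
  fractions <- counts$frames / sum(counts$frames)
  structure(list(rates = rates, fractions = fractions,
                 unobserved = unobserved, counts = counts,
                 frame_interval = frame_interval),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 4, ...) {
  cat("Estimated transition rates (h^-1; rows = from):\n")
  print(round(x$rates, digits))
  cat("Phenotype fractions:\n"); print(round(x$fractions, digits))
  if (length(x$unobserved))
    cat("Never observed (rates undefined):",
        paste(x$unobserved, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the phenotype-switching kinetics of a tracking table
#'
#' The central estimator: counts frame-adjacent label pairs and converts them
#' to a transition-rate matrix plus phenotype fractions. Returns a model
#' object supporting `coef()` (the rate matrix), `print()`, `summary()`
#' (fractions, stationary law of the fitted rates, enrichment factors) and
#' `simulate()` (agent-based tracks resimulated from the fitted rates).
#'
#' @param tracks A [as_track_table()].
#' @param frame_interval Frame interval, h (taken from the table when
#'   omitted).
#' @return Object of class `phenotype_kinetics`.
#' @examples
#' sim <- simulate_tracks(simulation_config(n_initial_cells = 50,
#'                                          release_flux = 0, seed = 1))
#' fit <- fit_phenotype_kinetics(sim$tracks)
#' coef(fit)
#' @export
fit_phenotype_kinetics <- function(tracks, frame_interval = NULL) {
  frame_interval <- frame_interval_of(tracks, frame_interval)
  counts <- count_transitions(tracks)
  est <- estimate_rates(counts, frame_interval)
  structure(list(rates = est$rates, fractions = est$fractions,
                 unobserved = est$unobserved, counts = counts,
                 frame_interval = frame_interval,
                 spheroid_radius = attr(tracks, "spheroid_radius")),
            class = "phenotype_kinetics")
}

#' @export
coef.phenotype_kinetics <- function(object, ...) object$rates

#' @export
print.phenotype_kinetics <- function(x, digits = 4, ...) {
  cat("Phenotype-switching kinetics fit\n")
  cat(sprintf("  %d frame pairs (incl. dwell), frame interval %g h\n",
              sum(x$counts$n), x$frame_interval))
  cat("Transition rates (h^-1; rows = from):\n")
  print(round(x$rates, digits))
  invisible(x)
}

#' @export
summary.phenotype_kinetics <- function(object, ...) {
  full <- length(object$unobserved) == 0L && all(is.finite(object$rates))
  out <- list(
    rates = object$rates,
    fractions = object$fractions,
    stationary = if (full) stationary_distribution(rate_matrix(object$rates))
                 else NULL,
    enrichment = if (full) enrichment_factors(rate_matrix(object$rates))
                 else NULL,
    mean_dwell_h = if (full) {
      ex <- rowSums(object$rates)
      sum(object$fractions) / sum(object$fractions * ex)
    } else NA_real_,
    n_pairs = sum(object$counts$n), unobserved = object$unobserved)
  class(out) <- "summary.phenotype_kinetics"
  out
}

#' @export
print.summary.phenotype_kinetics <- function(x, digits = 4, ...) {
  cat("Phenotype-switching kinetics fit (", x$n_pairs, " frame pairs)\n", sep = "")
  cat("Transition rates (h^-1):\n"); print(round(x$rates, digits))
  cat("Observed fractions:\n"); print(round(x$fractions, digits))
  if (!is.null(x$stationary)) {
    cat("Stationary law of fitted rates:\n"); print(round(x$stationary, digits))
    cat("Enrichment factors (in/out):\n"); print(round(x$enrichment, digits))
    cat(sprintf("Population mean time between transitions: %.3f h\n",
                x$mean_dwell_h))
  }
  if (length(x$unobserved))
    cat("Never observed:", paste(x$unobserved, collapse = ", "), "\n")
  invisible(x)
}

#' @export
simulate.phenotype_kinetics <- function(object, nsim = 1, seed = NULL, ...,
                                        config_args = list()) {
  if (is.null(seed)) stop("a seed is required", call. = FALSE)
  if (length(object$unobserved))
    stop("cannot simulate: rates undefined for ",
         paste(object$unobserved, collapse = ", "), call. = FALSE)
  args <- utils::modifyList(
    list(rates = rate_matrix(object$rates), seed = seed,
         spheroid_radius = if (is.null(object$spheroid_radius)) 200
                           else object$spheroid_radius),
    config_args)
  sims <- lapply(seq_len(nsim), function(i) {
    args$seed <- seed + i - 1L
    simulate_tracks(do.call(simulation_config, args))
  })
  if (nsim == 1L) sims[[1L]] else sims
}

#' Per-phenotype radial step statistics
#'
#' Radial displacements between consecutive frames, attributed to the label
#' held at the earlier frame (steps starting on an INTERMEDIATE frame are
#' excluded).
#'
#' @param tracks A [as_track_table()].
#' @param breaks Passed to [graphics::hist()] for the per-phenotype
#'   histograms (computed, not plotted).
#' @return Object of class `step_stats`: list with `table` (data frame of
#'   phenotype, n, mean, sd), `steps` (named list of raw step vectors) and
#'   `histograms`.
#' @export
step_statistics <- function(tracks, breaks = "Sturges") {
  pairs <- frame_pairs(tracks)
  pairs <- pairs[pairs$from != INTERMEDIATE, ]
  steps <- split(pairs$dr, factor(pairs$from, PHENOTYPES))
  tab <- data.frame(
    phenotype = PHENOTYPES,
    n = vapply(steps, length, integer(1)),
    mean = vapply(steps, function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1)),
    sd = vapply(steps, function(s) if (length(s) > 1) stats::sd(s) else
                  NA_real_, numeric(1)),
    row.names = NULL)
  hists <- lapply(steps, function(s)
    if (length(s)) graphics::hist(s, breaks = breaks, plot = FALSE) else NULL)
  structure(list(table = tab, steps = steps, histograms = hists),
            class = "step_stats")
}

#' @export
print.step_stats <- function(x, digits = 3, ...) {
  cat("Radial step statistics by starting phenotype (um/frame):\n")
  tab <- x$table
  tab$mean <- round(tab$mean, digits); tab$sd <- round(tab$sd, digits)
  print(tab)
  invisible(x)
}

#' @export
plot.step_stats <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2)); on.exit(graphics::par(op))
  for (p in PHENOTYPES) {
    s <- x$steps[[p]]
    if (length(s))
      graphics::hist(s, breaks = 30, freq = FALSE, main = p,
                     xlab = expression(Delta * r ~ (mu * m)), ...)
    else { graphics::plot.new(); graphics::title(main = paste(p, "(no steps)")) }
  }
  invisible(x)
}

#' Pooled autocorrelation of per-cell radial steps
#'
#' Pearson correlation of the pooled pairs (step_i, step_(i+lag)) within
#' cells, for each lag. A white-noise (memoryless) walk gives correlations of
#' order `1/sqrt(n)` at every positive lag.
#'
#' @param tracks A [as_track_table()].
#' @param max_lag Largest lag, in frames.
#' @return Data frame with `lag`, `correlation` (`NA` where undefined, e.g.
#'   zero variance or too few pairs) and `n_pairs`.
#' @export
step_autocorrelation <- function(tracks, max_lag = 10) {
  pairs <- frame_pairs(tracks)
  series <- split(pairs$dr, pairs$cell_id)
  out <- data.frame(lag = seq_len(max_lag), correlation = NA_real_,
                    n_pairs = 0L)
  for (lag in seq_len(max_lag)) {
    a <- unlist(lapply(series, function(s)
      if (length(s) > lag) s[seq_len(length(s) - lag)] else numeric(0)),
      use.names = FALSE)
    b <- unlist(lapply(series, function(s)
      if (length(s) > lag) s[-seq_len(lag)] else numeric(0)),
      use.names = FALSE)
    out$n_pairs[lag] <- length(a)
    if (length(a) > 2 && stats::sd(a) > 0 && stats::sd(b) > 0)
      out$correlation[lag] <- stats::cor(a, b)
  }
  out
}

#' Mean radial position of a phenotype at a frame time
#'
#' @param tracks A [as_track_table()].
#' @param phenotype Phenotype label.
#' @param t Frame time, h.
#' @return Mean `r_um` over cells carrying the label at that frame
#'   (`NA` with attribute `empty = TRUE` when no such cell exists).
#' @export
mean_radial_position <- function(tracks, phenotype, t) {
  assert_phenotype(phenotype, allow_intermediate = TRUE)
  r <- tracks$r_um[tracks$phenotype == phenotype &
                     abs(tracks$t_h - t) < 1e-9]
  if (!length(r)) return(structure(NA_real_, empty = TRUE))
  mean(r)
}

#' Mean radial position of every phenotype over time
#'
#' @param tracks A [as_track_table()].
#' @return Data frame with `t_h`, `phenotype`, `mean_r_um`, `n`.
#' @export
radial_position_series <- function(tracks) {
  keep <- tracks$phenotype != INTERMEDIATE
  agg <- stats::aggregate(tracks$r_um[keep],
                          list(t_h = tracks$t_h[keep],
                               phenotype = tracks$phenotype[keep]),
                          FUN = mean)
  cnt <- stats::aggregate(tracks$r_um[keep],
                          list(t_h = tracks$t_h[keep],
                               phenotype = tracks$phenotype[keep]),
                          FUN = length)
  out <- data.frame(t_h = agg$t_h, phenotype = agg$phenotype,
                    mean_r_um = agg$x, n = cnt$x)
  out[order(out$t_h, match(out$phenotype, PHENOTYPES)), ]
}

#' Radial cell-density profile in annuli
#'
#' Per-phenotype cell density in annular bins anchored at the spheroid
#' boundary: `rho_i = N_i / (pi * (r_(i+1)^2 - r_i^2))` where `N_i` is the
#' number of cells of the phenotype whose radial position falls in the
#' half-open bin `[r_i, r_(i+1))`.
#'
#' @param tracks A [as_track_table()].
#' @param t Frame time at which to take the snapshot, h.
#' @param bin_width Bin width, um (default 50).
#' @param r_s Spheroid radius, um (from the table when omitted).
#' @return Object of class `density_profile`: data frame with `r_lo`, `r_hi`,
#'   `phenotype`, `n`, `density` (cells/um^2).
#' @export
density_profile <- function(tracks, t, bin_width = 50, r_s = NULL) {
  r_s <- spheroid_radius_of(tracks, r_s)
  snap <- tracks[abs(tracks$t_h - t) < 1e-9 &
                   tracks$phenotype != INTERMEDIATE, ]
  r_max <- if (nrow(snap)) max(snap$r_um) else r_s
  edges <- seq(r_s, r_s + bin_width * max(1, ceiling((r_max - r_s) /
                                                       bin_width + 1e-12)),
               by = bin_width)
  if (length(edges) < 2L) edges <- c(r_s, r_s + bin_width)
  nb <- length(edges) - 1L
  out <- expand.grid(bin = seq_len(nb), phenotype = PHENOTYPES,
                     stringsAsFactors = FALSE)
  out$r_lo <- edges[out$bin]; out$r_hi <- edges[out$bin + 1L]
  out$n <- 0
  if (nrow(snap)) {
    idx <- findInterval(snap$r_um, edges, rightmost.closed = FALSE,
                        left.open = FALSE)
    idx[idx > nb] <- NA # beyond the last edge (cannot occur by construction)
    cnt <- table(factor(idx, seq_len(nb)),
                 factor(snap$phenotype, PHENOTYPES))
    out$n <- as.numeric(cnt[cbind(out$bin, match(out$phenotype, PHENOTYPES))])
  }
  out$density <- out$n / (pi * (out$r_hi^2 - out$r_lo^2))
  out$bin <- NULL
  structure(out[c("r_lo", "r_hi", "phenotype", "n", "density")],
            t = t, r_s = r_s, class = c("density_profile", "data.frame"))
}

#' Space-time enrichment field of a phenotype
#'
#' On a grid of frame times and annuli of width `annulus` anchored at the
#' spheroid boundary, computes `(P(r, t) - P) / P`, where `P(r, t)` is the
#' phenotype's fraction among cells in the annulus `[r, r + annulus)` at time
#' `t` and `P` is its global fraction over all cells and all frames.
#' INTERMEDIATE frames are excluded from numerator and denominator.
#'
#' @param tracks A [as_track_table()].
#' @param phenotype Phenotype of interest (default `"FP"`).
#' @param annulus Annulus width, um (default 50).
#' @param sliding If `TRUE`, annuli slide by `step` um instead of being
#'   disjoint.
#' @param step Sliding step, um (default `annulus / 5`).
#' @param r_s Spheroid radius, um.
#' @return Object of class `enrichment_field`: data frame with `t_h`, `r_lo`,
#'   `r_hi`, `n` and `value` (`NA` where the annulus holds no cell), plus the
#'   global fraction as attribute `global_fraction`.
#' @export
enrichment_field <- function(tracks, phenotype = "FP", annulus = 50,
                             sliding = FALSE, step = annulus / 5,
                             r_s = NULL) {
  assert_phenotype(phenotype)
  r_s <- spheroid_radius_of(tracks, r_s)
  keep <- tracks$phenotype != INTERMEDIATE
  lab <- tracks$phenotype[keep]; r <- tracks$r_um[keep]; tt <- tracks$t_h[keep]
  if (!length(lab)) stop("no classified cells in the track table", call. = FALSE)
  p_global <- mean(lab == phenotype)
  if (p_global == 0)
    stop("global fraction of ", phenotype, " is zero: enrichment undefined",
         call. = FALSE)
  r_max <- max(r)
  starts <- if (sliding) seq(r_s, max(r_s, r_max), by = step)
            else seq(r_s, r_s + annulus * max(1, ceiling((r_max - r_s) /
                                                           annulus + 1e-12)),
                     by = annulus)
  starts <- starts[starts <= r_max | starts == r_s]
  times <- sort(unique(tt))
  grid <- expand.grid(t_h = times, r_lo = starts)
  grid$r_hi <- grid$r_lo + annulus
  res <- mapply(function(t0, lo, hi) {
    inb <- abs(tt - t0) < 1e-9 & r >= lo & r < hi
    n <- sum(inb)
    c(n, if (n) (mean(lab[inb] == phenotype) - p_global) / p_global
      else NA_real_)
  }, grid$t_h, grid$r_lo, grid$r_hi)
  grid$n <- res[1, ]; grid$value <- res[2, ]
  structure(grid, global_fraction = p_global, phenotype = phenotype,
            r_s = r_s, class = c("enrichment_field", "data.frame"))
}

#' Filopodial depletion statistic near the spheroid boundary
#'
#' `P_full - P_near`: the phenotype's fraction over all disseminated cells
#' (all frames in the chosen time window) minus its fraction among cells
#' within `zone` um of the spheroid boundary. Positive values mean the
#' phenotype is depleted near the boundary relative to the bulk. Also
#' reports the cohort mean invasion depth over the same window.
#'
#' @param tracks A [as_track_table()].
#' @param phenotype Phenotype of interest (default `"FP"`).
#' @param zone Near-boundary zone width, um (default 50).
#' @param window Length of the trailing time window pooled, h (default 4;
#'   `Inf` pools the whole run).
#' @param r_s Spheroid radius, um.
#' @return Object of class `depletion_stat`: list with `statistic`
#'   (`p_full - p_near`), `p_full`, `p_near`, `mean_depth_um`, `n_full`,
#'   `n_near`. `p_near` is `NA` (flagged `empty_zone`) when the zone holds no
#'   cell.
#' @export
fp_depletion <- function(tracks, phenotype = "FP", zone = 50, window = 4,
                         r_s = NULL) {
  assert_phenotype(phenotype)
  r_s <- spheroid_radius_of(tracks, r_s)
  t_max <- max(tracks$t_h)
  keep <- tracks$phenotype != INTERMEDIATE & tracks$t_h > t_max - window
  lab <- tracks$phenotype[keep]
  depth <- tracks$r_um[keep] - r_s
  if (!length(lab)) stop("no classified cells in the window", call. = FALSE)
  near <- depth < zone
  p_full <- mean(lab == phenotype)
  p_near <- if (any(near)) mean(lab[near] == phenotype) else NA_real_
  out <- list(statistic = p_full - p_near, p_full = p_full, p_near = p_near,
              mean_depth_um = mean(depth), n_full = length(lab),
              n_near = sum(near), phenotype = phenotype, zone = zone,
              window = window)
  if (!any(near)) attr(out, "empty_zone") <- TRUE
  class(out) <- "depletion_stat"
  out
}

#' @export
print.depletion_stat <- function(x, ...) {
  cat(sprintf(paste0("%s depletion near the boundary: P_full - P_near = ",
                     "%.4f (P_full = %.4f, P_near = %.4f)\n"),
              x$phenotype, x$statistic, x$p_full, x$p_near))
  cat(sprintf("Mean invasion depth %.1f um over %d frame rows (%d in zone)\n",
              x$mean_depth_um, x$n_full, x$n_near))
  invisible(x)
}

#' Linear fit of the depletion statistic against invasion depth
#'
#' Ordinary least squares of `P_full - P_near` on the cohort mean invasion
#' depth across several track tables (or precomputed [fp_depletion()]
#' results), the dashed-line fit of the depletion-versus-depth relation.
#'
#' @param depletions List of [fp_depletion()] results, or list of track
#'   tables (each is reduced with `...` arguments first).
#' @param ... Passed to [fp_depletion()] when `depletions` holds track
#'   tables.
#' @return Object of class `depletion_fit`: list with `fit` (the `lm`),
#'   `slope` (per um), `intercept` and `data`.
#' @export
fit_depletion <- function(depletions, ...) {
  stats_list <- lapply(depletions, function(d)
    if (inherits(d, "depletion_stat")) d else fp_depletion(d, ...))
  dat <- data.frame(
    mean_depth_um = vapply(stats_list, `[[`, numeric(1), "mean_depth_um"),
    statistic = vapply(stats_list, `[[`, numeric(1), "statistic"))
  fit <- stats::lm(statistic ~ mean_depth_um, data = dat)
  structure(list(fit = fit, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), data = dat),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf(paste0("Depletion vs invasion depth over %d cohorts: slope ",
                     "%.3g per um, intercept %.3g\n"),
              nrow(x$data), x$slope, x$intercept))
  invisible(x)
}

#' @export
plot.depletion_fit <- function(x, ...) {
  graphics::plot(x$data$mean_depth_um, x$data$statistic,
                 xlab = "mean invasion depth (um)",
                 ylab = expression(P[full] - P[near]), pch = 19, ...)
  graphics::abline(x$fit, lty = 2)
  invisible(x)
}

#' Time-resolved enrichment factor near the spheroid boundary
#'
#' Within consecutive time windows, estimates in-zone transition rates from
#' frame pairs whose earlier frame lies within `zone` um of the boundary,
#' then forms the enrichment factor (total in-rate over total out-rate) of
#' the phenotype. Under boundary-suppressed transitions into FP, the FP
#' series decreases after the ramp starts.
#'
#' @param tracks A [as_track_table()].
#' @param phenotype Phenotype of interest (default `"FP"`).
#' @param zone Zone width, um (default 50).
#' @param window Window length, h (default 4).
#' @param frame_interval Frame interval, h.
#' @param r_s Spheroid radius, um.
#' @return Data frame with `t_lo`, `t_hi`, `t_mid`, `n_pairs` and `value`
#'   (`NA` where the window has no usable pairs or the out-rate is zero).
#' @export
time_resolved_enrichment <- function(tracks, phenotype = "FP", zone = 50,
                                     window = 4, frame_interval = NULL,
                                     r_s = NULL) {
  assert_phenotype(phenotype)
  r_s <- spheroid_radius_of(tracks, r_s)
  dt <- frame_interval_of(tracks, frame_interval)
  pairs <- frame_pairs(tracks)
  pairs <- pairs[pairs$from != INTERMEDIATE & pairs$to != INTERMEDIATE &
                   (pairs$r_um - r_s) < zone, ]
  t_max <- max(tracks$t_h)
  edges <- seq(0, t_max + window * 1e-9, by = window)
  if (edges[length(edges)] < t_max) edges <- c(edges, t_max)
  out <- data.frame(t_lo = edges[-length(edges)], t_hi = edges[-1])
  out$t_mid <- (out$t_lo + out$t_hi) / 2
  out$n_pairs <- 0L; out$value <- NA_real_
  others <- setdiff(PHENOTYPES, phenotype)
  for (i in seq_len(nrow(out))) {
    w <- pairs[pairs$t_h >= out$t_lo[i] & pairs$t_h < out$t_hi[i], ]
    out$n_pairs[i] <- nrow(w)
    if (!nrow(w)) next
    n <- table(factor(w$from, PHENOTYPES), factor(w$to, PHENOTYPES))
    frames <- table(factor(w$from, PHENOTYPES))
    if (frames[phenotype] == 0 || any(frames[others] == 0)) next
    rate_in <- n[others, phenotype] / (as.numeric(frames[others]) * dt)
    rate_out <- n[phenotype, others] / (as.numeric(frames[phenotype]) * dt)
    if (sum(rate_out) > 0)
      out$value[i] <- enrichment_factor(rate_in, rate_out)
  }
  out
}
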