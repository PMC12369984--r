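#' Migration phenotype labels
#'
#' The four dynamical migration phenotypes of disseminating breast cancer
#' cells: blebbing (BB), actin-enriched pseudopodial (AE), lamellipodial (LA)
#' and filopodial (FP). Tracking tables may additionally carry an
#' `"INTERMEDIATE"` label for frames whose morphology could not be assigned to
#' one of the four states; kinetics operations ignore it.
#'
#' @format Character vector of length 4.
#' @export
PHENOTYPES <- c("BB", "AE", "LA", "FP")

#' Observation label for unclassified frames
#' @rdname PHENOTYPES
#' @export
INTERMEDIATE <- "INTERMEDIATE"

assert_phenotype <- function(x, allow_intermediate = FALSE) {
  ok <- if (allow_intermediate) c(PHENOTYPES, INTERMEDIATE) else PHENOTYPES
  if (length(x) != 1L || !x %in% ok)
    stop("phenotype must be one of ", paste(ok, collapse = ", "),
         " (got ", deparse(x), ")", call. = FALSE)
  x
}

#' Construct a phenotype transition-rate matrix
#'
#' A `rate_matrix` holds the 12 off-diagonal transition rates
#' \eqn{r_{X \to Y}} (in h\eqn{^{-1}}) between the four migration phenotypes.
#' Rows are source states, columns destination states; the diagonal is fixed
#' at zero (exit rates are always recomputed as row sums).
#'
#' @param x 4x4 numeric matrix with `PHENOTYPES` dimnames (any row/column
#'   order), or an unnamed 4x4 matrix taken to be in BB, AE, LA, FP order.
#' @return Object of class `rate_matrix`: a 4x4 matrix, zero diagonal,
#'   nonnegative finite entries.
#' @seealso [calibrate_default_rates()], [stationary_distribution()]
#' @export
rate_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(dim(x) != 4L))
    stop("a rate matrix must be a 4x4 numeric matrix", call. = FALSE)
  if (is.null(dimnames(x))) {
    dimnames(x) <- list(PHENOTYPES, PHENOTYPES)
  } else {
    if (!setequal(rownames(x), PHENOTYPES) || !setequal(colnames(x), PHENOTYPES))
      stop("rate matrix dimnames must be the phenotypes ",
           paste(PHENOTYPES, collapse = ", "), call. = FALSE)
    x <- x[PHENOTYPES, PHENOTYPES]
  }
  diag(x) <- 0
  if (any(!is.finite(x)) || any(x < 0))
    stop("transition rates must be finite and nonnegative", call. = FALSE)
  structure(x, class = c("rate_matrix", "matrix", "array"))
}

#' @export
print.rate_matrix <- function(x, digits = 4, ...) {
  cat("Phenotype transition-rate matrix (h^-1; rows = from, cols = to)\n")
  print(round(unclass(x), digits), ...)
  cat("Exit rates:",
      paste(sprintf("%s %.3g", PHENOTYPES, exit_rates(x)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Total exit rate of each phenotype
#'
#' @param rates A [rate_matrix()].
#' @return Named numeric vector of row sums (h^-1).
#' @export
exit_rates <- function(rates) {
  rowSums(unclass(rate_matrix(rates)))
}

#' Build the infinitesimal generator from a rate matrix
#'
#' Off-diagonal entries are the transition rates; each diagonal entry is minus
#' the state's exit rate, so rows sum to zero.
#'
#' @inheritParams exit_rates
#' @return 4x4 generator matrix Q with zero row sums.
#' @export
generator_matrix <- function(rates) {
  q <- unclass(rate_matrix(rates))
  diag(q) <- -rowSums(q)
  q
}

# Strong connectivity of the >0 transition graph; returns character vector of
# "X -> Y" pairs that are unreachable, empty if irreducible.
unreachable_pairs <- function(rates) {
  adj <- unclass(rates) > 0
  reach <- adj | diag(4) > 0
  for (k in 1:4) # Floyd-Warshall transitive closure on a 4-node graph
    reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  bad <- which(!reach, arr.ind = TRUE)
  if (nrow(bad) == 0L) return(character(0))
  paste(PHENOTYPES[bad[, 1]], "->", PHENOTYPES[bad[, 2]])
}

#' Stationary phenotype composition of a rate matrix
#'
#' Solves \eqn{\pi Q = 0}, \eqn{\sum \pi = 1} for the unique stationary
#' probability vector of the continuous-time phenotype chain, where Q is the
#' generator built from the rates.
#'
#' @inheritParams exit_rates
#' @return Named probability vector over BB, AE, LA, FP (sums to 1).
#' @examples
#' stationary_distribution(calibrate_default_rates())
#' @export
stationary_distribution <- function(rates) {
  rates <- rate_matrix(rates)
  bad <- unreachable_pairs(rates)
  if (length(bad))
    stop("rate matrix is reducible; unreachable transitions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  q <- generator_matrix(rates)
  a <- rbind(t(q), rep(1, 4))
  pi_hat <- qr.solve(a, c(0, 0, 0, 0, 1))
  pi_hat <- pi_hat / sum(pi_hat)
  names(pi_hat) <- PHENOTYPES
  if (any(pi_hat < -1e-12))
    stop("stationary solve produced negative probabilities", call. = FALSE)
  pmax(pi_hat, 0) / sum(pmax(pi_hat, 0))
}

#' Calibrate a default rate matrix from population-level facts
#'
#' Constructs the simplest rate matrix with a prescribed stationary
#' composition and overall transition tempo: every rate into state Y is
#' proportional to Y's target stationary fraction,
#' \eqn{r_{X \to Y} = k\,\pi_Y}, with the constant k chosen so that the
#' population-averaged total transition rate
#' \eqn{\sum_X \pi_X (\mathrm{exit\ rate\ of\ } X)} equals
#' `1 / mean_transition_interval`. This gives
#' \eqn{k = (1/\tau) / (1 - \sum_X \pi_X^2)}.
#'
#' The defaults encode the observed population facts for spheroid-derived
#' MDA-MB-231 cells: blebbing cells make up 1/3 of the population,
#' actin-enriched pseudopodial cells 1/6, with about one phenotype transition
#' every 2 h. The LA/FP split of the remaining mass is not pinned down by
#' those facts and defaults to an even 1/4 each.
#'
#' @param target_fractions Named probability vector over the four phenotypes
#'   (default `c(BB = 1/3, AE = 1/6, LA = 1/4, FP = 1/4)`). All entries must
#'   be strictly positive (a zero fraction would disconnect the chain).
#' @param mean_transition_interval Mean time between transitions, h
#'   (default 2).
#' @return A [rate_matrix()] whose [stationary_distribution()] equals
#'   `target_fractions`.
#' @export
calibrate_default_rates <- function(target_fractions = c(BB = 1/3, AE = 1/6,
                                                         LA = 1/4, FP = 1/4),
                                    mean_transition_interval = 2) {
  p <- target_fractions
  if (is.null(names(p)) && length(p) == 4L) names(p) <- PHENOTYPES
  if (!setequal(names(p), PHENOTYPES))
    stop("target_fractions must be named with the four phenotypes", call. = FALSE)
  p <- p[PHENOTYPES]
  if (any(p <= 0))
    stop("all target fractions must be > 0; a zero fraction for ",
         paste(names(p)[p <= 0], collapse = ", "),
         " would make the chain reducible", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("target fractions must sum to 1", call. = FALSE)
  if (!is.numeric(mean_transition_interval) || mean_transition_interval <= 0)
    stop("mean_transition_interval must be a positive time in hours", call. = FALSE)
  k <- (1 / mean_transition_interval) / (1 - sum(p^2))
  m <- k * matrix(p, 4, 4, byrow = TRUE, dimnames = list(PHENOTYPES, PHENOTYPES))
  rate_matrix(m)
}

#' Space-time modulation schedule for transitions into a phenotype
#'
#' Describes the suppression of transition rates into one phenotype (by
#' default FP) for cells close to the spheroid boundary: within `zone_width`
#' um of the boundary, rates into the target are left unchanged up to
#' `t_start`, then ramp linearly down, reaching zero at `t_end`. As printed,
#' the ramp factor for the default window is \eqn{(24 - t)/18}, which is
#' discontinuous at t = 8 h (it jumps from 1 to 16/18); set
#' `continuous_ramp = TRUE` to use \eqn{(t_{end} - t)/(t_{end} - t_{start})}
#' instead, which starts at exactly 1.
#'
#' @param zone_width Width of the modulated zone, um from the spheroid
#'   boundary (default 50). Zone membership is strict: depth < `zone_width`.
#' @param t_start Ramp start, h (default 8).
#' @param t_end Time at which the modulated rates reach 0, h (default 24).
#' @param target Phenotype whose in-rates are modulated (default `"FP"`).
#' @param continuous_ramp Use the continuous ramp denominator
#'   `t_end - t_start` instead of the printed constant 18 (default FALSE).
#' @param direction `"into"` (default) modulates transitions into `target`;
#'   `"out_of"` modulates transitions out of it (an alternative reading of
#'   which rates are suppressed, kept as an option).
#' @return Object of class `modulation_schedule`.
#' @export
modulation_schedule <- function(zone_width = 50, t_start = 8, t_end = 24,
                                target = "FP", continuous_ramp = FALSE,
                                direction = c("into", "out_of")) {
  direction <- match.arg(direction)
  assert_phenotype(target)
  if (!(zone_width > 0)) stop("zone_width must be > 0", call. = FALSE)
  if (!(t_start >= 0 && t_start < t_end))
    stop("need 0 <= t_start < t_end", call. = FALSE)
  structure(list(zone_width = zone_width, t_start = t_start, t_end = t_end,
                 target = target, continuous_ramp = isTRUE(continuous_ramp),
                 direction = direction),
            class = "modulation_schedule")
}

#' @export
print.modulation_schedule <- function(x, ...) {
  cat(sprintf(paste0("Modulation schedule: rates %s %s ramp to 0 over t = ",
                     "(%g, %g] h within %g um of the spheroid boundary\n"),
              if (x$direction == "into") "into" else "out of",
              x$target, x$t_start, x$t_end, x$zone_width))
  cat(sprintf("Ramp factor: (%g - t)/%g for t > %g\n", x$t_end,
              if (x$continuous_ramp) x$t_end - x$t_start else 18, x$t_start))
  invisible(x)
}

#' Ramp factor of a modulation schedule
#'
#' Vectorized over `t` and `depth`. Returns the multiplicative factor applied
#' to the modulated rates: 1 outside the zone or before `t_start`, otherwise
#' `(t_end - t)/denom` clipped below at 0, where `denom` is 18 (printed form)
#' or `t_end - t_start` when `continuous_ramp` is set.
#'
#' @param schedule A [modulation_schedule()] or `NULL` (no modulation).
#' @param t Time(s), h; must be >= 0.
#' @param depth Distance(s) to the spheroid boundary, um; must be >= 0.
#' @return Numeric vector of factors in \\[0, 1\\].
#' @export
modulation_factor <- function(schedule, t, depth) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  n <- max(length(t), length(depth))
  if (is.null(schedule)) return(rep(1, n))
  stopifnot(inherits(schedule, "modulation_schedule"))
  t <- rep_len(t, n); depth <- rep_len(depth, n)
  denom <- if (schedule$continuous_ramp) schedule$t_end - schedule$t_start else 18
  f <- rep(1, n)
  on <- depth < schedule$zone_width & t > schedule$t_start
  f[on] <- pmax(0, (schedule$t_end - t[on]) / denom)
  f
}

#' Modulated transition rate at a given time and depth
#'
#' The effective rate \eqn{\tilde r_{X \to Y}(t, d)}: equal to the base rate
#' unless the pair is covered by the schedule (destination equals the
#' schedule's target for the default `"into"` direction, the cell is within
#' the zone, and `t > t_start`), in which case the base rate is multiplied by
#' the linear ramp factor of [modulation_factor()].
#'
#' @inheritParams exit_rates
#' @param schedule A [modulation_schedule()] or `NULL`.
#' @param from,to Source and destination phenotypes.
#' @param t Time, h (>= 0); vectorized.
#' @param depth Distance to the spheroid boundary, um (>= 0); vectorized.
#' @return Effective rate(s), h^-1.
#' @examples
#' r <- calibrate_default_rates()
#' s <- modulation_schedule()
#' modulated_rate(r, s, "BB", "FP", t = 16, depth = 20) # ramped by 8/18
#' @export
modulated_rate <- function(rates, schedule, from, to, t, depth) {
  rates <- rate_matrix(rates)
  assert_phenotype(from); assert_phenotype(to)
  base <- rates[from, to]
  if (is.null(schedule)) {
    if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
    if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
    return(rep_len(base, max(length(t), length(depth))))
  }
  covered <- if (schedule$direction == "into") to == schedule$target
             else from == schedule$target
  f <- modulation_factor(schedule, t, depth)
  if (!covered) f[] <- 1
  base * f
}

#' Enrichment factor of a phenotype
#'
#' Ratio of the total transition rate into a phenotype to the total rate out
#' of it. Values above 1 mean the phenotype accumulates; below 1 it depletes.
#'
#' @param rates_in Numeric vector of rates into the phenotype (one per source
#'   state), h^-1.
#' @param rates_out Numeric vector of rates out of the phenotype (one per
#'   destination state), h^-1; must have positive sum.
#' @return Dimensionless ratio `sum(rates_in) / sum(rates_out)`. A zero total
#'   in-rate gives 0; a zero total out-rate is an error (the ratio is
#'   undefined).
#' @export
enrichment_factor <- function(rates_in, rates_out) {
  if (any(rates_in < 0) || any(rates_out < 0))
    stop("rates must be nonnegative", call. = FALSE)
  tot_out <- sum(rates_out)
  if (tot_out <= 0)
    stop("total out-rate is zero: enrichment factor undefined", call. = FALSE)
  sum(rates_in) / tot_out
}

#' Enrichment factors of all phenotypes of a (possibly modulated) rate matrix
#'
#' @inheritParams exit_rates
#' @param schedule Optional [modulation_schedule()]; when given, `t` and
#'   `depth` locate the evaluation point.
#' @param t,depth Evaluation time (h) and depth (um) when a schedule is used.
#' @return Named numeric vector of in/out rate ratios per phenotype.
#' @export
enrichment_factors <- function(rates, schedule = NULL, t = 0, depth = Inf) {
  rates <- rate_matrix(rates)
  eff <- unclass(rates)
  if (!is.null(schedule)) {
    for (from in PHENOTYPES) for (to in PHENOTYPES) if (from != to)
      eff[from, to] <- modulated_rate(rates, schedule, from, to, t,
                                      min(depth, .Machine$double.xmax))
  }
  vapply(PHENOTYPES, function(p) {
    enrichment_factor(eff[setdiff(PHENOTYPES, p), p],
                      eff[p, setdiff(PHENOTYPES, p)])
  }, numeric(1))
}
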