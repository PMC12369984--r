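#' Default phenotype speeds and diffusivities from a step model
#'
#' Speeds are the mean radial step divided by the frame interval (e.g. FP:
#' 4.5 um / 0.25 h = 18 um/h). Diffusivities use the standard variance
#' mapping `D = sd^2 / (2 * frame_interval)` (e.g. FP ~ 69.6 um^2/h).
#'
#' @param steps A [step_model()].
#' @return Named numeric vector, um/h (speeds) or um^2/h (diffusivities).
#' @export
step_speeds <- function(steps = step_model()) {
  stopifnot(inherits(steps, "step_model"))
  steps$mean / steps$frame_interval
}

#' @rdname step_speeds
#' @export
step_diffusivities <- function(steps = step_model()) {
  stopifnot(inherits(steps, "step_model"))
  steps$sd^2 / (2 * steps$frame_interval)
}

#' Parameters of the phenotype-density continuum model
#'
#' The model evolves four phenotype densities along a ray from the spheroid:
#' reaction terms exchange density between phenotypes at the (possibly
#' depth/time-modulated) transition rates, and a Heaviside-gated advection
#' term transports each phenotype outward at its own speed only where its
#' density decreases outward, so cells always move away from the spheroid.
#' A constant flux injects cells of every phenotype at the boundary; the far
#' boundary is absorbing.
#'
#' @param rates A [rate_matrix()] (default [calibrate_default_rates()]).
#' @param speeds Named per-phenotype speeds, um/h (default [step_speeds()]).
#' @param flux Boundary influx per phenotype, cells/h (default 4; equal for
#'   all phenotypes).
#' @param schedule A [modulation_schedule()] or `NULL`.
#' @param diffusion Named per-phenotype diffusivities, um^2/h (default 0;
#'   use [step_diffusivities()] for the step-variance values).
#' @param r_s Spheroid radius, um (default 200).
#' @param r_max Outer edge of the domain, um (default `r_s + 1000`).
#' @param dr Grid spacing, um (default 5).
#' @param dt Time step, h; default from the CFL condition with safety factor
#'   0.5 (`dt = 0.5 * dr / max(speeds)`, further limited by the diffusive
#'   stability bound when diffusion is on, and capped at 0.05 h so the
#'   reaction terms stay well resolved).
#' @param duration Integration time, h (default 24).
#' @param advection `"upwind"` (default): conservative first-order upwind
#'   with outward-only interface fluxes `v * rho[i]`, which cannot move mass
#'   toward the spheroid by construction, conserves cell number exactly and
#'   converges under grid refinement. `"gated"`: the transport term written
#'   pointwise with the Heaviside gate, `-H(-d rho/dr) v d rho/dr` by
#'   backward differences, frozen wherever the local gradient is positive
#'   (H(0) = 0); faithful to the model equation as written, but
#'   non-conservative wherever the profile is locally increasing (see the
#'   package vignette).
#' @return Object of class `continuum_params`.
#' @export
continuum_params <- function(rates = calibrate_default_rates(),
                             speeds = step_speeds(), flux = 4,
                             schedule = NULL, diffusion = 0, r_s = 200,
                             r_max = r_s + 1000, dr = 5, dt = NULL,
                             duration = 24,
                             advection = c("upwind", "gated")) {
  advection <- match.arg(advection)
  rates <- rate_matrix(rates)
  if (length(speeds) == 1L) speeds <- stats::setNames(rep(speeds, 4), PHENOTYPES)
  if (length(diffusion) == 1L)
    diffusion <- stats::setNames(rep(diffusion, 4), PHENOTYPES)
  stopifnot(setequal(names(speeds), PHENOTYPES),
            setequal(names(diffusion), PHENOTYPES))
  speeds <- speeds[PHENOTYPES]; diffusion <- diffusion[PHENOTYPES]
  stopifnot(all(speeds >= 0), all(diffusion >= 0), flux >= 0, dr > 0,
            r_max > r_s, duration > 0)
  if (!is.null(schedule)) stopifnot(inherits(schedule, "modulation_schedule"))
  if (is.null(dt)) {
    dt <- 0.05
    if (max(speeds) > 0) dt <- min(dt, 0.5 * dr / max(speeds))
    if (max(diffusion) > 0) dt <- min(dt, 0.25 * dr^2 / max(diffusion))
  }
  if (max(speeds) * dt / dr > 1 + 1e-12)
    stop(sprintf("CFL violation: max(v)*dt/dr = %.3g > 1",
                 max(speeds) * dt / dr), call. = FALSE)
  if (max(diffusion) * dt / dr^2 > 0.5 + 1e-12)
    stop("diffusive stability violated: need D*dt/dr^2 <= 1/2", call. = FALSE)
  structure(list(rates = rates, speeds = speeds, flux = flux,
                 schedule = schedule, diffusion = diffusion, r_s = r_s,
                 r_max = r_max, dr = dr, dt = dt, duration = duration,
                 advection = advection),
            class = "continuum_params")
}

#' Initial (empty) continuum state
#'
#' Densities live at cell centers `r_s + (i - 1/2) dr`; the state is a nodes
#' x 4 matrix of linear densities (cells per um of ray).
#'
#' @param params A [continuum_params()].
#' @return Object of class `continuum_state`: list with `r` (node centers,
#'   um), `rho` (nodes x 4 density matrix) and `t` (h).
#' @export
continuum_state <- function(params) {
  n <- floor((params$r_max - params$r_s) / params$dr)
  r <- params$r_s + (seq_len(n) - 0.5) * params$dr
  structure(list(r = r,
                 rho = matrix(0, n, 4, dimnames = list(NULL, PHENOTYPES)),
                 t = 0),
            class = "continuum_state")
}

# reaction increment (density/h): pairwise exchange, conserves total density
# exactly (every term enters once positively and once negatively)
reaction_terms <- function(rho, rates, schedule, depth, t) {
  base <- unclass(rates)
  f <- modulation_factor(schedule, t, depth) # per-node ramp factor
  react <- matrix(0, nrow(rho), 4, dimnames = dimnames(rho))
  into <- is.null(schedule) || schedule$direction == "into"
  target <- if (is.null(schedule)) NA_character_ else schedule$target
  for (from in PHENOTYPES) for (to in PHENOTYPES) {
    if (from == to || base[from, to] == 0) next
    fac <- if (!is.null(schedule) &&
               ((into && to == target) || (!into && from == target))) f else 1
    flow <- rho[, from] * base[from, to] * fac
    react[, to] <- react[, to] + flow
    react[, from] <- react[, from] - flow
  }
  react
}

#' Advance the continuum state by one time step
#'
#' Explicit first-order update: reaction terms evaluated from the (possibly
#' modulated) rates at each node's depth and the current time; outward
#' advection per `params$advection` (conservative upwind by default, or the
#' pointwise Heaviside-gated transport term); optional diffusion by central
#' differences (reflecting inner, absorbing outer boundary); the boundary
#' flux enters the first cell (`flux * dt / dr` for the conservative scheme;
#' the flux-matching inlet `(flux - v * rho[1]) * dt / dr` for the gated
#' scheme); free outflow at the outer edge.
#'
#' @param state A [continuum_state()].
#' @param params A [continuum_params()].
#' @return The advanced `continuum_state`.
#' @export
step_continuum <- function(state, params) {
  stopifnot(inherits(state, "continuum_state"),
            inherits(params, "continuum_params"))
  if (max(params$speeds) * params$dt / params$dr > 1 + 1e-12)
    stop("CFL violation: max(v)*dt/dr > 1", call. = FALSE)
  rho <- state$rho
  n <- nrow(rho)
  dt <- params$dt; dr <- params$dr
  depth <- state$r - params$r_s
  new <- rho + dt * reaction_terms(rho, params$rates, params$schedule,
                                   depth, state$t)
  gated <- identical(params$advection, "gated")
  for (p in PHENOTYPES) {
    v <- params$speeds[[p]]
    x <- rho[, p]
    if (v > 0) {
      if (gated) {
        # pointwise -H(-grad) v grad with backward differences; frozen on
        # locally increasing stretches (H(0) = 0); inlet cell obeys the
        # flux-matching condition d rho_1 = (F - v rho_1)/dr
        grad <- diff(x) / dr
        new[-1, p] <- new[-1, p] + dt * ifelse(grad < 0, -v * grad, 0)
        new[1, p] <- new[1, p] + dt * (params$flux - v * x[1]) / dr
      } else {
        # conservative upwind: outward-only interface flux v*rho[i];
        # absorbing outer ghost, injection into the first cell
        fl <- v * x
        new[, p] <- new[, p] + dt / dr * (c(0, fl[-n]) - fl)
        new[1, p] <- new[1, p] + params$flux * dt / dr
      }
    } else {
      new[1, p] <- new[1, p] + params$flux * dt / dr
    }
    d <- params$diffusion[[p]]
    if (d > 0) {
      up <- c(x[-1], 0)           # absorbing outer ghost
      down <- c(x[1], x[-n])      # reflecting inner ghost
      new[, p] <- new[, p] + d * dt / dr^2 * (up - 2 * x + down)
    }
  }
  if (any(new < -1e-9))
    stop("negative density after update: time step too large for the rates",
         call. = FALSE)
  new[new < 0] <- 0
  structure(list(r = state$r, rho = new, t = state$t + dt),
            class = "continuum_state")
}

#' Integrate the continuum model and track invasion depths
#'
#' Runs [step_continuum()] from an empty initial state for
#' `params$duration` hours, recording the density-weighted mean invasion
#' depth of each phenotype,
#' `dbar_X(t) = sum((r - r_s) * rho_X) / sum(rho_X)`, and profile snapshots.
#'
#' @param params A [continuum_params()].
#' @param save_every Interval between saved snapshots, h (default 1).
#' @return Object of class `continuum_fit`: list with `depth` (data frame
#'   `t_h`, one column per phenotype, um), `profiles` (data frame `t_h`,
#'   `r_um`, `phenotype`, `density` at the saved times), `mass` (total cells
#'   in the domain per saved time) and `params`.
#' @examples
#' fit <- run_continuum(continuum_params(duration = 6))
#' tail(fit$depth, 1)
#' @export
run_continuum <- function(params, save_every = 1) {
  state <- continuum_state(params)
  n_steps <- ceiling(params$duration / params$dt - 1e-9)
  # hit the duration exactly by shrinking the last step if needed
  times <- unique(c(seq(0, params$duration, by = save_every), params$duration))
  depth_rows <- list(); prof_rows <- list(); mass <- numeric(0)
  record <- function(state) {
    d <- vapply(PHENOTYPES, function(p) {
      tot <- sum(state$rho[, p])
      if (tot > 0) sum((state$r - params$r_s) * state$rho[, p]) / tot
      else NA_real_
    }, numeric(1))
    depth_rows[[length(depth_rows) + 1L]] <<- c(t_h = state$t, d)
    mass <<- c(mass, sum(state$rho) * params$dr)
    prof_rows[[length(prof_rows) + 1L]] <<- data.frame(
      t_h = state$t, r_um = rep(state$r, 4),
      phenotype = rep(PHENOTYPES, each = length(state$r)),
      density = as.vector(state$rho))
  }
  record(state)
  next_save <- 2L
  for (s in seq_len(n_steps)) {
    if (state$t >= params$duration - 1e-12) break
    p_step <- params
    if (state$t + params$dt > params$duration)
      p_step$dt <- params$duration - state$t
    state <- step_continuum(state, p_step)
    while (next_save <= length(times) &&
           state$t >= times[next_save] - 1e-9) {
      record(state); next_save <- next_save + 1L
    }
  }
  depth <- as.data.frame(do.call(rbind, depth_rows))
  structure(list(depth = depth, profiles = do.call(rbind, prof_rows),
                 mass = data.frame(t_h = depth$t_h, cells = mass),
                 final_state = state, params = params),
            class = "continuum_fit")
}

#' @export
print.continuum_fit <- function(x, ...) {
  last <- x$depth[nrow(x$depth), ]
  cat(sprintf("Continuum run to t = %g h (%d nodes, dr = %g um, dt = %.4g h)\n",
              last$t_h, length(x$final_state$r), x$params$dr, x$params$dt))
  cat("Mean invasion depth at end (um):\n")
  print(round(unlist(last[PHENOTYPES]), 2))
  cat(sprintf("Total cells in domain: %.2f (injected: %.2f)\n",
              x$mass$cells[nrow(x$mass)], 4 * x$params$flux * last$t_h))
  invisible(x)
}

#' @export
plot.continuum_fit <- function(x, which = c("depth", "profiles"), ...) {
  which <- match.arg(which)
  cols <- c(BB = "forestgreen", AE = "goldenrod2", LA = "steelblue",
            FP = "magenta3")
  if (which == "depth") {
    graphics::matplot(x$depth$t_h, as.matrix(x$depth[PHENOTYPES]),
                      type = "l", lty = 1, lwd = 2, col = cols,
                      xlab = "t (h)", ylab = "mean invasion depth (um)", ...)
    graphics::legend("topleft", legend = PHENOTYPES, col = cols, lty = 1,
                     lwd = 2, bty = "n")
  } else {
    pr <- x$profiles[x$profiles$t_h == max(x$profiles$t_h), ]
    graphics::plot(range(pr$r_um), range(pr$density), type = "n",
                   xlab = "r (um)", ylab = "density (cells/um)", ...)
    for (p in PHENOTYPES)
      graphics::lines(pr$r_um[pr$phenotype == p],
                      pr$density[pr$phenotype == p], col = cols[p], lwd = 2)
    graphics::legend("topright", legend = PHENOTYPES, col = cols, lty = 1,
                     lwd = 2, bty = "n")
  }
  invisible(x)
}
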