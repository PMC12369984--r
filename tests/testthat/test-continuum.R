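test_that("null state stays null and reaction terms conserve density", {
  p <- continuum_params(flux = 0, duration = 1)
  s <- continuum_state(p)
  s2 <- step_continuum(s, p)
  expect_true(all(s2$rho == 0))

  # discrete reaction terms sum to zero across phenotypes, identically
  p2 <- continuum_params(schedule = modulation_schedule())
  s <- continuum_state(p2)
  set.seed(73)
  s$rho[] <- runif(length(s$rho))
  s$t <- 12
  react <- mesoinvasion:::reaction_terms(s$rho, p2$rates, p2$schedule,
                                         s$r - p2$r_s, s$t)
  expect_true(all(abs(rowSums(react)) < 1e-12))
})

test_that("with v = 0 node compositions follow the matrix-exponential oracle", {
  r <- test_rates()
  q <- generator_matrix(r)
  p <- continuum_params(rates = r, speeds = 0, flux = 0, r_max = 250,
                        dr = 5, dt = 1e-4, duration = 2)
  s <- continuum_state(p)
  init <- c(BB = 0.6, AE = 0.1, LA = 0.2, FP = 0.1)
  s$rho <- matrix(init, nrow(s$rho), 4, byrow = TRUE,
                  dimnames = list(NULL, PHENOTYPES))
  n_steps <- round(2 / p$dt)
  for (i in seq_len(n_steps)) s <- step_continuum(s, p)
  oracle <- drop(init %*% expm_oracle(q, 2))
  for (node in c(1, nrow(s$rho)))
    expect_equal(unname(s$rho[node, ]), unname(oracle), tolerance = 1e-4)

  # long-run composition at every node relaxes to the stationary law
  p_long <- continuum_params(rates = r, speeds = 0, flux = 0, r_max = 250,
                             dr = 5, dt = 0.02, duration = 60)
  s2 <- continuum_state(p_long)
  s2$rho <- matrix(init, nrow(s2$rho), 4, byrow = TRUE,
                   dimnames = list(NULL, PHENOTYPES))
  for (i in seq_len(round(60 / 0.02))) s2 <- step_continuum(s2, p_long)
  pi_hat <- stationary_distribution(r)
  for (node in c(1, nrow(s2$rho)))
    expect_equal(unname(s2$rho[node, ] / sum(s2$rho[node, ])),
                 unname(pi_hat), tolerance = 1e-6)
})

test_that("gated transport freezes uphill stretches; both schemes advect downhill", {
  pg <- continuum_params(rates = rate_matrix(matrix(0, 4, 4)), flux = 0,
                         duration = 1, advection = "gated")
  s <- continuum_state(pg)
  n <- nrow(s$rho)
  # monotonically increasing profile: the gated advection term is
  # identically zero at every interior node (H(0) = 0, positive gradient)
  s$rho[, "FP"] <- seq(0.5, 1, length.out = n)
  s2 <- step_continuum(s, pg)
  expect_equal(s2$rho[2:n, "FP"], s$rho[2:n, "FP"])
  # the inlet cell discharges through the flux-matching boundary (F = 0)
  expect_lt(s2$rho[1, "FP"], s$rho[1, "FP"])

  # monotonically decreasing profile: transported outward by both schemes
  pu <- continuum_params(rates = rate_matrix(matrix(0, 4, 4)), flux = 0,
                         duration = 1, advection = "upwind")
  for (p in list(pg, pu)) {
    s$rho[, "FP"] <- seq(1, 0, length.out = n)
    s3 <- step_continuum(s, p)
    drift <- sum(s3$r * s3$rho[, "FP"]) / sum(s3$rho[, "FP"]) -
      sum(s$r * s$rho[, "FP"]) / sum(s$rho[, "FP"])
    expect_gt(drift, 0)
  }

  # conservative upwind moves mass outward everywhere (never inward),
  # even on an increasing profile
  s$rho[, "FP"] <- seq(0, 1, length.out = n)
  s4 <- step_continuum(s, pu)
  com_before <- sum(s$r * s$rho[, "FP"]) / sum(s$rho[, "FP"])
  kept <- sum(s4$rho[, "FP"]) # outer edge is absorbing
  expect_lte(kept, sum(s$rho[, "FP"]))
  expect_gte(sum(s4$r * s4$rho[, "FP"]) / kept, com_before - 1e-9)

  # CFL violation rejected before any update
  expect_error(continuum_params(speeds = 50, dr = 5, dt = 0.2), "CFL")
})

test_that("mass balance: total cells equal injected flux times time", {
  p <- continuum_params(duration = 24)
  fit <- run_continuum(p)
  expect_lt(abs(fit$mass$cells[nrow(fit$mass)] - 4 * p$flux * 24) /
              (4 * p$flux * 24), 0.001)
  # nonnegativity throughout
  expect_true(all(fit$profiles$density >= 0))
  # with the schedule on as well
  fit2 <- run_continuum(continuum_params(schedule = modulation_schedule(),
                                         duration = 24))
  expect_lt(abs(fit2$mass$cells[nrow(fit2$mass)] - 4 * p$flux * 24) /
              (4 * p$flux * 24), 0.001)
})

test_that("constant rates equalize depths; boundary FP suppression breaks it", {
  # constant rates: per-phenotype offsets are a fixed few-micrometer
  # mixing-length effect, so the four depth curves coincide relative to the
  # advancing front: the relative gap shrinks with time (the full asymptotic
  # coincidence check lives with the longer acceptance run)
  fit <- run_continuum(continuum_params(duration = 48, r_max = 200 + 1500),
                       save_every = 24)
  gap <- apply(as.matrix(fit$depth[-1, PHENOTYPES]), 1,
               function(x) (max(x) - min(x)) / mean(x))
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 0.1)
  d48 <- unlist(fit$depth[nrow(fit$depth), PHENOTYPES])
  expect_lt(diff(range(d48)), 20) # absolute spread stays ~one mixing length

  # schedule on: FP strictly leads every other phenotype at 24 h
  fit_on <- run_continuum(continuum_params(schedule = modulation_schedule(),
                                           duration = 24))
  d_on <- unlist(fit_on$depth[nrow(fit_on$depth), PHENOTYPES])
  expect_true(all(d_on[["FP"]] > d_on[c("BB", "AE", "LA")]))

  # adding step-variance diffusion preserves the FP-leads ordering
  fit_d <- run_continuum(continuum_params(schedule = modulation_schedule(),
                                          diffusion = step_diffusivities(),
                                          duration = 24))
  d_d <- unlist(fit_d$depth[nrow(fit_d$depth), PHENOTYPES])
  expect_true(all(d_d[["FP"]] > d_d[c("BB", "AE", "LA")]))

  # far from the boundary the schedule-on composition is the unmodulated
  # stationary law
  pr <- fit_on$profiles[fit_on$profiles$t_h == 24, ]
  far <- pr[pr$r_um > 300 & pr$r_um < 400, ]
  comp <- tapply(far$density, far$phenotype, sum)
  comp <- as.numeric(comp[PHENOTYPES] / sum(comp))
  pi_hat <- unname(stationary_distribution(calibrate_default_rates()))
  expect_equal(comp, pi_hat, tolerance = 0.05)
})

test_that("halving the grid changes final depths by less than 2 percent", {
  base <- continuum_params(duration = 24)
  fine <- continuum_params(duration = 24, dr = base$dr / 2, dt = base$dt / 2)
  d1 <- unlist(run_continuum(base)$depth[25, PHENOTYPES])
  d2 <- unlist(run_continuum(fine)$depth[25, PHENOTYPES])
  expect_true(all(abs(d1 - d2) / d2 < 0.02))
})

test_that("out-of-FP modulation variant runs and suppresses FP instead", {
  sched <- modulation_schedule(direction = "out_of")
  fit <- run_continuum(continuum_params(schedule = sched, duration = 24))
  expect_true(all(is.finite(unlist(fit$depth[25, PHENOTYPES]))))
})
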