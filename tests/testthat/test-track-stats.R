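test_that("transition counting matches hand counts and drops INTERMEDIATE", {
  tr <- make_tracks(list(c("BB", "BB", "AE", "AE")))
  tc <- count_transitions(tr)
  expect_equal(tc$n["BB", "BB"], 1)
  expect_equal(tc$n["BB", "AE"], 1)
  expect_equal(tc$n["AE", "AE"], 1)
  expect_equal(sum(tc$n), 3)
  expect_equal(tc$frames[["BB"]], 2)
  expect_equal(tc$frames[["AE"]], 2)

  # constant-label track: only dwell pairs, L - 1 of them
  tc2 <- count_transitions(make_tracks(list(rep("FP", 7))))
  expect_equal(sum(tc2$n), 6)
  expect_equal(tc2$n["FP", "FP"], 6)

  # both pairs touching an INTERMEDIATE frame are dropped
  tc3 <- count_transitions(make_tracks(list(c("BB", "INTERMEDIATE", "AE"))))
  expect_equal(sum(tc3$n), 0)
  expect_equal(tc3$n_pairs_dropped, 2)

  # total pairs = sum over cells of (frames - 1) when no INTERMEDIATE
  tr4 <- make_tracks(list(rep("BB", 5), c("LA", "FP", "LA")))
  expect_equal(sum(count_transitions(tr4)$n), 4 + 2)

  expect_error(as_track_table(
    data.frame(cell_id = 1, t_h = 0, r_um = 200, phenotype = "??"),
    spheroid_radius = 200), "cell_ids")
})

test_that("rate estimation: hand example, zero counts, unobserved flags", {
  tr <- make_tracks(list(c("BB", "BB", "AE", "AE")), dt = 0.25)
  est <- estimate_rates(count_transitions(tr), frame_interval = 0.25)
  expect_equal(est$rates["BB", "AE"], 1 / (2 * 0.25)) # = 2 per hour
  expect_equal(est$rates["AE", "BB"], 0)

  # no off-diagonal counts -> all observed rates zero
  est2 <- estimate_rates(count_transitions(make_tracks(list(rep("BB", 4),
                                                            rep("AE", 4)))),
                         0.25)
  expect_true(all(est2$rates[c("BB", "AE"), ] == 0, na.rm = TRUE))
  # LA, FP never observed: undefined with a flag, not zero
  expect_setequal(est2$unobserved, c("LA", "FP"))
  expect_true(all(is.na(est2$rates["LA", c("BB", "AE", "FP")])))
  expect_equal(est2$fractions[["BB"]], 0.5)
})

test_that("rate estimation round-trips against simulated dynamics", {
  # short frames (dwell/16) keep the discretization bias well below the
  # Monte Carlo noise; compare each estimated rate to the exact
  # discrete-time truth expm(Q*dt)/dt within 3 binomial SE, and to the
  # generating rates within 3 SE plus the documented O(r*dt) bias bound
  r <- test_rates()
  dt <- 1 / 16
  sim <- simulate_tracks(simulation_config(
    n_initial_cells = 150, release_flux = 0, duration = 24, rates = r,
    steps = step_model(frame_interval = dt), seed = 47))
  tc <- count_transitions(sim$tracks)
  expect_gt(sum(tc$n), 5e4)
  est <- estimate_rates(tc, dt)
  p_true <- expm_oracle(generator_matrix(r), dt) # frame-step probabilities
  for (from in PHENOTYPES) for (to in setdiff(PHENOTYPES, from)) {
    p_obs <- est$rates[from, to] * dt
    se <- sqrt(p_true[from, to] * (1 - p_true[from, to]) / tc$frames[[from]])
    expect_lt(abs(p_obs - p_true[from, to]), 3 * se)
    bias_bound <- unclass(r)[from, to] * max(exit_rates(r)) * dt
    expect_lt(abs(est$rates[from, to] - unclass(r)[from, to]),
              3 * se / dt + bias_bound)
  }
  # observed fractions agree with the stationary law (cluster SE)
  p <- stationary_distribution(r)
  for (ph in PHENOTYPES)
    expect_lt(abs(est$fractions[[ph]] - p[[ph]]),
              3 * cluster_se_prop(sim$tracks, ph))
})

test_that("kinetics fit object behaves like a model fit", {
  sim <- simulate_tracks(simulation_config(n_initial_cells = 80,
                                           release_flux = 0, seed = 53))
  fit <- fit_phenotype_kinetics(sim$tracks)
  expect_s3_class(fit, "phenotype_kinetics")
  expect_equal(dim(coef(fit)), c(4L, 4L))
  sm <- summary(fit)
  expect_equal(sum(sm$stationary), 1, tolerance = 1e-9)
  expect_output(print(fit), "Transition rates")
  resim <- simulate(fit, seed = 54,
                    config_args = list(n_initial_cells = 5, release_flux = 0,
                                       duration = 2))
  expect_s3_class(resim, "spheroid_sim")
})

test_that("step statistics attribute steps to the starting label", {
  # two-frame track 200 -> 210 labeled LA: one LA step of +10
  tr <- make_tracks(list(c("LA", "FP")), r = list(c(200, 210)))
  st <- step_statistics(tr)
  expect_equal(st$steps$LA, 10)
  expect_equal(length(st$steps$FP), 0L)
  # INTERMEDIATE-start steps excluded
  tr2 <- make_tracks(list(c("INTERMEDIATE", "BB", "BB")),
                     r = list(c(200, 210, 215)))
  st2 <- step_statistics(tr2)
  expect_equal(st2$steps$BB, 5)
  expect_equal(sum(st2$table$n), 1)
  # frozen tracks: all steps zero
  st3 <- step_statistics(make_tracks(list(rep("BB", 6))))
  expect_equal(st3$table$sd[st3$table$phenotype == "BB"], 0)
})

test_that("step autocorrelation flags degenerate series and sees structure", {
  # deterministic constant steps: zero variance, undefined
  tr <- make_tracks(list(rep("BB", 10)), r = list(seq(200, 245, by = 5)))
  ac <- step_autocorrelation(tr, max_lag = 2)
  expect_true(all(is.na(ac$correlation)))
  # alternating +1/-1 steps: lag-1 correlation is -1
  rr <- 201 + c(0, cumsum(rep(c(1, -1), 10)))
  tr2 <- make_tracks(list(rep("BB", length(rr))), r = list(rr))
  ac2 <- step_autocorrelation(tr2, max_lag = 2)
  expect_equal(ac2$correlation[1], -1, tolerance = 1e-9)
  # i.i.d. steps: white-noise null
  set.seed(61)
  rw <- 400 + c(0, cumsum(rnorm(5000)))
  tr3 <- make_tracks(list(rep("BB", length(rw))), r = list(rw), r_s = 200)
  ac3 <- step_autocorrelation(tr3, max_lag = 3)
  expect_true(all(abs(ac3$correlation) < 3 / sqrt(ac3$n_pairs)))
})

test_that("mean radial position per phenotype and time", {
  tr <- make_tracks(list(c("FP", "FP"), c("LA", "LA")),
                    r = list(c(250, 260), c(240, 220)))
  expect_equal(mean_radial_position(tr, "FP", 0), 250)
  expect_equal(mean_radial_position(tr, "FP", 0.25), 260)
  empty <- mean_radial_position(tr, "BB", 0)
  expect_true(is.na(empty))
  expect_true(attr(empty, "empty"))
  rs <- radial_position_series(tr)
  expect_equal(rs$mean_r_um[rs$phenotype == "LA" & rs$t_h == 0.25], 220)
})

test_that("density profile implements the annulus formula and conserves counts", {
  # 3 cells at depths 10, 20, 30 um: all in the first 50-um annulus
  tr <- make_tracks(list("FP", "FP", "FP"), r = list(210, 220, 230))
  dp <- density_profile(tr, t = 0)
  first_fp <- dp$density[dp$phenotype == "FP" & dp$r_lo == 200]
  expect_equal(first_fp, 3 / (pi * (250^2 - 200^2)), tolerance = 1e-12)

  # half-open binning: a cell exactly at an edge belongs to the upper bin
  tr_edge <- make_tracks(list("BB"), r = list(250))
  dpe <- density_profile(tr_edge, t = 0)
  expect_equal(dpe$n[dpe$phenotype == "BB" & dpe$r_lo == 250], 1)
  expect_equal(dpe$n[dpe$phenotype == "BB" & dpe$r_lo == 200], 0)

  # empty table: all-zero profile
  dp0 <- density_profile(make_tracks(list(character(0))), t = 0, r_s = 200)
  expect_true(all(dp0$density == 0))

  # conservation: counts recovered from density * annulus area, exactly
  sim <- simulate_tracks(simulation_config(n_initial_cells = 120,
                                           release_flux = 0, seed = 67))
  dps <- density_profile(sim$tracks, t = 24)
  recovered <- sum(dps$density * pi * (dps$r_hi^2 - dps$r_lo^2))
  expect_equal(recovered, sum(dps$n), tolerance = 1e-9)
  expect_equal(sum(dps$n),
               sum(abs(sim$tracks$t_h - 24) < 1e-9))

  # uniform-area scattering gives a flat profile within Monte Carlo error
  set.seed(71)
  n <- 2e4
  r_uni <- sqrt(runif(n, 200^2, 500^2)) # uniform over annulus area
  tru <- as_track_table(data.frame(cell_id = seq_len(n), t_h = 0,
                                   r_um = r_uni, phenotype = "BB"),
                        spheroid_radius = 200, frame_interval = 0.25)
  dpu <- density_profile(tru, t = 0)
  dens <- dpu$density[dpu$phenotype == "BB" & dpu$r_hi <= 500]
  expected <- n / (pi * (500^2 - 200^2))
  ns <- dpu$n[dpu$phenotype == "BB" & dpu$r_hi <= 500]
  expect_true(all(abs(dens - expected) / expected < 3 / sqrt(pmax(ns, 1))))
})

test_that("enrichment field normalizes by the global fraction", {
  # all cells FP: field is 0 wherever defined
  tr <- make_tracks(list(rep("FP", 3), rep("FP", 3)),
                    r = list(c(210, 260, 310), c(220, 270, 320)))
  ef <- enrichment_field(tr)
  expect_true(all(ef$value[!is.na(ef$value)] == 0))
  expect_equal(attr(ef, "global_fraction"), 1)
  # no FP anywhere: error
  tr2 <- make_tracks(list(rep("BB", 3)))
  expect_error(enrichment_field(tr2), "zero")
  # empty annuli flagged NA
  tr3 <- make_tracks(list(c("FP", "BB")), r = list(c(210, 350)))
  ef3 <- enrichment_field(tr3)
  expect_true(any(is.na(ef3$value)))
  # hand check: one FP among two cells in the annulus, global P = 1/2
  tr4 <- make_tracks(list("FP", "BB", "BB", "FP"),
                     r = list(210, 220, 310, 320))
  ef4 <- enrichment_field(tr4)
  v <- ef4$value[ef4$r_lo == 200]
  expect_equal(v, (0.5 - 0.5) / 0.5)
})

test_that("depletion statistic and its regression on invasion depth", {
  # spatially uniform labels: statistic ~ 0 (exactly 0 for identical mix)
  tr <- make_tracks(list("FP", "BB", "FP", "BB"),
                    r = list(210, 220, 310, 320))
  d <- fp_depletion(tr, window = Inf)
  expect_equal(d$statistic, 0)
  # all FP outside the zone, none inside: statistic = P_full
  tr2 <- make_tracks(list("BB", "BB", "FP", "FP"),
                     r = list(210, 230, 310, 320))
  d2 <- fp_depletion(tr2, window = Inf)
  expect_equal(d2$p_near, 0)
  expect_equal(d2$statistic, d2$p_full)
  expect_equal(d2$p_full, 0.5)
  # invariant under relabeling of non-FP phenotypes among themselves
  tr3 <- make_tracks(list("BB", "AE", "FP", "LA"),
                     r = list(210, 230, 310, 320))
  relabeled <- tr3
  map <- c(BB = "LA", AE = "BB", LA = "AE", FP = "FP")
  relabeled$phenotype <- unname(map[relabeled$phenotype])
  expect_equal(fp_depletion(tr3, window = Inf)$statistic,
               fp_depletion(relabeled, window = Inf)$statistic)
  # empty zone flagged
  tr4 <- make_tracks(list("FP"), r = list(300))
  expect_true(is.na(fp_depletion(tr4, window = Inf)$p_near))
  # OLS fit across cohorts recovers a constructed linear trend
  mk <- function(stat, depth) structure(
    list(statistic = stat, mean_depth_um = depth), class = "depletion_stat")
  fit <- fit_depletion(list(mk(0.01, 50), mk(0.05, 100), mk(0.09, 150)))
  expect_equal(fit$slope, 0.0008, tolerance = 1e-9)
})

test_that("time-resolved enrichment is flat without modulation, falls with it", {
  sched <- modulation_schedule()
  sims_on <- lapply(1:6, function(i) simulate_tracks(
    simulation_config(release_flux = 12, schedule = sched, seed = 400 + i)))
  em <- vapply(sims_on, function(s)
    time_resolved_enrichment(s$tracks, window = 8)$value, numeric(3))
  # windows: (0,8], (8,16], (16,24]; FP enrichment falls across the ramp
  expect_equal(dim(em), c(3L, 6L))
  drop_late <- em[1, ] - em[3, ]
  expect_gt(mean(drop_late),
            3 * sd(drop_late) / sqrt(length(drop_late)))
  # schedule off: no systematic change across the well-populated later
  # windows (the sparse first window carries a small-sample ratio bias)
  sims_off <- lapply(1:6, function(i) simulate_tracks(
    simulation_config(release_flux = 12, seed = 500 + i)))
  em0 <- vapply(sims_off, function(s)
    time_resolved_enrichment(s$tracks, window = 8)$value, numeric(3))
  diff0 <- em0[2, ] - em0[3, ]
  expect_lt(abs(mean(diff0)), 3 * sd(diff0) / sqrt(length(diff0)))
})

test_that("schedule-on invasion puts FP ahead of LA at the final frame", {
  fp_minus_la <- function(seed, schedule) {
    sim <- simulate_tracks(simulation_config(release_flux = 10,
                                             schedule = schedule,
                                             seed = seed))
    mean_radial_position(sim$tracks, "FP", 24) -
      mean_radial_position(sim$tracks, "LA", 24)
  }
  on <- vapply(1:5, function(i) fp_minus_la(600 + i, modulation_schedule()),
               numeric(1))
  off <- vapply(1:5, function(i) fp_minus_la(700 + i, NULL), numeric(1))
  # with the schedule the gap is large and systematic; without it is not
  expect_gt(mean(on) - mean(off),
            3 * sqrt(var(on) / 5 + var(off) / 5))
  expect_true(all(on > 0))
})
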