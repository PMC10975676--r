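short_sched <- function(len = 60) light_schedule(c("light", "dark"), len)

test_that("a simulator with no motion sources produces zero displacement", {
  p <- track_sim_params(bout_rate_per_s = 0, rest_jitter_mm = 0,
                        startle_peak_mm_s = 0, cruise_speed_mm_s = 0,
                        schedule = short_sched(), seed = 1)
  sim <- simulate_track(p)
  expect_equal(diff(range(sim$track$frames$x_mm)), 0)
  expect_equal(diff(range(sim$track$frames$y_mm)), 0)
  expect_true(all(sim$truth$state == "rest"))
})

test_that("identical seeds give bit-identical tracks, different seeds differ", {
  p <- track_sim_params(schedule = short_sched(), seed = 9)
  a <- simulate_track(p)
  b <- simulate_track(p)
  expect_identical(a$track$frames, b$track$frames)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_track(track_sim_params(schedule = short_sched(), seed = 10))
  expect_false(identical(a$track$frames, c_$track$frames))
})

test_that("simulated positions respect the arena and planted speeds", {
  p <- track_sim_params(seed = 5, schedule = short_sched(120))
  sim <- simulate_track(p)
  r <- sqrt(sim$track$frames$x_mm^2 + sim$track$frames$y_mm^2)
  expect_lte(max(r), p$arena_radius + 1e-9)
  kin <- frame_kinematics(sim$track, motion_config())
  # ground-truth rest frames move less than the 0.2 mm swim step
  rest <- sim$truth$state == "rest" & !is.na(kin$step_mm)
  expect_lt(max(kin$step_mm[rest]), 0.2)
  # non-reflected swim frames realize their planned speed exactly, so
  # cruise-phase frames travel at >= cruise speed (startle ramps aside)
  swim <- sim$truth$state == "swim" & !sim$truth$reflected &
    !is.na(kin$speed_mm_s)
  expect_lt(max(abs(kin$speed_mm_s[swim] -
                      sim$truth$planned_speed_mm_s[swim])), 1e-6)
  cruise <- swim & sim$truth$planned_speed_mm_s >= p$cruise_speed_mm_s
  expect_gte(min(kin$speed_mm_s[cruise]), p$cruise_speed_mm_s - 1e-9)
  # per-bout chord path approximates speed x duration (reflection only
  # shortens chords slightly)
  ids <- stats::na.omit(unique(sim$truth$bout_id))
  for (bid in ids[1:5]) {
    ii <- which(sim$truth$bout_id == bid)
    planned <- sum(sim$truth$planned_speed_mm_s[ii]) / p$fps
    measured <- sum(kin$step_mm[ii])
    expect_lt(abs(measured - planned) / planned, 0.1)
  }
})

test_that("simulator parameter validation matches the documented contract", {
  expect_error(track_sim_params(fps = 0), "fps")
  expect_error(track_sim_params(arena_radius = -1), "arena_radius")
  expect_error(track_sim_params(rest_jitter_mm = 0.25), "0.2 mm")
  expect_error(track_sim_params(startle_peak_mm_s = 5,
                                cruise_speed_mm_s = 10), "exceed")
  expect_error(track_sim_params(bout_rate_per_s = 2, bout_duration_s = 0.6),
               "< 1")
  expect_error(light_schedule(character(0), numeric(0)), "at least one")
})

test_that("artifact injection changes exactly the returned indices", {
  sim <- simulate_track(track_sim_params(seed = 21, schedule = short_sched(120)))
  inj <- inject_artifacts(sim$track, artifact_params(type1_rate = 2e-3,
                                                     type2_rate = 2e-3,
                                                     seed = 21))
  expect_gt(nrow(inj$artifacts), 0L)
  delta <- inj$track$frames$x_mm != sim$track$frames$x_mm |
    inj$track$frames$y_mm != sim$track$frames$y_mm
  expect_setequal(which(delta), inj$artifacts$frame)
  # type-2 frames sit exactly on the arena edge
  t2 <- inj$artifacts$frame[inj$artifacts$type == "type2"]
  r <- sqrt(inj$track$frames$x_mm[t2]^2 + inj$track$frames$y_mm[t2]^2)
  expect_equal(r, rep(sim$track$arena$radius, length(t2)))
  # zero rates are a no-op
  inj0 <- inject_artifacts(sim$track, artifact_params(0, 0, seed = 1))
  expect_identical(inj0$track$frames, sim$track$frames)
  expect_equal(nrow(inj0$artifacts), 0L)
  expect_error(artifact_params(type1_rate = 1.5), "\\[0, 1\\]")
})

test_that("every injected artifact is flagged by its own detector", {
  for (seed in 1:5) {
    sim <- simulate_track(track_sim_params(seed = seed,
                                           schedule = short_sched(120)))
    inj <- inject_artifacts(sim$track,
                            artifact_params(type1_rate = 2e-3,
                                            type2_rate = 2e-3, seed = seed))
    fl <- flag_artifacts(inj$track)
    expect_equal(fl$labels[inj$artifacts$frame], inj$artifacts$type)
  }
})

test_that("simulated mortality follows the planted probit curve", {
  # at the LC50 itself the mortality fraction converges to one half
  p <- dose_sim_params(doses = 10^0.33, n_per_dose = 2e5, seed = 2)
  mt <- simulate_mortality(p)
  expect_lt(abs(mt$n_dead / mt$n_exposed - 0.5), 0.005)
  # an extreme slope gives a step function around the LC50
  ps <- dose_sim_params(doses = c(1, 10), n_per_dose = 50,
                        probit_slope = 500, seed = 2)
  ms <- simulate_mortality(ps)
  expect_equal(ms$n_dead, c(0L, 50L))
  # seeded determinism
  expect_identical(simulate_mortality(dose_sim_params(seed = 7)),
                   simulate_mortality(dose_sim_params(seed = 7)))
  expect_error(dose_sim_params(doses = c(-1, 2)), "positive")
})

test_that("empirical mortality matches the probit probability across seeds", {
  p0 <- dose_sim_params(n_per_dose = 50)
  truth <- stats::pnorm(p0$probit_slope * (log10(p0$doses) - p0$log10_lc50))
  frac <- sapply(1:40, function(s) {
    mt <- simulate_mortality(dose_sim_params(n_per_dose = 50, seed = s))
    mt$n_dead / mt$n_exposed
  })
  emp <- rowMeans(frac)
  mc_se <- sqrt(truth * (1 - truth) / (50 * 40))
  expect_true(all(abs(emp - truth) < 4 * pmax(mc_se, 1e-3)))
})

test_that("lipid simulation plants exact values when noise is off", {
  pe <- data.frame(species = "PS(40:5)", treatment = "high", effect = 0.4)
  p <- lipid_sim_params(cv = 0, planted_effects = pe, seed = 3)
  tab <- simulate_lipids(p)
  expect_equal(unique(tab[["PS(40:5)"]][tab$treatment == "high"]), 0.4)
  expect_equal(unique(tab[["PS(40:5)"]][tab$treatment == "control"]), 1)
  # cv = 0: all pools within a treatment identical
  expect_equal(length(unique(tab[["PE(38:5)"]])), 1L)
  # null planted effect: group means equal in expectation (exact at cv 0)
  expect_equal(mean(tab[["PE(38:5)"]][tab$treatment == "high"]),
               mean(tab[["PE(38:5)"]][tab$treatment == "control"]))
  # seeded determinism with noise on
  pn <- lipid_sim_params(seed = 4)
  expect_identical(simulate_lipids(pn), simulate_lipids(pn))
  expect_error(lipid_sim_params(baseline_nmol_per_mg = 0), "positive")
  expect_error(lipid_sim_params(pools_per_treatment = 1), ">= 2")
})
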