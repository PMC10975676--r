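test_that("turning angle follows the four-quadrant sign convention", {
  expect_equal(turning_angle(c(0, 0), c(1, 0), c(2, 0)), 0)
  expect_equal(turning_angle(c(0, 0), c(1, 0), c(1, -1)), -pi / 2)
  expect_equal(turning_angle(c(0, 0), c(1, 0), c(1, 1)), pi / 2)
  expect_equal(abs(turning_angle(c(0, 0), c(1, 0), c(0, 0))), pi)
  expect_true(is.na(turning_angle(c(0, 0), c(0, 0), c(1, 0))))
  # vectorized over rows
  prev <- rbind(c(0, 0), c(0, 0))
  cur <- rbind(c(1, 0), c(1, 0))
  nxt <- rbind(c(2, 0), c(1, -1))
  expect_equal(turning_angle(prev, cur, nxt), c(0, -pi / 2))
})

test_that("type-1 detector requires both the angle and net-distance criteria", {
  # straight constant-speed track: no flags
  straight <- make_track(cbind(seq(0, 3, by = 0.3), 0))
  expect_false(any(flag_type1(straight)))

  # reversal with net 0.03 < 0.06: flagged
  spike <- make_track(rbind(c(-1, 0), c(0, 0), c(0.5, 0), c(0.03, 0), c(1, 0)))
  expect_equal(which(flag_type1(spike)), 3L)

  # same geometry, net 0.10 >= 0.06: not flagged
  wide <- make_track(rbind(c(-1, 0), c(0, 0), c(0.5, 0), c(0.10, 0), c(1, 0)))
  expect_false(any(flag_type1(wide)))

  # first/last frames never flagged
  expect_false(flag_type1(spike)[1])
  expect_false(flag_type1(spike)[5])
})

test_that("type-2 detector enforces net, leg-length and tolerance criteria", {
  ok <- make_track(rbind(c(-1, 0), c(0, 0), c(5, 0), c(0.2, 0), c(1, 0)))
  expect_equal(which(flag_type2(ok)), 3L)

  # legs 5 and 3: 40% length difference (and net 2 > 0.6): not flagged
  far <- make_track(rbind(c(-1, 0), c(0, 0), c(5, 0), c(2, 0), c(1, 0)))
  expect_false(any(flag_type2(far)))

  # legs below the 2 mm floor: not flagged
  small <- make_track(rbind(c(-1, 0), c(0, 0), c(1.5, 0), c(0.1, 0), c(1, 0)))
  expect_false(any(flag_type2(small)))
})

test_that("a frame satisfying both detectors is labelled type2", {
  # edge jump over a stationary fish satisfies type-1 too (net < 0.06)
  tr <- make_track(rbind(c(0, 0), c(0, 0), c(5, 0), c(0, 0), c(0, 0)),
                   radius = 5)
  fl <- flag_artifacts(tr)
  expect_equal(fl$labels[3], "type2")
  expect_true(flag_type1(tr)[3] && flag_type2(tr)[3])
})

test_that("equidistant correction replaces flagged runs between anchors", {
  tr <- make_track(rbind(c(0, 0), c(9, 9), c(1, 0)))
  out <- correct_flags(tr, c(FALSE, TRUE, FALSE))
  expect_equal(c(out$frames$x_mm[2], out$frames$y_mm[2]), c(0.5, 0))
  expect_equal(out$frames$status[2], "interpolated")

  tr2 <- make_track(rbind(c(0, 0), c(9, 9), c(-9, 4), c(3, 0)))
  out2 <- correct_flags(tr2, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out2$frames$x_mm, c(0, 1, 2, 3))
  expect_equal(out2$frames$y_mm, rep(0, 4))

  # no flags: identity
  expect_equal(correct_flags(tr, c(FALSE, FALSE, FALSE)), tr)

  # boundary-touching run: ignored with a warning, positions untouched
  expect_warning(out3 <- correct_flags(tr, c(TRUE, FALSE, FALSE)), "ignored")
  expect_equal(out3$frames$status[1], "ignored")
  expect_equal(out3$frames$x_mm, tr$frames$x_mm)
})

test_that("unflagged frames are bit-identical through correction", {
  sim <- simulate_track(track_sim_params(
    seed = 3, schedule = light_schedule(c("light", "dark"), 60)))
  inj <- inject_artifacts(sim$track, artifact_params(type1_rate = 5e-3,
                                                     type2_rate = 5e-3,
                                                     seed = 3))
  fl <- flag_artifacts(inj$track)
  out <- correct_flags(inj$track, fl)
  clean <- fl$labels == "clean"
  expect_identical(out$frames$x_mm[clean], inj$track$frames$x_mm[clean])
  expect_identical(out$frames$y_mm[clean], inj$track$frames$y_mm[clean])
})

test_that("micro-movement suppression acts only inside high-error windows", {
  # a burst of artifacts creates a high-error window; 0.1 mm jitter there
  # is held in place, 0.5 mm steps are retained
  n <- 90
  xy <- matrix(0, n, 2)
  xy[, 1] <- cumsum(rep(0.1, n))            # persistent 0.1 mm drift
  xy[60:90, 1] <- xy[59, 1] + cumsum(rep(0.5, 31)) # larger steps later
  tr <- make_track(xy)
  fl <- list(labels = rep("clean", n), high_error = rep(FALSE, n))
  fl$high_error[10:80] <- TRUE
  class(fl) <- "vmr_flags"
  out <- suppress_micro_movement(tr, fl)
  # inside the window the 0.1 mm steps collapse...
  expect_equal(out$frames$x_mm[10:59], rep(tr$frames$x_mm[9], 50))
  # ...the 0.5 mm steps survive...
  d <- diff(out$frames$x_mm[61:80])
  expect_true(all(d >= 0.5 - 1e-12))
  # ...and frames outside the window are untouched
  expect_equal(out$frames$x_mm[81:90], tr$frames$x_mm[81:90])

  # zero flagged frames: identity
  none <- flag_artifacts(tr)
  expect_equal(suppress_micro_movement(tr, none), tr)
})

test_that("subject exclusion covers design flags and tracking loss", {
  good <- make_track(cbind(seq(0, 1, length.out = 120), 0), subject_id = "ok")
  xy <- cbind(seq(0, 1, length.out = 120), 0)
  xy[30:120, ] <- NA # 91 frames = 3.03 s gap
  gappy <- make_track(xy, subject_id = "gap")
  design <- tibble::tibble(
    subject_id = c("ok", "gap", "dead1"),
    chemical = "PFOA", dose_ppm = 188, plate = "P1",
    well = c("A1", "A2", "A3"), breed = "B1",
    excluded = c(FALSE, FALSE, TRUE),
    exclusion_reason = c(NA, NA, "dead"))
  dead <- make_track(cbind(0, 0)[rep(1, 10), ], subject_id = "dead1")
  res <- exclude_subjects(list(good, gappy, dead), design)
  expect_equal(vapply(res$kept, function(t) t$subject_id, character(1)), "ok")
  expect_equal(res$report$reason[res$report$subject_id == "gap"],
               "tracking-loss")
  expect_equal(res$report$reason[res$report$subject_id == "dead1"], "dead")

  # no gaps, no design flags: all retained
  res2 <- exclude_subjects(list(good), design[design$subject_id == "ok", ])
  expect_length(res2$kept, 1L)
  expect_equal(nrow(res2$report), 0L)
})

test_that("cleaning config rejects invalid thresholds", {
  expect_error(cleaning_config(type1_dist_mm = -1), "positive")
  expect_error(cleaning_config(type1_angle_deg = 190), "180")
  expect_error(cleaning_config(type2_leg_len_tol = 1.5), "\\[0, 1\\]")
})
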