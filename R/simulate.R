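#' Parameters for the beat-and-glide track simulator
#'
#' The simulator emulates larval zebrafish locomotion in a circular
#' well: bouts of swimming at cruise speed alternate with rest, as an
#' alternating renewal process, and every light transition of the
#' schedule triggers a startle bout whose speed ramps to a known peak at
#' a known latency. Because the generated regime and the known ground
#' truth exercise exactly the segmentation and startle logic of the
#' behavior module, endpoint extraction can be validated against
#' planted values.
#'
#' Bout onsets are spaced so that the realized bout rate matches
#' `bout_rate_per_s`: inter-bout gaps are a minimum separation plus an
#' exponential whose mean makes the full cycle (gap + bout) average
#' `1 / bout_rate_per_s`. Bout durations are a minimum detectable length
#' (8 frames) plus an exponential with overall mean `bout_duration_s`.
#'
#' @param arena_radius Well radius in mm (default 5.5).
#' @param fps Frames per second (default 30).
#' @param bout_rate_per_s Swim-bout initiation rate (default 0.8 /s;
#'   must satisfy `bout_rate_per_s * bout_duration_s < 1`).
#' @param bout_duration_s Mean bout length in seconds (default 0.4).
#' @param cruise_speed_mm_s Within-bout speed (default 10 mm/s).
#' @param rest_jitter_mm Sub-threshold positional noise amplitude during
#'   rest (mm per frame). Default 0: centroid noise below tracker
#'   resolution is off, which keeps rest segments zero-length so the
#'   artifact detectors are exercised against exactly the planted
#'   errors. Must stay below the 0.2 mm swim step threshold.
#' @param startle_latency_s Ground-truth latency from a light transition
#'   to peak speed (default 0.5 s).
#' @param startle_peak_mm_s Ground-truth peak speed of the startle
#'   response (default 25 mm/s; must exceed `cruise_speed_mm_s`).
#' @param schedule A `vmr_schedule` (default [vmr_schedule()]).
#' @param seed Integer seed; every simulator call with the same seed
#'   yields a bit-identical track.
#' @return A `track_sim_params` list.
#' @export
track_sim_params <- function(arena_radius = 5.5, fps = 30,
                             bout_rate_per_s = 0.8, bout_duration_s = 0.4,
                             cruise_speed_mm_s = 10, rest_jitter_mm = 0,
                             startle_latency_s = 0.5,
                             startle_peak_mm_s = 25,
                             schedule = vmr_schedule(), seed = 1L) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  if (arena_radius <= 0) stop("arena_radius must be positive", call. = FALSE)
  if (!inherits(schedule, "vmr_schedule") || nrow(schedule) == 0L) {
    stop("schedule must be a non-empty vmr_schedule", call. = FALSE)
  }
  rates <- c(bout_rate_per_s, bout_duration_s, cruise_speed_mm_s,
             rest_jitter_mm, startle_latency_s, startle_peak_mm_s)
  if (any(rates < 0)) stop("rates and speeds must be non-negative", call. = FALSE)
  if (rest_jitter_mm >= 0.2) {
    stop("rest_jitter_mm must stay below the 0.2 mm swim step", call. = FALSE)
  }
  if (bout_rate_per_s > 0 && bout_rate_per_s * bout_duration_s >= 1) {
    stop("bout_rate_per_s * bout_duration_s must be < 1", call. = FALSE)
  }
  if (startle_peak_mm_s > 0 && startle_peak_mm_s <= cruise_speed_mm_s) {
    stop("startle_peak_mm_s must exceed cruise_speed_mm_s", call. = FALSE)
  }
  structure(list(arena_radius = arena_radius, fps = fps,
                 bout_rate_per_s = bout_rate_per_s,
                 bout_duration_s = bout_duration_s,
                 cruise_speed_mm_s = cruise_speed_mm_s,
                 rest_jitter_mm = rest_jitter_mm,
                 startle_latency_s = startle_latency_s,
                 startle_peak_mm_s = startle_peak_mm_s,
                 schedule = schedule, seed = as.integer(seed)),
            class = "track_sim_params")
}

# reflect a proposed step off the circular wall, preserving path length
reflect_into_arena <- function(p, q, R) {
  reflected <- FALSE
  for (it in 1:8) {
    if (sqrt(sum(q^2)) <= R) break
    d <- q - p
    a <- sum(d^2)
    b <- 2 * sum(p * d)
    cc <- sum(p^2) - R^2
    disc <- b^2 - 4 * a * cc
    tt <- if (disc >= 0) (-b + sqrt(disc)) / (2 * a) else 1
    tt <- min(max(tt, 0), 1)
    w <- p + tt * d
    nrm <- w / sqrt(sum(w^2))
    v <- q - w
    v <- v - 2 * sum(v * nrm) * nrm
    p <- w
    q <- w + v
    reflected <- TRUE
  }
  if (sqrt(sum(q^2)) > R) q <- q * (R * 0.999) / sqrt(sum(q^2))
  list(q = q, reflected = reflected)
}

#' Simulate a larval swim track with ground truth
#'
#' Generates a seeded beat-and-glide track under the given light
#' schedule (see [track_sim_params()]). The per-frame planned speed
#' profile is built first (renewal bouts at cruise speed, startle bouts
#' ramping linearly to the planted peak at the planted latency after
#' each light transition, runs shorter than the detectable minimum
#' removed), then integrated into positions with specular reflection at
#' the arena wall.
#'
#' @param params A [track_sim_params()].
#' @return A `vmr_sim` list: `track` (a `vmr_track`), `truth` (tibble
#'   with per-frame `state`, `bout_id`, `planned_speed_mm_s`,
#'   `reflected`), `startles` (tibble of startle times with planted
#'   latency and peak), and `params`.
#' @export
simulate_track <- function(params) {
  stopifnot(inherits(params, "track_sim_params"))
  withr::with_seed(params$seed, {
    fps <- params$fps
    total_s <- schedule_duration(params$schedule)
    n <- round(total_s * fps)
    dur_min <- 8L / fps
    gap_min <- 0.2
    speed <- numeric(n) # planned speed of the step into each frame

    if (params$bout_rate_per_s > 0) {
      gap_mean <- 1 / params$bout_rate_per_s - params$bout_duration_s
      if (gap_mean <= gap_min) {
        stop("bout rate too high for the minimum inter-bout gap",
             call. = FALSE)
      }
      t <- 0
      while (t < total_s) {
        gap <- gap_min + stats::rexp(1, 1 / (gap_mean - gap_min))
        dur <- dur_min + stats::rexp(1, 1 / max(params$bout_duration_s - dur_min,
                                                1e-6))
        a <- ceiling((t + gap) * fps) + 1L
        b <- min(a + round(dur * fps) - 1L, n)
        if (a > n) break
        speed[a:b] <- params$cruise_speed_mm_s
        t <- t + gap + dur
      }
    }

    ev <- startle_events(params$schedule)
    L <- max(1L, round(params$startle_latency_s * fps))
    H <- max(1L, round(params$bout_duration_s * fps))
    G <- round(gap_min * fps)
    for (ts in ev$time_s) {
      s <- round(ts * fps) + 1L # row index of the frame at the startle
      if (s < 1L || s > n) next
      v0 <- speed[s]
      up <- s + seq_len(L)
      down <- s + L + seq_len(L)
      hold <- s + 2L * L + seq_len(H)
      quiet <- s + 2L * L + H + seq_len(G)
      assign_in <- function(idx, val) {
        ok <- idx <= n
        speed[idx[ok]] <<- val[ok]
      }
      assign_in(up, v0 + (params$startle_peak_mm_s - v0) * seq_len(L) / L)
      assign_in(down, params$startle_peak_mm_s +
                  (params$cruise_speed_mm_s - params$startle_peak_mm_s) *
                  seq_len(L) / L)
      assign_in(hold, rep(params$cruise_speed_mm_s, H))
      assign_in(quiet, rep(0, G))
    }

    # drop positive runs too short to count as swimming
    r <- rle(speed > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] < 8L) speed[starts[k]:ends[k]] <- 0
    }

    bout_id <- label_runs(speed > 0)

    # integrate positions with reflection
    R <- params$arena_radius
    rr <- R * sqrt(stats::runif(1)) * 0.9
    th <- stats::runif(1, -pi, pi)
    pos <- matrix(0, n, 2)
    pos[1, ] <- c(rr * cos(th), rr * sin(th))
    reflected <- rep(FALSE, n)
    heading <- stats::runif(1, -pi, pi)
    jit_heading <- stats::runif(1, -pi, pi)
    prev_bout <- NA_integer_
    for (i in 2:n) {
      if (speed[i] > 0) {
        if (is.na(prev_bout) || !identical(prev_bout, bout_id[i])) {
          heading <- stats::runif(1, -pi, pi)
        } else {
          heading <- heading + stats::rnorm(1, 0, 15 * pi / 180)
        }
        prev_bout <- bout_id[i]
        len <- speed[i] / fps
        q <- pos[i - 1, ] + len * c(cos(heading), sin(heading))
        refl <- reflect_into_arena(pos[i - 1, ], q, R)
        pos[i, ] <- refl$q
        reflected[i] <- refl$reflected
        if (refl$reflected) {
          heading <- atan2(pos[i, 2] - pos[i - 1, 2],
                           pos[i, 1] - pos[i - 1, 1])
        }
      } else if (params$rest_jitter_mm > 0) {
        prev_bout <- NA_integer_
        jit_heading <- jit_heading + stats::runif(1, -pi / 2, pi / 2)
        q <- pos[i - 1, ] + params$rest_jitter_mm *
          c(cos(jit_heading), sin(jit_heading))
        refl <- reflect_into_arena(pos[i - 1, ], q, R)
        pos[i, ] <- refl$q
      } else {
        prev_bout <- NA_integer_
        pos[i, ] <- pos[i - 1, ]
      }
    }

    frames <- tibble::tibble(frame = 0:(n - 1L), time_s = (0:(n - 1L)) / fps,
                             x_mm = pos[, 1], y_mm = pos[, 2])
    track <- vmr_track(sprintf("sim-%d", params$seed), frames, fps = fps,
                       arena_radius = R)
    truth <- tibble::tibble(
      frame = frames$frame,
      state = ifelse(speed > 0, "swim", "rest"),
      bout_id = bout_id,
      planned_speed_mm_s = speed,
      reflected = reflected
    )
    structure(list(track = track, truth = truth,
                   startles = tibble::tibble(
                     time_s = ev$time_s, direction = ev$direction,
                     latency_s = L / fps,
                     peak_mm_s = params$startle_peak_mm_s),
                   params = params),
              class = "vmr_sim")
  })
}

#' Parameters for artifact injection
#'
#' Rates are per-frame probabilities applied to eligible frames. The
#' default geometry places each corrupted frame strictly inside the
#' flagging criteria of [flag_type1()] / [flag_type2()]: type-1 events
#' displace a single resting frame by `type1_jump_mm` (legs well under
#' the 2 mm type-2 floor), type-2 events relocate a frame to the arena
#' edge and back. Setting `near_threshold = TRUE` instead generates
#' geometry close to the flagging boundaries, for boundary testing.
#'
#' @param type1_rate Per-eligible-frame probability of a
#'   body-point-switch jitter event (default 5e-4).
#' @param type2_rate Per-eligible-frame probability of an arena-edge
#'   jump (default 5e-4).
#' @param type1_jump_mm Displacement of a type-1 event (default 1 mm).
#' @param near_threshold Generate near-threshold geometry (default
#'   FALSE).
#' @param seed Integer seed.
#' @return An `artifact_params` list.
#' @export
artifact_params <- function(type1_rate = 5e-4, type2_rate = 5e-4,
                            type1_jump_mm = 1, near_threshold = FALSE,
                            seed = 1L) {
  if (type1_rate < 0 || type1_rate > 1 || type2_rate < 0 || type2_rate > 1) {
    stop("artifact rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(type1_rate = type1_rate, type2_rate = type2_rate,
                 type1_jump_mm = type1_jump_mm,
                 near_threshold = near_threshold, seed = as.integer(seed)),
            class = "artifact_params")
}

#' Inject tracking artifacts into a track
#'
#' Corrupts single frames with the two tracking-error classes. Type-1
#' eligibility requires the previous and future locations to sit within
#' the type-1 net-distance criterion (as in real data, where the body
#' point switches while the fish holds station); type-2 eligibility
#' additionally requires the edge point to give legs above the 2 mm
#' floor. Injected frames are separated by at least two frames so each
#' keeps clean neighbours. All frames other than the returned indices
#' are bit-identical to the input.
#'
#' @param track A `vmr_track` with at least 3 frames.
#' @param params An [artifact_params()].
#' @return List with `track` (corrupted copy) and `artifacts` (tibble
#'   `frame` -- 1-based row index -- and `type`).
#' @export
inject_artifacts <- function(track, params) {
  stopifnot(inherits(track, "vmr_track"), inherits(params, "artifact_params"))
  if (n_frames(track) < 3L) stop("track must have >= 3 frames", call. = FALSE)
  withr::with_seed(params$seed, {
    xy <- track_xy(track)
    n <- nrow(xy)
    R <- track$arena$radius
    g <- spike_geometry(xy)
    net <- rep(NA_real_, n)
    net[g$idx] <- g$net
    interior <- 2:(n - 1)
    ok <- interior[!is.na(net[interior])]
    elig1 <- ok[net[ok] < 0.05]
    elig2 <- ok[net[ok] <= 0.5]
    pick <- function(elig, rate) elig[stats::runif(length(elig)) < rate]
    sel1 <- pick(elig1, params$type1_rate)
    sel2 <- pick(elig2, params$type2_rate)
    # resolve collisions and enforce >= 2 frame separation
    sel <- rbind(
      if (length(sel1)) data.frame(frame = sel1, type = "type1"),
      if (length(sel2)) data.frame(frame = sel2, type = "type2")
    )
    if (is.null(sel) || nrow(sel) == 0L) {
      return(list(track = track,
                  artifacts = tibble::tibble(frame = integer(0),
                                             type = character(0))))
    }
    sel <- sel[order(sel$frame, sel$type), , drop = FALSE]
    keep <- rep(TRUE, nrow(sel))
    last <- -10L
    for (k in seq_len(nrow(sel))) {
      if (sel$frame[k] - last < 2L) keep[k] <- FALSE else last <- sel$frame[k]
    }
    sel <- sel[keep, , drop = FALSE]
    jump1 <- if (params$near_threshold) 1.8 else params$type1_jump_mm
    for (k in seq_len(nrow(sel))) {
      i <- sel$frame[k]
      if (sel$type[k] == "type1") {
        for (try in 1:20) {
          a <- stats::runif(1, -pi, pi)
          q <- xy[i, ] + jump1 * c(cos(a), sin(a))
          if (sqrt(sum(q^2)) <= R) break
        }
        if (sqrt(sum(q^2)) > R) q <- q * (R * 0.999) / sqrt(sum(q^2))
        xy[i, ] <- q
      } else {
        p <- xy[i - 1, ]
        nr <- sqrt(sum(p^2))
        u <- if (nr > 1e-9) -p / nr else c(1, 0)
        xy[i, ] <- R * u # far edge: legs ~ R + |p| >= 2 mm
      }
    }
    out <- track
    out$frames$x_mm <- xy[, 1]
    out$frames$y_mm <- xy[, 2]
    list(track = out,
         artifacts = tibble::as_tibble(sel))
  })
}

#' Parameters for dose-mortality simulation
#'
#' @param doses Strictly increasing, strictly positive concentrations
#'   (ppm).
#' @param n_per_dose Subjects per dose level (>= 1).
#' @param log10_lc50 Location of 50% lethality on the log10-dose scale.
#' @param probit_slope Probit slope on the log10-dose scale (> 0).
#' @param seed Integer seed.
#' @return A `dose_sim_params` list.
#' @export
dose_sim_params <- function(doses = c(0.5, 1, 1.5, 2, 3), n_per_dose = 200,
                            log10_lc50 = 0.33, probit_slope = 4, seed = 1L) {
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly positive and strictly increasing",
         call. = FALSE)
  }
  if (n_per_dose < 1) stop("n_per_dose must be >= 1", call. = FALSE)
  if (probit_slope <= 0) stop("probit_slope must be > 0", call. = FALSE)
  structure(list(doses = doses, n_per_dose = n_per_dose,
                 log10_lc50 = log10_lc50, probit_slope = probit_slope,
                 seed = as.integer(seed)),
            class = "dose_sim_params")
}

#' Simulate a dose-mortality table from a probit curve
#'
#' Deaths at each dose are binomial with probability
#' `pnorm(probit_slope * (log10(dose) - log10_lc50))`.
#'
#' @param params A [dose_sim_params()].
#' @return A mortality tibble: `dose_ppm`, `n_exposed`, `n_dead`,
#'   `timepoint_hpf`.
#' @export
simulate_mortality <- function(params) {
  stopifnot(inherits(params, "dose_sim_params"))
  withr::with_seed(params$seed, {
    p <- stats::pnorm(params$probit_slope *
                        (log10(params$doses) - params$log10_lc50))
    tibble::tibble(
      dose_ppm = params$doses,
      n_exposed = params$n_per_dose,
      n_dead = stats::rbinom(length(p), params$n_per_dose, p),
      timepoint_hpf = 120
    )
  })
}

#' Parameters for lipid-pool simulation
#'
#' Pooled-embryo lipid tables: per-species lognormal values (nmol per
#' mg wet weight) around a baseline, with multiplicative treatment
#' effects planted on chosen (species, treatment) cells.
#'
#' @param treatments Treatment labels; the first is taken as the
#'   control when tests are run downstream.
#' @param pools_per_treatment Pools per treatment (>= 2 for any
#'   treatment entering ANOVA; default 5).
#' @param species Character vector of species names in `CLASS(C:D)`
#'   notation.
#' @param baseline_nmol_per_mg Per-species baseline means (recycled).
#' @param cv Per-species coefficient of variation (default 0.10, the
#'   scale of pooled-sample technical plus biological spread).
#' @param planted_effects Data frame with columns `species`,
#'   `treatment`, `effect` (multiplicative), or `NULL` for a global
#'   null.
#' @param n_embryos Embryos per pool (default 8).
#' @param embryo_wet_weight_mg Wet weight per embryo (default 0.8 mg).
#' @param seed Integer seed.
#' @return A `lipid_sim_params` list.
#' @export
lipid_sim_params <- function(treatments = c("control", "low", "mid", "high"),
                             pools_per_treatment = 5,
                             species = c("PS(40:5)", "PS(34:1)", "PE(38:5)",
                                         "PE(36:5)", "PC(32:1)", "ePC(34:1)",
                                         "ePE(36:1)", "PA(34:1)", "DSM(16:0)",
                                         "FA(16:0)", "LPE(18:1)", "SM(16:0)"),
                             baseline_nmol_per_mg = 1,
                             cv = 0.10, planted_effects = NULL,
                             n_embryos = 8, embryo_wet_weight_mg = 0.8,
                             seed = 1L) {
  baseline_nmol_per_mg <- rep_len(baseline_nmol_per_mg, length(species))
  if (any(baseline_nmol_per_mg <= 0)) {
    stop("baselines must be positive", call. = FALSE)
  }
  if (any(cv < 0)) stop("cv must be >= 0", call. = FALSE)
  if (pools_per_treatment < 2) {
    stop("pools_per_treatment must be >= 2 for ANOVA", call. = FALSE)
  }
  if (!is.null(planted_effects)) {
    stopifnot(all(c("species", "treatment", "effect") %in%
                    names(planted_effects)))
    if (any(planted_effects$effect <= 0)) {
      stop("planted effects are multiplicative and must be positive",
           call. = FALSE)
    }
  }
  structure(list(treatments = treatments,
                 pools_per_treatment = pools_per_treatment,
                 species = species,
                 baseline_nmol_per_mg = baseline_nmol_per_mg,
                 cv = rep_len(cv, length(species)),
                 planted_effects = planted_effects,
                 n_embryos = n_embryos,
                 embryo_wet_weight_mg = embryo_wet_weight_mg,
                 seed = as.integer(seed)),
            class = "lipid_sim_params")
}

#' Simulate a pooled-sample lipid table
#'
#' Values are lognormal with the configured per-species mean and CV
#' (`cv = 0` collapses to the exact mean), multiplied by any planted
#' treatment effect. Rows are pools, columns are pool metadata plus one
#' column per lipid species (nmol per mg wet weight).
#'
#' @param params A [lipid_sim_params()].
#' @return A lipid tibble with metadata columns `pool_id`, `treatment`,
#'   `wet_weight_mg`, `n_embryos` and one numeric column per species.
#' @export
simulate_lipids <- function(params) {
  stopifnot(inherits(params, "lipid_sim_params"))
  withr::with_seed(params$seed, {
    meta <- expand.grid(pool = seq_len(params$pools_per_treatment),
                        treatment = params$treatments,
                        stringsAsFactors = FALSE)
    npool <- nrow(meta)
    vals <- matrix(NA_real_, npool, length(params$species),
                   dimnames = list(NULL, params$species))
    for (j in seq_along(params$species)) {
      mu <- params$baseline_nmol_per_mg[j]
      cv <- params$cv[j]
      eff <- rep(1, npool)
      if (!is.null(params$planted_effects)) {
        pe <- params$planted_effects[
          params$planted_effects$species == params$species[j], , drop = FALSE]
        for (r in seq_len(nrow(pe))) {
          eff[meta$treatment == pe$treatment[r]] <- pe$effect[r]
        }
      }
      if (cv == 0) {
        vals[, j] <- mu * eff
      } else {
        sdlog <- sqrt(log(1 + cv^2))
        vals[, j] <- stats::rlnorm(npool, log(mu * eff) - sdlog^2 / 2, sdlog)
      }
    }
    tibble::tibble(
      pool_id = sprintf("%s-p%d", meta$treatment, meta$pool),
      treatment = meta$treatment,
      wet_weight_mg = params$n_embryos * params$embryo_wet_weight_mg,
      n_embryos = params$n_embryos,
      tibble::as_tibble(vals)
    )
  })
}
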