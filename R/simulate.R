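#' Simulation configuration for synthetic trajectories
#'
#' The generator emulates the structure the kinematic analysis assumes:
#' alternating immobility gaps (exponential, initiation rate
#' `bout_rate_hz`) and movement bouts (exponential, mean `mean_bout_s`)
#' whose within-bout speed ramps up at `ramp_accel_cm_s2`, cruises at
#' `cruise_speed_cm_s` and ramps down at `ramp_decel_cm_s2`; headings
#' follow a correlated random walk (von Mises turning noise with
#' concentration `heading_concentration`), with specular reflection at
#' walls. `zone_bias` (named weights per zone role) biases heading
#' proposals toward attractive roles, and `social_modulation`
#' (multiplicative `accel`, `stop_rate`, `speed` factors) applies while the
#' animal is inside a `chamber_social` zone. All stochastic output is a
#' pure function of (config, seed).
#'
#' Defaults mirror the stated experimental world: 5-minute sessions at
#' 30 frames/s (the webcam class used for such recordings does not
#' advertise its rate; 1/30 s is the package-wide default and is always
#' recorded in output), and speed/acceleration defaults chosen so that
#' summaries land in the realistic rat band (cruise ~18 cm/s, mean
#' acceleration ~150 cm/s^2, ~50% time moving).
#'
#' @param arena an [arena_spec()].
#' @param duration_s session length (s).
#' @param dt_s frame interval (s).
#' @param bout_rate_hz movement-bout initiations per second of immobility.
#' @param mean_bout_s mean bout duration (s).
#' @param ramp_accel_cm_s2,cruise_speed_cm_s,ramp_decel_cm_s2 within-bout
#'   speed model.
#' @param heading_concentration von Mises concentration of per-step turning
#'   noise (larger = straighter paths).
#' @param zone_bias NULL or named numeric weights per zone role (>= 0;
#'   unnamed roles weigh 1). While moving, the animal reorients at rate
#'   `zone_attract_hz` toward the center of a zone drawn with probability
#'   proportional to its role weight — a biased heading-proposal scheme
#'   whose stationary occupancy roughly follows the weight shares.
#' @param zone_attract_hz reorientation rate per second of movement
#'   (default 0.5).
#' @param social_modulation NULL or list(accel=, stop_rate=, speed=).
#' @param bout_rate_halflife_s optional halving time of `bout_rate_hz`
#'   across the session (models habituation); `Inf` = stationary.
#' @param subject_sd log-scale SD of per-subject lognormal multipliers on
#'   (cruise, ramp rates, bout rate, bout length); 0 = identical subjects.
#' @param start_xy starting position (cm); default arena center.
#' @param seed integer RNG seed.
#' @param label phenotype label carried into provenance.
#' @return `ek_simconfig` list.
#' @export
simulation_config <- function(arena, duration_s = 300, dt_s = 1 / 30,
                              bout_rate_hz = 1, mean_bout_s = 1,
                              ramp_accel_cm_s2 = 150,
                              cruise_speed_cm_s = 18,
                              ramp_decel_cm_s2 = 150,
                              heading_concentration = 4,
                              zone_bias = NULL, zone_attract_hz = 0.5,
                              social_modulation = NULL,
                              bout_rate_halflife_s = Inf,
                              subject_sd = 0, start_xy = NULL, seed = 1,
                              label = "") {
  if (!inherits(arena, "ek_arena")) {
    ek_stop("arena must be an ek_arena", "ek_invalid_config")
  }
  for (nm in c("duration_s", "dt_s", "mean_bout_s",
               "ramp_accel_cm_s2", "cruise_speed_cm_s",
               "ramp_decel_cm_s2")) {
    assert_scalar_num(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  # zero bout rate is legal: a session in which the animal never moves
  assert_scalar_num(bout_rate_hz, "bout_rate_hz", lower = 0)
  if (cruise_speed_cm_s * dt_s >= min(arena$bounds_cm)) {
    ek_stop("arena too small for a single cruise step", "ek_invalid_config")
  }
  if (!is.null(zone_bias)) {
    if (is.null(names(zone_bias)) || any(zone_bias < 0)) {
      ek_stop("zone_bias must be a named non-negative vector", "ek_invalid_config")
    }
  }
  if (!is.null(social_modulation)) {
    social_modulation <- utils::modifyList(
      list(accel = 1, stop_rate = 1, speed = 1), social_modulation)
  }
  start_xy <- start_xy %||% (arena$bounds_cm / 2)
  structure(list(arena = arena, duration_s = duration_s, dt_s = dt_s,
                 bout_rate_hz = bout_rate_hz, mean_bout_s = mean_bout_s,
                 ramp_accel_cm_s2 = ramp_accel_cm_s2,
                 cruise_speed_cm_s = cruise_speed_cm_s,
                 ramp_decel_cm_s2 = ramp_decel_cm_s2,
                 heading_concentration = heading_concentration,
                 zone_bias = zone_bias, zone_attract_hz = zone_attract_hz,
                 social_modulation = social_modulation,
                 bout_rate_halflife_s = bout_rate_halflife_s,
                 subject_sd = subject_sd,
                 start_xy = as.numeric(start_xy), seed = seed,
                 label = label),
            class = "ek_simconfig")
}

# von Mises sampler, Best & Fisher (1979) wrapping rejection method
# (batched rejection: proposals drawn in blocks until n are accepted)
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-6) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.3))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, (sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))))[ok])
  }
  out[seq_len(n)]
}

# triangle fold: exact specular reflection of an unbounded coordinate into [0, L]
fold_reflect <- function(p, L) {
  m <- p %% (2 * L)
  L - abs(m - L)
}

# draw the alternating gap/bout schedule in steps (shared by both paths)
draw_schedule <- function(n_steps, dt, bout_rate, mean_bout, halflife) {
  phase_moving <- logical(0)
  bout_id <- integer(0)
  t <- 0; total <- 0L; bid <- 0L
  while (total < n_steps) {
    rate <- bout_rate * 2^(-t / halflife)
    gap <- stats::rexp(1, rate = max(rate, 1e-12))
    # cap before integer conversion: a near-zero rate yields huge gaps
    gsteps <- as.integer(min(max(1, round(gap / dt)), n_steps - total))
    phase_moving <- c(phase_moving, rep(FALSE, gsteps))
    bout_id <- c(bout_id, rep(0L, gsteps))
    total <- total + gsteps; t <- t + gsteps * dt
    if (total >= n_steps) break
    bout <- stats::rexp(1, rate = 1 / mean_bout)
    bsteps <- as.integer(min(max(1, round(bout / dt)), n_steps - total))
    bid <- bid + 1L
    phase_moving <- c(phase_moving, rep(TRUE, bsteps))
    bout_id <- c(bout_id, rep(bid, bsteps))
    total <- total + bsteps; t <- t + bsteps * dt
  }
  list(moving = phase_moving, bout_id = bout_id)
}

#' Simulate a trajectory with ground truth
#'
#' See [simulation_config()] for the generative model. Two equivalent
#' integrators are used: a fast vectorized one when neither `zone_bias` nor
#' `social_modulation` is configured (walls handled by exact triangle-fold
#' specular reflection of the unbounded path), and a per-step state machine
#' otherwise (bout initiation/termination as per-step hazards, weighted
#' goal-directed reorientation per `zone_bias`, explicit wall and
#' three-chamber divider reflection with passage only through the door
#' strip). A given config always takes the same path, so results are
#' reproducible under the seed.
#'
#' @param cfg an [simulation_config()].
#' @param subject_id,group_label provenance for the emitted trajectory.
#' @return list with `trajectory` (an [trajectory()]) and `truth`: list of
#'   `schedule` (per-step moving flag and bout id), `bouts` (data.frame of
#'   scheduled bouts with peak speed), `n_bouts`, `n_stops` (internal gaps),
#'   `frame_role` (zone role per frame), `params` (realized per-subject
#'   parameters after lognormal multipliers), `label`.
#' @export
simulate_trajectory <- function(cfg, subject_id = "sim",
                                group_label = cfg$label) {
  if (!inherits(cfg, "ek_simconfig")) {
    ek_stop("cfg must be an ek_simconfig", "ek_invalid_config")
  }
  with_seed_local(cfg$seed, {
    mult <- if (cfg$subject_sd > 0) {
      exp(stats::rnorm(4, 0, cfg$subject_sd))
    } else rep(1, 4)
    par <- list(
      cruise = cfg$cruise_speed_cm_s * mult[1],
      accel = cfg$ramp_accel_cm_s2 * mult[2],
      decel = cfg$ramp_decel_cm_s2 * mult[2],
      bout_rate = cfg$bout_rate_hz * mult[3],
      mean_bout = cfg$mean_bout_s * mult[4])
    n_steps <- as.integer(round(cfg$duration_s / cfg$dt_s))
    if (n_steps < 1L) ek_stop("duration shorter than one frame", "ek_invalid_config")
    use_loop <- !is.null(cfg$zone_bias) || !is.null(cfg$social_modulation)
    sim <- if (use_loop) {
      simulate_loop(cfg, par, n_steps)
    } else {
      simulate_vectorized(cfg, par, n_steps)
    }
    traj <- trajectory(sim$x, sim$y, dt_s = cfg$dt_s,
                       subject_id = subject_id, group_label = group_label,
                       test_stage = cfg$arena$name)
    frame_role <- {
      zid <- assign_zone(sim$x, sim$y, cfg$arena)
      role_of <- stats::setNames(cfg$arena$zones$role, cfg$arena$zones$zone_id)
      ifelse(is.na(zid), NA_character_, role_of[zid])
    }
    bid <- sim$bout_id
    bouts <- NULL
    n_bouts <- max(0L, max(bid))
    if (n_bouts > 0L) {
      runs <- true_runs(bid > 0L)
      bouts <- data.frame(
        bout = seq_len(nrow(runs)), start_step = runs$start,
        end_step = runs$end,
        peak_speed_cm_s = mapply(function(s, e) max(sim$speed[s:e]),
                                 runs$start, runs$end))
    }
    # internal gaps = immobile runs flanked by bouts on both sides
    moving <- bid > 0L
    gaps <- true_runs(!moving)
    n_stops <- if (nrow(gaps) == 0L) 0L else {
      sum(gaps$start > 1L & gaps$end < length(moving))
    }
    list(trajectory = traj,
         truth = list(schedule = data.frame(moving = moving, bout_id = bid),
                      bouts = bouts, n_bouts = n_bouts, n_stops = n_stops,
                      frame_role = frame_role, params = par,
                      label = cfg$label))
  })
}

# fast path: no zone bias, no social modulation
simulate_vectorized <- function(cfg, par, n_steps) {
  dt <- cfg$dt_s
  sch <- draw_schedule(n_steps, dt, par$bout_rate, par$mean_bout,
                       cfg$bout_rate_halflife_s)
  bid <- sch$bout_id
  speed <- numeric(n_steps)
  runs <- true_runs(bid > 0L)
  if (nrow(runs) > 0L) {
    # trapezoidal speed profile per bout, fully vectorized over bouts
    within <- sequence(runs$length)
    lens <- rep(runs$length, runs$length)
    idx <- sequence(runs$length, from = runs$start)
    speed[idx] <- pmin(par$cruise, par$accel * dt * within,
                       par$decel * dt * (lens - within + 1L))
  }
  mov <- bid > 0L
  n_mov <- sum(mov)
  dtheta <- rvonmises(n_mov, cfg$heading_concentration)
  theta0 <- stats::runif(1, -pi, pi)
  theta_mov <- theta0 + cumsum(dtheta)
  dx <- numeric(n_steps); dy <- numeric(n_steps)
  dx[mov] <- speed[mov] * dt * cos(theta_mov)
  dy[mov] <- speed[mov] * dt * sin(theta_mov)
  x <- fold_reflect(cfg$start_xy[1] + c(0, cumsum(dx)), cfg$arena$bounds_cm[1])
  y <- fold_reflect(cfg$start_xy[2] + c(0, cumsum(dy)), cfg$arena$bounds_cm[2])
  list(x = x, y = y, bout_id = bid, speed = speed)
}

# state-machine path: zone bias and/or social modulation
simulate_loop <- function(cfg, par, n_steps) {
  dt <- cfg$dt_s
  W <- cfg$arena$bounds_cm[1]; H <- cfg$arena$bounds_cm[2]
  zones <- cfg$arena$zones
  bias <- cfg$zone_bias
  mod <- cfg$social_modulation %||% list(accel = 1, stop_rate = 1, speed = 1)
  is_3c <- cfg$arena$name == "three_chamber"
  dividers <- if (is_3c) c(W / 3, 2 * W / 3) else numeric(0)
  door <- attr(cfg$arena, "door_cm") %||% H
  door_lo <- (H - door) / 2; door_hi <- (H + door) / 2
  role_at <- function(px, py) {
    for (k in seq_len(nrow(zones))) {
      if (px >= zones$x0[k] && px < zones$x1[k] &&
          py >= zones$y0[k] && py < zones$y1[k]) return(zones$role[k])
    }
    NA_character_
  }
  weight_of <- function(role) {
    if (is.null(bias) || is.na(role) || !(role %in% names(bias))) 1
    else bias[[role]]
  }
  # weighted reorientation targets: zone centers sampled proportional to
  # their role weight, at rate zone_attract_hz per second of movement
  attract_hz <- cfg$zone_attract_hz %||% 0.5
  zone_w <- vapply(zones$role, weight_of, numeric(1))
  zone_cx <- (zones$x0 + zones$x1) / 2
  zone_cy <- (zones$y0 + zones$y1) / 2
  use_attraction <- !is.null(bias) && any(zone_w != zone_w[1])
  x <- numeric(n_steps + 1L); y <- numeric(n_steps + 1L)
  bout_id <- integer(n_steps); speed <- numeric(n_steps)
  x[1] <- cfg$start_xy[1]; y[1] <- cfg$start_xy[2]
  # one turning-noise draw is consumed per step regardless of branch
  vm <- rvonmises(n_steps, cfg$heading_concentration)
  theta <- stats::runif(1, -pi, pi)
  state <- "immobile"; v <- 0; decelerating <- FALSE; bid <- 0L
  for (i in seq_len(n_steps)) {
    role <- role_at(x[i], y[i])
    social <- identical(role, "chamber_social")
    m_acc <- if (social) mod$accel else 1
    m_stop <- if (social) mod$stop_rate else 1
    m_speed <- if (social) mod$speed else 1
    if (state == "immobile") {
      rate <- par$bout_rate * 2^(-(i - 1L) * dt / cfg$bout_rate_halflife_s)
      if (stats::runif(1) < 1 - exp(-rate * dt)) {
        state <- "moving"; decelerating <- FALSE; v <- 0; bid <- bid + 1L
      }
    }
    if (state == "immobile") {
      x[i + 1L] <- x[i]; y[i + 1L] <- y[i]
      next
    }
    cruise_eff <- par$cruise * m_speed
    if (!decelerating) {
      v <- min(v + par$accel * m_acc * dt, cruise_eff)
      if (stats::runif(1) < 1 - exp(-dt * m_stop / par$mean_bout)) {
        decelerating <- TRUE
      }
    } else {
      v <- v - par$decel * m_acc * dt
      if (v <= 0) {
        v <- 0; state <- "immobile"; decelerating <- FALSE
        x[i + 1L] <- x[i]; y[i + 1L] <- y[i]
        next
      }
    }
    step <- v * dt
    propose <- function(th) {
      px <- x[i] + step * cos(th); py <- y[i] + step * sin(th)
      # outer walls: specular reflection
      if (px < 0) px <- -px else if (px > W) px <- 2 * W - px
      if (py < 0) py <- -py else if (py > H) py <- 2 * H - py
      # three-chamber dividers: pass only through the door strip
      for (dv in dividers) {
        if ((x[i] - dv) * (px - dv) < 0 && (py < door_lo || py > door_hi)) {
          px <- 2 * dv - px
        }
      }
      c(px, py)
    }
    th1 <- if (use_attraction && stats::runif(1) < attract_hz * dt) {
      k <- sample.int(length(zone_w), 1L, prob = zone_w)
      atan2(zone_cy[k] - y[i], zone_cx[k] - x[i]) + vm[i]
    } else {
      theta + vm[i]
    }
    p1 <- propose(th1)
    theta <- th1
    x[i + 1L] <- p1[1]; y[i + 1L] <- p1[2]
    bout_id[i] <- bid; speed[i] <- v
  }
  list(x = x, y = y, bout_id = bout_id, speed = speed)
}

#' Phenotype preset simulation configs
#'
#' Encodes the qualitative group contrasts of the modeled experiment as
#' generative properties. `control_like` animals modulate their kinematics
#' in the social chamber (ramp acceleration x0.65, bout-termination hazard
#' x1.9) and prefer it (~63% occupancy). `vpa_like` animals have higher
#' baseline acceleration (x1.7) and much shorter bouts (x0.4, with the
#' initiation rate scaled x2.5 so the moving-time fraction — and hence
#' traveled distance and effective velocity — is preserved by
#' construction), no social modulation, and only a weak social-chamber
#' attraction (~50% occupancy, making their social/non-social count ratios
#' neutral). All magnitudes are tuning constants of the synthetic world,
#' not measured facts.
#'
#' @param phenotype `"control_like"` or `"vpa_like"`.
#' @param stage `"oft"` (5-min open field), `"habituation"` (5-min centre
#'   habituation in the three-chamber box) or `"social"` (10-min social
#'   stage).
#' @param seed RNG seed stored in the config.
#' @param subject_sd per-subject lognormal multiplier SD (default 0.15).
#' @param ... overrides passed to [simulation_config()].
#' @return `ek_simconfig`.
#' @export
phenotype_preset <- function(phenotype = c("control_like", "vpa_like"),
                             stage = c("oft", "habituation", "social"),
                             seed = 1, subject_sd = 0.15, ...) {
  phenotype <- match.arg(phenotype)
  stage <- match.arg(stage)
  arena <- switch(stage,
                  oft = make_open_field(),
                  habituation = make_three_chamber(),
                  social = make_three_chamber())
  duration <- if (stage == "social") 600 else 300
  # the ramp rate must span several frames at 30 fps (cruise / (a * dt)
  # frames) or the measured mean positive velocity increment no longer
  # tracks it; 80 cm/s^2 with an 18 cm/s cruise gives ~7-frame ramps
  base <- list(arena = arena, duration_s = duration, dt_s = 1 / 30,
               bout_rate_hz = 1, mean_bout_s = 1,
               ramp_accel_cm_s2 = 80, cruise_speed_cm_s = 18,
               ramp_decel_cm_s2 = 80, heading_concentration = 4,
               subject_sd = subject_sd, seed = seed, label = phenotype)
  if (phenotype == "vpa_like") {
    base$ramp_accel_cm_s2 <- base$ramp_accel_cm_s2 * 1.7
    base$ramp_decel_cm_s2 <- base$ramp_decel_cm_s2 * 1.7
    base$mean_bout_s <- base$mean_bout_s * 0.4
    # initiation-rate compensation: with bouts 0.4x as long, a bare 1/0.4
    # rate raise preserves moving time but not distance (short bouts spend
    # proportionally more time in ramps); 2.9 is the calibrated
    # distance-neutral point, keeping the preset distance/velocity-neutral
    # by construction
    base$bout_rate_hz <- base$bout_rate_hz * 2.9
  }
  if (stage == "social") {
    # weights/rates calibrated once against the stated occupancies
    # (~63% social time for controls, ~50% for the treated phenotype so
    # its social/non-social count ratios are neutral); see the methods
    # vignette for the calibration rationale
    if (phenotype == "control_like") {
      base$social_modulation <- list(accel = 0.65, stop_rate = 1.9, speed = 1)
      base$zone_bias <- c(chamber_social = 2.5)
      base$zone_attract_hz <- 2
    } else {
      base$zone_bias <- c(chamber_social = 2.4)
      base$zone_attract_hz <- 3
    }
  }
  args <- utils::modifyList(base, list(...))
  do.call(simulation_config, args)
}

#' Simulate a two-group cohort
#'
#' Generates `n_per_group` subjects per group from a control and a treated
#' config; subject `i` of the cohort uses seed `base_seed + i`, so the
#' whole cohort is a pure function of (configs, base_seed).
#'
#' @param control_cfg,treated_cfg [simulation_config()]s (e.g. from
#'   [phenotype_preset()]).
#' @param n_per_group subjects per group (>= 1).
#' @param base_seed integer; per-subject seeds are consecutive from it.
#' @return list with `manifest` (subject_id, group, seed), `trajectories`
#'   (named list of [trajectory()]s) and `truths`.
#' @export
make_cohort <- function(control_cfg, treated_cfg, n_per_group,
                        base_seed = 1) {
  if (n_per_group < 1) ek_stop("n_per_group must be >= 1", "ek_invalid_input")
  manifest <- NULL; trajectories <- list(); truths <- list()
  idx <- 0L
  for (grp in c("control", "treated")) {
    cfg0 <- if (grp == "control") control_cfg else treated_cfg
    for (i in seq_len(n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", grp, i)
      cfg <- cfg0
      cfg$seed <- base_seed + idx
      sim <- simulate_trajectory(cfg, subject_id = sid, group_label = grp)
      trajectories[[sid]] <- sim$trajectory
      truths[[sid]] <- sim$truth
      manifest <- rbind(manifest, data.frame(
        subject_id = sid, group = grp, seed = cfg$seed,
        phenotype = cfg$label, stringsAsFactors = FALSE))
    }
  }
  list(manifest = manifest, trajectories = trajectories, truths = truths)
}

#' Render a trajectory as a synthetic grayscale frame stack
#'
#' Draws a filled dark disc at the calibrated pixel position of each frame
#' on a light background, adds i.i.d. Gaussian pixel noise, clips to
#' [0, 255] and rounds — a ground-truthed fixture for the tracking chain.
#'
#' @param traj an [trajectory()].
#' @param cal a [calibration()] mapping cm to pixels.
#' @param blob_radius_px disc radius (px).
#' @param blob_intensity,background_intensity gray levels (0-255); the blob
#'   must be darker than the background by at least `3 * noise_sd`.
#' @param noise_sd Gaussian pixel noise SD.
#' @param frame_dims `c(height, width)` in px; default: tight fit to the
#'   path plus a margin.
#' @param seed RNG seed for the pixel noise.
#' @return list with `stack` (a [frame_stack()]) and `truth_px`
#'   (data.frame `frame`, `x_px`, `y_px` of true disc centers).
#' @export
render_frames <- function(traj, cal, blob_radius_px = 4,
                          blob_intensity = 30, background_intensity = 220,
                          noise_sd = 5, frame_dims = NULL, seed = 1) {
  if (background_intensity - blob_intensity < 3 * noise_sd) {
    ek_stop("blob must be darker than background by >= 3 * noise_sd",
            "ek_invalid_config")
  }
  x_px <- traj$x_cm * cal$px_per_cm_x + cal$origin_px[1]
  y_px <- traj$y_cm * cal$px_per_cm_y + cal$origin_px[2]
  r <- blob_radius_px
  if (is.null(frame_dims)) {
    frame_dims <- c(ceiling(max(y_px) + r + 2) + 1,
                    ceiling(max(x_px) + r + 2) + 1)
  }
  nr <- frame_dims[1]; nc <- frame_dims[2]
  if (any(x_px - r < 0) || any(y_px - r < 0) ||
      any(x_px + r > nc - 1) || any(y_px + r > nr - 1)) {
    ek_stop("blob leaves the frame; enlarge frame_dims or shift origin",
            "ek_invalid_config")
  }
  with_seed_local(seed, {
    frames <- vector("list", nrow(traj))
    for (f in seq_len(nrow(traj))) {
      img <- matrix(background_intensity, nr, nc)
      cx <- x_px[f]; cy <- y_px[f]
      cols <- max(0, floor(cx - r)):min(nc - 1, ceiling(cx + r))
      rows <- max(0, floor(cy - r)):min(nr - 1, ceiling(cy + r))
      dx2 <- (cols - cx)^2
      dy2 <- (rows - cy)^2
      mask <- outer(dy2, dx2, "+") <= r^2
      sub <- img[rows + 1, cols + 1, drop = FALSE]
      sub[mask] <- blob_intensity
      img[rows + 1, cols + 1] <- sub
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
      frames[[f]] <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
                            nr, nc)
    }
    list(stack = frame_stack(frames, frame_interval_s = traj_dt(traj),
                             source_id = sprintf("render:%s",
                                                 attr(traj, "subject_id"))),
         truth_px = data.frame(frame = traj$frame, x_px = x_px,
                               y_px = y_px))
  })
}
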