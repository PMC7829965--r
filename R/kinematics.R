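#' Segment a trajectory into movement bouts and stops
#'
#' The moving/immobile split drives all five kinematic statistics. A *step*
#' is the displacement between consecutive frames; step `i` is *moving* when
#' its Euclidean length exceeds `epsilon_cm` (strictly). A *bout* is a
#' maximal run of moving steps. A *stop* is a maximal run of immobile steps
#' flanked by moving steps on both sides — an interruption of one movement
#' series by at least one immobile frame, followed by more movement. Leading
#' and trailing immobility therefore never counts as a stop, and the number
#' of stops is always `max(0, n_bouts - 1)`.
#'
#' `epsilon_cm` is the immobility threshold. Real centroids jitter by a
#' fraction of a body length even when the animal is still, so 0 is almost
#' never the right value; the default 0.3 cm/step corresponds to sub-body
#' jitter at webcam frame rates and is always echoed in summaries.
#'
#' @param traj an [trajectory()].
#' @param epsilon_cm immobility threshold in cm per step (>= 0).
#' @return `ek_segmentation`: list with `step_cm` (length `n_frames - 1`),
#'   `moving` (logical, same length), `epsilon_cm`, `dt_s`, `bouts` and
#'   `stops` (data.frames of 1-based inclusive step indices).
#' @examples
#' tr <- trajectory(c(0, 1, 2, 2, 3), rep(0, 5), dt_s = 0.1)
#' seg <- segment_movement(tr, epsilon_cm = 0.1)
#' count_stops(seg)
#' @export
segment_movement <- function(traj, epsilon_cm = 0.3) {
  if (!inherits(traj, "ek_trajectory")) {
    ek_stop("`traj` must be an ek_trajectory", "ek_invalid_input")
  }
  assert_scalar_num(epsilon_cm, "epsilon_cm", lower = 0)
  if (nrow(traj) < 2L) ek_stop("need >= 2 frames", "ek_invalid_input")
  step_cm <- step_lengths(traj$x_cm, traj$y_cm)
  moving <- step_cm > epsilon_cm
  bouts <- true_runs(moving)
  stops <- true_runs(!moving)
  if (nrow(stops) > 0L) {
    # keep only immobile runs strictly between two bouts
    flanked <- stops$start > 1L & stops$end < length(moving)
    stops <- stops[flanked, , drop = FALSE]
    rownames(stops) <- NULL
  }
  structure(list(step_cm = step_cm, moving = moving,
                 epsilon_cm = epsilon_cm, dt_s = traj_dt(traj),
                 bouts = bouts, stops = stops),
            class = "ek_segmentation")
}

#' @export
print.ek_segmentation <- function(x, ...) {
  cat(sprintf("<ek_segmentation> %d steps, %d moving, %d bouts, %d stops (eps = %g cm)\n",
              length(x$moving), sum(x$moving), nrow(x$bouts), nrow(x$stops),
              x$epsilon_cm))
  invisible(x)
}

#' Traveled distance
#'
#' Cumulative frame-to-frame displacement. By default only moving steps are
#' summed: sub-threshold jitter is what the immobility split exists to
#' discard, and excluding it keeps the identity
#' `effective_velocity * moving_time == traveled_distance` exact.
#' `include_jitter = TRUE` restores the all-steps sum.
#'
#' @param seg an [segment_movement()] result.
#' @param include_jitter also sum sub-threshold steps.
#' @return distance in cm (>= 0).
#' @export
traveled_distance <- function(seg, include_jitter = FALSE) {
  if (include_jitter) sum(seg$step_cm) else sum(seg$step_cm[seg$moving])
}

#' Effective velocity
#'
#' Total distance divided by the time during which the animal was actually
#' moving — "effective", not mean, velocity: immobile time is excluded from
#' the denominator.
#'
#' @param seg an [segment_movement()] result.
#' @return cm/s, or `NA` when the animal never moved (degenerate).
#' @export
effective_velocity <- function(seg) {
  n_mov <- sum(seg$moving)
  if (n_mov == 0L) return(NA_real_)
  traveled_distance(seg) / (n_mov * seg$dt_s)
}

#' Mean acceleration
#'
#' Per-step speed is `displacement / dt` for moving steps. Over consecutive
#' step pairs that are *both* moving (velocity increments are never taken
#' across a stop), the velocity change `dv = v[i+1] - v[i]` is formed and the
#' mean of the *positive* increments, divided by `dt`, is returned (cm/s^2).
#'
#' `denominator = "positive"` (default) averages only the positive
#' increments; `"all_pairs"` averages `max(dv, 0)` over all moving pairs,
#' the alternative reading of "mean positive change of velocity". The value
#' is 0 when moving pairs exist but none accelerates, and `NA` when fewer
#' than 2 consecutive moving steps exist. An increment counts as positive
#' only when it exceeds 1e-9 cm/s: two steps of equal true speed can differ
#' by ~1e-15 after coordinate round-off, and admitting such ties as
#' "positive" would flood the mean with zeros.
#'
#' @param seg an [segment_movement()] result.
#' @param denominator `"positive"` or `"all_pairs"`.
#' @return cm/s^2.
#' @export
mean_acceleration <- function(seg, denominator = c("positive", "all_pairs")) {
  denominator <- match.arg(denominator)
  m <- seg$moving
  if (length(m) < 2L) return(NA_real_)
  both <- m[-length(m)] & m[-1L]
  if (!any(both)) return(NA_real_)
  v <- seg$step_cm / seg$dt_s
  dv <- (v[-1L] - v[-length(v)])[both]
  pos <- dv[dv > EK_DV_TOL]
  if (denominator == "positive") {
    if (length(pos) == 0L) return(0)
    mean(pos) / seg$dt_s
  } else {
    mean(dv * (dv > EK_DV_TOL)) / seg$dt_s
  }
}

# velocity-increment tie tolerance (cm/s); see mean_acceleration()
EK_DV_TOL <- 1e-9

#' Number of stops
#'
#' Times a movement series was interrupted by at least one immobile frame
#' and then resumed. See [segment_movement()] for the flanking rule.
#'
#' @param seg an [segment_movement()] result.
#' @return integer count.
#' @export
count_stops <- function(seg) nrow(seg$stops)

#' Distance per stop
#'
#' Total traveled distance divided by the number of stops; `NA` when the
#' trajectory has no stops.
#'
#' @param seg an [segment_movement()] result.
#' @param include_jitter passed to [traveled_distance()].
#' @return cm, or `NA`.
#' @export
distance_per_stop <- function(seg, include_jitter = FALSE) {
  ns <- count_stops(seg)
  if (ns == 0L) return(NA_real_)
  traveled_distance(seg, include_jitter) / ns
}

#' Summarize the five kinematic statistics of a trajectory
#'
#' One segmentation pass produces traveled distance, effective velocity,
#' mean acceleration, stops and distance/stop, plus moving time and step
#' counts. A subject that never moved is flagged `degenerate` and all rate
#' statistics are `NA`; degenerate subjects are excluded from group
#' statistics downstream (mirroring the exclusion of animals that did not
#' move at all).
#'
#' @param traj an [trajectory()].
#' @param epsilon_cm immobility threshold (cm/step).
#' @param acceleration_denominator passed to [mean_acceleration()].
#' @param include_jitter passed to [traveled_distance()].
#' @return `ek_summary`: one-row data.frame with columns `subject_id`,
#'   `group`, `stage`, `n_steps`, `moving_steps`, `moving_time_s`,
#'   `distance_cm`, `eff_vel_cm_s`, `mean_acc_cm_s2`, `stops`,
#'   `dist_per_stop_cm`, `degenerate`, `epsilon_cm`.
#' @examples
#' tr <- trajectory(cumsum(runif(60)), cumsum(runif(60)), dt_s = 1 / 30)
#' summarize_kinematics(tr, epsilon_cm = 0.3)
#' @export
summarize_kinematics <- function(traj, epsilon_cm = 0.3,
                                 acceleration_denominator = "positive",
                                 include_jitter = FALSE) {
  seg <- segment_movement(traj, epsilon_cm)
  out <- summarize_segmentation(
    seg,
    subject_id = attr(traj, "subject_id"),
    group = attr(traj, "group_label"),
    stage = attr(traj, "test_stage"),
    acceleration_denominator = acceleration_denominator,
    include_jitter = include_jitter
  )
  out
}

# shared by whole-session, per-minute and per-zone summaries
summarize_segmentation <- function(seg, subject_id = "", group = "",
                                   stage = "",
                                   acceleration_denominator = "positive",
                                   include_jitter = FALSE) {
  n_mov <- sum(seg$moving)
  degenerate <- n_mov == 0L
  dist <- traveled_distance(seg, include_jitter)
  out <- data.frame(
    subject_id = subject_id, group = group, stage = stage,
    n_steps = length(seg$moving), moving_steps = n_mov,
    moving_time_s = n_mov * seg$dt_s,
    distance_cm = if (degenerate) 0 else dist,
    eff_vel_cm_s = effective_velocity(seg),
    mean_acc_cm_s2 = if (degenerate) NA_real_ else
      mean_acceleration(seg, acceleration_denominator),
    stops = count_stops(seg),
    dist_per_stop_cm = distance_per_stop(seg, include_jitter),
    degenerate = degenerate,
    epsilon_cm = seg$epsilon_cm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ek_summary", "data.frame")
  out
}

#' Minute-by-minute kinematic profile
#'
#' Frames are assigned to half-open windows `[k * bin_s, (k + 1) * bin_s)`
#' relative to session start, and each bin is segmented and summarized
#' *independently*: a stop spanning a bin boundary is counted in neither
#' bin, and per-bin distances sum to the whole-session distance up to one
#' boundary step per bin edge. Bins with fewer than 2 frames are dropped.
#'
#' @param traj an [trajectory()].
#' @param epsilon_cm immobility threshold (cm/step).
#' @param bin_s bin width in seconds (default 60).
#' @param ... passed to [summarize_kinematics()] internals.
#' @return data.frame: one [summarize_kinematics()] row per bin plus a
#'   leading `minute` column (1-based bin number).
#' @export
bin_by_minute <- function(traj, epsilon_cm = 0.3, bin_s = 60, ...) {
  assert_scalar_num(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
  rel <- traj$t_s - traj$t_s[1L]
  bin <- floor(rel / bin_s)
  out <- NULL
  for (k in sort(unique(bin))) {
    idx <- which(bin == k)
    if (length(idx) < 2L) next
    seg <- segment_movement(traj_subset(traj, idx), epsilon_cm)
    row <- summarize_segmentation(seg,
                                  subject_id = attr(traj, "subject_id"),
                                  group = attr(traj, "group_label"),
                                  stage = attr(traj, "test_stage"), ...)
    out <- rbind(out, cbind(minute = k + 1L, row))
  }
  out
}

#' Straight-line walking segments
#'
#' Detects runs of consecutive moving steps whose *straightness* (net
#' displacement over path length, in [0, 1]) reaches `straightness_min`, of
#' at least `min_steps` steps, and reports walking velocity = path length /
#' duration for each. Candidate windows are scanned inside each movement
#' bout and only maximal qualifying windows (not contained in a longer
#' qualifying window) are kept. Detection is automated where the original
#' procedure picked segments visually, so counts are comparable in kind,
#' not number.
#'
#' @param traj an [trajectory()].
#' @param min_steps minimum number of steps (>= 2, default 3).
#' @param straightness_min minimum net/path ratio in (0, 1] (default 0.95).
#' @param epsilon_cm immobility threshold (cm/step).
#' @return data.frame with columns `start_frame`, `end_frame` (0-based frame
#'   indices bounding the run), `path_length_cm`, `duration_s`,
#'   `straightness`, `walking_velocity_cm_s`.
#' @export
straight_walk_segments <- function(traj, min_steps = 3,
                                   straightness_min = 0.95,
                                   epsilon_cm = 0.3) {
  if (min_steps < 2) ek_stop("min_steps must be >= 2", "ek_invalid_input")
  if (straightness_min <= 0 || straightness_min > 1) {
    ek_stop("straightness_min must be in (0, 1]", "ek_invalid_input")
  }
  seg <- segment_movement(traj, epsilon_cm)
  out <- NULL
  cum <- c(0, cumsum(seg$step_cm))
  for (b in seq_len(nrow(seg$bouts))) {
    s0 <- seg$bouts$start[b]; e0 <- seg$bouts$end[b]
    if (e0 - s0 + 1L < min_steps) next
    qual <- list()
    # steps i..j correspond to frames i..(j+1) (1-based)
    for (i in s0:(e0 - min_steps + 1L)) {
      for (j in (i + min_steps - 1L):e0) {
        path <- cum[j + 1L] - cum[i]
        net <- sqrt((traj$x_cm[j + 1L] - traj$x_cm[i])^2 +
                    (traj$y_cm[j + 1L] - traj$y_cm[i])^2)
        if (path > 0 && net / path >= straightness_min) {
          qual[[length(qual) + 1L]] <- c(i, j)
        }
      }
    }
    if (length(qual) == 0L) next
    qm <- do.call(rbind, qual)
    maximal <- vapply(seq_len(nrow(qm)), function(r) {
      !any(qm[, 1] <= qm[r, 1] & qm[, 2] >= qm[r, 2] &
             (qm[, 1] < qm[r, 1] | qm[, 2] > qm[r, 2]))
    }, logical(1))
    qm <- qm[maximal, , drop = FALSE]
    for (r in seq_len(nrow(qm))) {
      i <- qm[r, 1]; j <- qm[r, 2]
      path <- cum[j + 1L] - cum[i]
      net <- sqrt((traj$x_cm[j + 1L] - traj$x_cm[i])^2 +
                  (traj$y_cm[j + 1L] - traj$y_cm[i])^2)
      dur <- (j - i + 1L) * seg$dt_s
      out <- rbind(out, data.frame(
        start_frame = i - 1L, end_frame = j, path_length_cm = path,
        duration_s = dur, straightness = net / path,
        walking_velocity_cm_s = path / dur))
    }
  }
  out %||% data.frame(start_frame = integer(0), end_frame = integer(0),
                      path_length_cm = numeric(0), duration_s = numeric(0),
                      straightness = numeric(0),
                      walking_velocity_cm_s = numeric(0))
}

#' Returns (half turns) and circling (full turns)
#'
#' Headings are taken per moving step (`atan2` of the step vector) and
#' signed heading changes are accumulated along runs of consistent turning
#' direction inside each movement bout, with the run capped at `window_s`
#' seconds. Each completed 360 degrees of same-signed turning counts one
#' circling event (consuming its frames); a terminated run whose residual
#' lies in [180, 360) degrees counts one return. This replaces visual
#' scoring and is flagged as a heuristic: thresholds are configuration, not
#' facts.
#'
#' @param traj an [trajectory()].
#' @param window_s maximum time a turning run may span (default 3 s).
#' @param epsilon_cm immobility threshold (cm/step).
#' @param angle_tol_deg slack subtracted from the 180/360 degree thresholds
#'   (default 10): a discretized closed loop of n steps only accumulates
#'   `360 * (n - 1) / n` degrees of heading change.
#' @param arena optional [arena_spec()]; when supplied, counts are also
#'   split by the zone role where each event completed.
#' @return list with `returns`, `circlings` (integer counts) and, when an
#'   arena is given, `by_role` (data.frame role/returns/circlings).
#' @export
turning_events <- function(traj, window_s = 3, epsilon_cm = 0.3,
                           angle_tol_deg = 10, arena = NULL) {
  assert_scalar_num(window_s, "window_s", lower = 0, strict_lower = TRUE)
  seg <- segment_movement(traj, epsilon_cm)
  max_steps <- max(1L, floor(window_s / seg$dt_s))
  tol <- angle_tol_deg * pi / 180
  circ_thr <- 2 * pi - tol
  ret_thr <- pi - tol
  returns <- 0L; circlings <- 0L
  events <- list()
  heading <- atan2(diff(traj$y_cm), diff(traj$x_cm))
  record <- function(kind, step_idx) {
    events[[length(events) + 1L]] <<- list(kind = kind, step = step_idx)
  }
  finish_run <- function(total, step_idx) {
    if (abs(total) >= ret_thr && abs(total) < circ_thr) {
      returns <<- returns + 1L
      record("return", step_idx)
    }
  }
  for (b in seq_len(nrow(seg$bouts))) {
    s0 <- seg$bouts$start[b]; e0 <- seg$bouts$end[b]
    if (e0 <= s0) next
    total <- 0; run_len <- 0L
    for (i in (s0 + 1L):e0) {
      d <- heading[i] - heading[i - 1L]
      d <- atan2(sin(d), cos(d))  # wrap to (-pi, pi]
      if (run_len > 0L && sign(d) != 0 && sign(d) != sign(total) &&
          total != 0) {
        finish_run(total, i - 1L)
        total <- 0; run_len <- 0L
      }
      total <- total + d
      run_len <- run_len + 1L
      if (abs(total) >= circ_thr) {
        circlings <- circlings + 1L
        record("circling", i)
        total <- 0; run_len <- 0L
      } else if (run_len >= max_steps) {
        finish_run(total, i)
        total <- 0; run_len <- 0L
      }
    }
    finish_run(total, e0)
  }
  out <- list(returns = returns, circlings = circlings)
  if (!is.null(arena) && length(events) > 0L) {
    roles <- vapply(events, function(ev) {
      zid <- assign_zone(traj$x_cm[ev$step + 1L], traj$y_cm[ev$step + 1L],
                         arena)
      if (is.na(zid)) "unassigned" else
        arena$zones$role[arena$zones$zone_id == zid]
    }, character(1))
    kinds <- vapply(events, `[[`, character(1), "kind")
    out$by_role <- as.data.frame(table(role = roles, kind = kinds),
                                 responseName = "count")
  } else if (!is.null(arena)) {
    out$by_role <- data.frame(role = character(0), kind = character(0),
                              count = integer(0))
  }
  out
}
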