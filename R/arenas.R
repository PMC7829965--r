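ZONE_ROLES <- c("corner", "center", "chamber_social", "chamber_center",
                "chamber_empty", "arm_open", "arm_closed", "hub", "other")

#' Arena specification
#'
#' Named axis-aligned rectangular zones in arena coordinates (cm, origin
#' top-left, x rightward, y downward). Rectangles are treated half-open,
#' `[x0, x1) x [y0, y1)`, and the first matching zone in declaration order
#' wins, so a point on a shared boundary is assigned deterministically.
#'
#' @param name arena name.
#' @param bounds_cm numeric `c(width, height)` in cm.
#' @param zones data.frame with columns `zone_id`, `x0`, `y0`, `x1`, `y1`,
#'   `role`; roles must come from the known set (corner, center,
#'   chamber_social, chamber_center, chamber_empty, arm_open, arm_closed,
#'   hub, other); zones must lie within bounds and ids must be unique.
#' @return `ek_arena` object.
#' @seealso [make_open_field()], [make_three_chamber()], [make_epm()]
#' @export
arena_spec <- function(name, bounds_cm, zones) {
  if (length(bounds_cm) != 2L || any(bounds_cm <= 0)) {
    ek_stop("bounds_cm must be positive c(width, height)", "ek_invalid_config")
  }
  need <- c("zone_id", "x0", "y0", "x1", "y1", "role")
  if (!all(need %in% names(zones))) {
    ek_stop("zones need columns zone_id,x0,y0,x1,y1,role", "ek_invalid_config")
  }
  if (anyDuplicated(zones$zone_id)) {
    ek_stop("zone_ids must be unique", "ek_invalid_config")
  }
  if (!all(zones$role %in% ZONE_ROLES)) {
    ek_stop(sprintf("unknown zone role(s): %s; allowed: %s",
                    paste(setdiff(zones$role, ZONE_ROLES), collapse = ","),
                    paste(ZONE_ROLES, collapse = ",")), "ek_invalid_config")
  }
  eps <- 1e-9
  inside <- zones$x0 >= -eps & zones$y0 >= -eps &
    zones$x1 <= bounds_cm[1] + eps & zones$y1 <= bounds_cm[2] + eps &
    zones$x0 < zones$x1 & zones$y0 < zones$y1
  if (!all(inside)) {
    ek_stop(sprintf("zone(s) outside bounds or empty: %s",
                    paste(zones$zone_id[!inside], collapse = ",")),
            "ek_invalid_config")
  }
  structure(list(name = name, bounds_cm = as.numeric(bounds_cm),
                 zones = as.data.frame(zones, stringsAsFactors = FALSE)),
            class = "ek_arena")
}

#' @export
print.ek_arena <- function(x, ...) {
  cat(sprintf("<ek_arena> %s  %g x %g cm, %d zones\n", x$name,
              x$bounds_cm[1], x$bounds_cm[2], nrow(x$zones)))
  print(x$zones, row.names = FALSE)
  invisible(x)
}

#' Open-field arena (3 x 3 quadrant grid)
#'
#' A square open field partitioned into a 3 x 3 grid of quadrants: the four
#' grid corners are `corner` zones, the central cell is `center`, and the
#' four edge cells are `other`. The default is the 60 cm arena with
#' 20 x 20 cm quadrants; any side/quadrant pair with
#' `3 * quadrant_cm == side_cm` is accepted.
#'
#' @param side_cm arena side (cm).
#' @param quadrant_cm grid cell side (cm), must be `side_cm / 3`.
#' @return `ek_arena`.
#' @export
make_open_field <- function(side_cm = 60, quadrant_cm = side_cm / 3) {
  assert_scalar_num(side_cm, "side_cm", lower = 0, strict_lower = TRUE)
  if (abs(3 * quadrant_cm - side_cm) > 1e-9) {
    ek_stop("open-field layout requires 3 * quadrant_cm == side_cm",
            "ek_invalid_config")
  }
  q <- quadrant_cm
  cell <- function(cx, cy) c(cx * q, cy * q, (cx + 1) * q, (cy + 1) * q)
  ids <- c("corner_nw", "edge_n", "corner_ne",
           "edge_w", "center", "edge_e",
           "corner_sw", "edge_s", "corner_se")
  roles <- c("corner", "other", "corner",
             "other", "center", "other",
             "corner", "other", "corner")
  grid <- expand.grid(cx = 0:2, cy = 0:2)
  rect <- t(mapply(cell, grid$cx, grid$cy))
  zones <- data.frame(zone_id = ids, x0 = rect[, 1], y0 = rect[, 2],
                      x1 = rect[, 3], y1 = rect[, 4], role = roles,
                      stringsAsFactors = FALSE)
  arena_spec("open_field", c(side_cm, side_cm), zones)
}

#' Three-chamber sociability arena
#'
#' Three abutting chambers along x. Roles are `chamber_social`,
#' `chamber_center`, `chamber_empty`, with the social chamber on the
#' configured side. Chambers share boundaries; the half-open assignment rule
#' gives each dividing line (where the 10 x 10 cm doors sit) to the chamber
#' on its right, and transitional door crossings are assigned to the center
#' chamber by the zone declaration order, so they never inflate
#' social-chamber statistics.
#'
#' @param chamber_w,chamber_h single chamber width/height (cm); defaults
#'   30 x 22.
#' @param door_cm door opening (cm), must not exceed `chamber_h`.
#' @param social_side `"left"` or `"right"`.
#' @return `ek_arena` with total bounds `3 * chamber_w x chamber_h` and a
#'   `social_side` attribute.
#' @export
make_three_chamber <- function(chamber_w = 30, chamber_h = 22, door_cm = 10,
                               social_side = c("left", "right")) {
  social_side <- match.arg(social_side)
  assert_scalar_num(chamber_w, "chamber_w", lower = 0, strict_lower = TRUE)
  assert_scalar_num(chamber_h, "chamber_h", lower = 0, strict_lower = TRUE)
  if (door_cm > chamber_h) {
    ek_stop("door_cm cannot exceed chamber_h", "ek_invalid_config")
  }
  roles_lr <- if (social_side == "left") {
    c("chamber_social", "chamber_center", "chamber_empty")
  } else {
    c("chamber_empty", "chamber_center", "chamber_social")
  }
  # center chamber declared first: boundary/door points fall to the center
  ord <- c(2L, 1L, 3L)
  zones <- data.frame(
    zone_id = c("chamber_left", "chamber_mid", "chamber_right")[ord],
    x0 = (c(0, 1, 2) * chamber_w)[ord], y0 = 0,
    x1 = (c(1, 2, 3) * chamber_w)[ord], y1 = chamber_h,
    role = roles_lr[ord], stringsAsFactors = FALSE)
  out <- arena_spec("three_chamber", c(3 * chamber_w, chamber_h), zones)
  attr(out, "social_side") <- social_side
  attr(out, "door_cm") <- door_cm
  out
}

#' Elevated plus maze arena
#'
#' Plus-shaped layout: two open arms (horizontal), two closed arms
#' (vertical) and a central hub of `arm_w x arm_w`. The hub counts toward
#' neither arm type; closed-arm occupancy uses total session time as the
#' denominator.
#'
#' @param arm_l,arm_w arm length and width (cm); defaults 40 x 10.
#' @return `ek_arena` with square bounds `2 * arm_l + arm_w`.
#' @export
make_epm <- function(arm_l = 40, arm_w = 10) {
  assert_scalar_num(arm_l, "arm_l", lower = 0, strict_lower = TRUE)
  assert_scalar_num(arm_w, "arm_w", lower = 0, strict_lower = TRUE)
  side <- 2 * arm_l + arm_w
  c0 <- arm_l; c1 <- arm_l + arm_w
  zones <- data.frame(
    zone_id = c("hub", "arm_open_w", "arm_open_e", "arm_closed_n",
                "arm_closed_s"),
    x0 = c(c0, 0, c1, c0, c0),
    y0 = c(c0, c0, c0, 0, c1),
    x1 = c(c1, c0, side, c1, c1),
    y1 = c(c1, c1, c1, c0, side),
    role = c("hub", "arm_open", "arm_open", "arm_closed", "arm_closed"),
    stringsAsFactors = FALSE)
  arena_spec("epm", c(side, side), zones)
}

#' Assign points to arena zones
#'
#' Vectorized half-open rectangle containment; the first matching zone in
#' declaration order wins; points outside all zones get `NA` (unassigned).
#'
#' @param x,y point coordinates (cm), equal length.
#' @param arena an [arena_spec()].
#' @return character vector of zone ids (`NA` = unassigned).
#' @export
assign_zone <- function(x, y, arena) {
  z <- arena$zones
  out <- rep(NA_character_, length(x))
  for (k in seq_len(nrow(z))) {
    hit <- is.na(out) & x >= z$x0[k] & x < z$x1[k] &
      y >= z$y0[k] & y < z$y1[k]
    out[hit] <- z$zone_id[k]
  }
  out
}

#' Zone occupancy of a trajectory
#'
#' Per-zone frame counts, seconds (`frames * dt`) and percentage of total
#' session time, plus role-level aggregates (e.g. the four open-field
#' corners pooled). Percentages over zones plus the unassigned remainder
#' sum to 100.
#'
#' @param traj an [trajectory()].
#' @param arena an [arena_spec()].
#' @return `ek_occupancy`: list with `zones` and `roles` data.frames
#'   (`frames`, `seconds`, `percent`), `unassigned_frames`, `total_frames`,
#'   `dt_s`.
#' @export
zone_occupancy <- function(traj, arena) {
  zid <- assign_zone(traj$x_cm, traj$y_cm, arena)
  n <- nrow(traj)
  dt <- traj_dt(traj)
  counts <- vapply(arena$zones$zone_id, function(id) sum(zid == id, na.rm = TRUE),
                   integer(1))
  zones <- data.frame(zone_id = arena$zones$zone_id,
                      role = arena$zones$role,
                      frames = as.integer(counts),
                      seconds = counts * dt,
                      percent = 100 * counts / n,
                      stringsAsFactors = FALSE)
  roles <- stats::aggregate(cbind(frames, seconds, percent) ~ role, zones, sum)
  structure(list(zones = zones, roles = roles,
                 unassigned_frames = sum(is.na(zid)),
                 total_frames = n, dt_s = dt),
            class = "ek_occupancy")
}

#' @export
print.ek_occupancy <- function(x, ...) {
  cat(sprintf("<ek_occupancy> %d frames (%d unassigned)\n",
              x$total_frames, x$unassigned_frames))
  print(x$roles, row.names = FALSE)
  invisible(x)
}

#' Per-zone-role kinematics
#'
#' Steps, not frames, carry kinematics: a step belongs to the zone role of
#' its *earlier* frame. Steps are grouped per role (or per pooled role
#' group), and the five statistics are computed within each group using the
#' whole-session segmentation. A stop is attributed to a group only when
#' the moving steps flanking it on both sides belong to that group; stops
#' whose flanking bouts straddle a boundary are counted in whole-session
#' totals but in no group (the count is reported as `boundary_stops`).
#'
#' @param traj an [trajectory()].
#' @param arena an [arena_spec()].
#' @param epsilon_cm immobility threshold (cm/step).
#' @param role_grouping named list mapping group name -> character vector of
#'   roles to pool; default: one group per role present in the arena.
#' @param acceleration_denominator passed to [mean_acceleration()].
#' @return list with `summaries` (data.frame, one [summarize_kinematics()]
#'   -style row per group; `area` column holds the group name) and
#'   `boundary_stops`.
#' @export
per_zone_kinematics <- function(traj, arena, epsilon_cm = 0.3,
                                role_grouping = NULL,
                                acceleration_denominator = "positive") {
  if (is.null(role_grouping)) {
    role_grouping <- as.list(unique(arena$zones$role))
    names(role_grouping) <- unlist(role_grouping)
  }
  seg <- segment_movement(traj, epsilon_cm)
  zid <- assign_zone(traj$x_cm, traj$y_cm, arena)
  role_of <- stats::setNames(arena$zones$role, arena$zones$zone_id)
  frame_role <- ifelse(is.na(zid), NA_character_, role_of[zid])
  step_role <- frame_role[-length(frame_role)]  # earlier frame's role
  v <- seg$step_cm / seg$dt_s
  mov <- seg$moving
  n_steps <- length(mov)
  # flanking moving step of each stop run (guaranteed to exist by flanking)
  stop_roles <- NULL
  if (nrow(seg$stops) > 0L) {
    stop_roles <- data.frame(
      before = step_role[seg$stops$start - 1L],
      after = step_role[seg$stops$end + 1L], stringsAsFactors = FALSE)
  }
  rows <- NULL
  stops_assigned <- 0L
  for (g in names(role_grouping)) {
    in_g <- !is.na(step_role) & step_role %in% role_grouping[[g]]
    mov_g <- mov & in_g
    n_mov <- sum(mov_g)
    dist <- sum(seg$step_cm[mov_g])
    # acceleration: consecutive pairs, both moving, both in group
    acc <- NA_real_
    if (n_steps >= 2L) {
      both <- mov[-n_steps] & mov[-1L] & in_g[-n_steps] & in_g[-1L]
      if (any(both)) {
        dv <- (v[-1L] - v[-n_steps])[both]
        pos <- dv[dv > EK_DV_TOL]
        acc <- if (acceleration_denominator == "positive") {
          if (length(pos) == 0L) 0 else mean(pos) / seg$dt_s
        } else mean(dv * (dv > EK_DV_TOL)) / seg$dt_s
      }
    }
    n_stops <- if (is.null(stop_roles)) 0L else {
      sum(stop_roles$before %in% role_grouping[[g]] &
            stop_roles$after %in% role_grouping[[g]], na.rm = TRUE)
    }
    stops_assigned <- stops_assigned + n_stops
    degenerate <- n_mov == 0L
    rows <- rbind(rows, data.frame(
      area = g,
      subject_id = attr(traj, "subject_id"),
      group = attr(traj, "group_label"),
      stage = attr(traj, "test_stage"),
      n_steps = sum(in_g), moving_steps = n_mov,
      moving_time_s = n_mov * seg$dt_s,
      distance_cm = dist,
      eff_vel_cm_s = if (degenerate) NA_real_ else dist / (n_mov * seg$dt_s),
      mean_acc_cm_s2 = if (degenerate) NA_real_ else acc,
      stops = n_stops,
      dist_per_stop_cm = if (n_stops > 0L) dist / n_stops else NA_real_,
      degenerate = degenerate,
      epsilon_cm = epsilon_cm,
      stringsAsFactors = FALSE))
  }
  list(summaries = rows,
       boundary_stops = count_stops(seg) - stops_assigned)
}

#' Social preference (% time in the social chamber)
#'
#' Occupancy percentage of the `chamber_social` role over the whole
#' session; the usual index of sociability in the three-chamber test.
#'
#' @param traj an [trajectory()].
#' @param arena a three-chamber [arena_spec()].
#' @return percent of session time (0-100).
#' @export
social_preference <- function(traj, arena) {
  if (!"chamber_social" %in% arena$zones$role) {
    ek_stop("arena has no chamber_social zone: not a three-chamber arena",
            "ek_invalid_config")
  }
  occ <- zone_occupancy(traj, arena)
  r <- occ$roles
  s <- r$percent[r$role == "chamber_social"]
  if (length(s) == 0L) 0 else s
}

#' Social / non-social kinematic ratio report
#'
#' The five kinematic statistics are evaluated separately in the social
#' area (the social chamber only) and the non-social area (center plus
#' empty chamber pooled), and each ratio social / non-social is reported.
#' A ratio below 1 for mean acceleration, or above 1 for stops, indicates
#' context modulation of that statistic. Ratios are `NA` when the
#' non-social value is not positive or either side is degenerate.
#'
#' @param traj an [trajectory()].
#' @param arena a three-chamber [arena_spec()].
#' @param epsilon_cm immobility threshold (cm/step).
#' @return `ek_social_ratio`: data.frame with columns `statistic`,
#'   `social`, `non_social`, `ratio`.
#' @export
social_ratio_report <- function(traj, arena, epsilon_cm = 0.3) {
  if (!"chamber_social" %in% arena$zones$role) {
    ek_stop("arena has no chamber_social zone", "ek_invalid_config")
  }
  pz <- per_zone_kinematics(
    traj, arena, epsilon_cm,
    role_grouping = list(social = "chamber_social",
                         non_social = c("chamber_center", "chamber_empty")))
  s <- pz$summaries[pz$summaries$area == "social", ]
  ns <- pz$summaries[pz$summaries$area == "non_social", ]
  stats_cols <- c(distance_cm = "distance_cm",
                  eff_vel_cm_s = "eff_vel_cm_s",
                  mean_acc_cm_s2 = "mean_acc_cm_s2",
                  stops = "stops",
                  dist_per_stop_cm = "dist_per_stop_cm")
  out <- data.frame(statistic = names(stats_cols),
                    social = NA_real_, non_social = NA_real_,
                    ratio = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(stats_cols)) {
    sv <- as.numeric(s[[stats_cols[i]]])
    nv <- as.numeric(ns[[stats_cols[i]]])
    out$social[i] <- sv
    out$non_social[i] <- nv
    if (!s$degenerate && !ns$degenerate && is.finite(sv) && is.finite(nv) &&
        nv > 0) {
      out$ratio[i] <- sv / nv
    }
  }
  class(out) <- c("ek_social_ratio", "data.frame")
  out
}
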