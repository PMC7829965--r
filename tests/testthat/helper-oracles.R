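# Independent oracles and fixture builders. These deliberately use plain
# loops and first-principles bookkeeping, not the package's vectorized
# code paths.

# build a trajectory from prescribed step displacements along x
traj_from_steps <- function(steps, dt = 0.1, ...) {
  trajectory(cumsum(c(0, steps)), rep(0, length(steps) + 1), dt_s = dt, ...)
}

# seeded planar random walk with immobile, jitter and real steps
rw_traj <- function(n_steps = 500, seed = 1, dt = 1 / 30, scale = 1) {
  withr::with_seed(seed, {
    kind <- sample(c("still", "jitter", "move"), n_steps, replace = TRUE,
                   prob = c(0.3, 0.2, 0.5))
    len <- numeric(n_steps)
    len[kind == "jitter"] <- runif(sum(kind == "jitter"), 0, 0.3)
    len[kind == "move"] <- runif(sum(kind == "move"), 0.31, 2)
    len <- len * scale
    th <- runif(n_steps, -pi, pi)
    trajectory(cumsum(c(0, len * cos(th))), cumsum(c(0, len * sin(th))),
               dt_s = dt)
  })
}

# naive loop implementation of the five statistics (+ bout/stop counts)
oracle_summary <- function(traj, eps) {
  x <- traj$x_cm; y <- traj$y_cm
  dt <- attr(traj, "dt_s")
  n <- length(x) - 1
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  moving <- d > eps
  dist <- 0; n_mov <- 0
  for (i in seq_len(n)) if (moving[i]) { dist <- dist + d[i]; n_mov <- n_mov + 1 }
  # stops: immobile runs flanked by movement on both sides
  stops <- 0L; bouts <- 0L
  seen_move <- FALSE; gap_open <- FALSE
  for (i in seq_len(n)) {
    if (moving[i]) {
      if (!seen_move || gap_open) bouts <- bouts + 1L
      if (seen_move && gap_open) stops <- stops + 1L
      seen_move <- TRUE; gap_open <- FALSE
    } else if (seen_move) {
      gap_open <- TRUE
    }
  }
  # acceleration: positive velocity increments across moving pairs
  acc_sum <- 0; acc_n <- 0; pairs <- 0
  for (i in seq_len(n - 1)) {
    if (moving[i] && moving[i + 1]) {
      pairs <- pairs + 1
      dv <- (d[i + 1] - d[i]) / dt
      if (dv > 1e-9) { acc_sum <- acc_sum + dv; acc_n <- acc_n + 1 }
    }
  }
  list(
    distance = dist,
    eff_vel = if (n_mov > 0) dist / (n_mov * dt) else NA_real_,
    mean_acc = if (pairs == 0) NA_real_
               else if (acc_n == 0) 0 else (acc_sum / acc_n) / dt,
    stops = stops, bouts = bouts, moving_steps = n_mov,
    dist_per_stop = if (stops > 0) dist / stops else NA_real_)
}

# exhaustive-enumeration Mann-Whitney oracle (tie-free two-tailed p)
mw_enum_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_obs <- min(u_a, n_a * n_b - u_a)
  subsets <- utils::combn(n_a + n_b, n_a)
  us <- apply(subsets, 2, function(s) sum(seq_len(n_a + n_b)[s]) -
                n_a * (n_a + 1) / 2)
  min(1, 2 * mean(us <= u_obs))
}

# brute-force zone containment (declaration order, half-open rectangles)
brute_zone <- function(x, y, arena) {
  z <- arena$zones
  out <- rep(NA_character_, length(x))
  for (p in seq_along(x)) {
    for (k in seq_len(nrow(z))) {
      if (x[p] >= z$x0[k] && x[p] < z$x1[k] &&
          y[p] >= z$y0[k] && y[p] < z$y1[k]) {
        out[p] <- z$zone_id[k]
        break
      }
    }
  }
  out
}

# a large wall-free bench arena for kinematic fixtures
bench_arena <- function(side = 1000) {
  arena_spec("bench", c(side, side),
             data.frame(zone_id = "all", x0 = 0, y0 = 0, x1 = side,
                        y1 = side, role = "other"))
}
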