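#' Calibrated animal trajectory
#'
#' A trajectory is the per-frame centroid path of one animal in arena
#' coordinates (cm, image convention: origin at the arena's top-left corner,
#' x rightward, y downward), sampled at a constant frame interval. It is the
#' exchange format between the tracking, kinematics and arena modules.
#'
#' @param x_cm,y_cm numeric vectors of centroid coordinates (cm), equal
#'   length, at least 2 frames, finite.
#' @param dt_s frame interval in seconds (> 0). Exactly one of `dt_s` /
#'   `t_s` must be given.
#' @param t_s per-frame timestamps (seconds); must be strictly increasing
#'   with a constant step (tolerance 1e-6 s).
#' @param subject_id,group_label,test_stage provenance strings carried into
#'   summaries and reports.
#'
#' @return An object of class `ek_trajectory`: a data.frame with columns
#'   `frame` (0-based), `t_s`, `x_cm`, `y_cm`, and attributes `dt_s`,
#'   `subject_id`, `group_label`, `test_stage`.
#' @examples
#' tr <- trajectory(x_cm = c(0, 1, 2), y_cm = c(0, 0, 0), dt_s = 1 / 30)
#' nrow(tr)
#' @export
trajectory <- function(x_cm, y_cm, dt_s = NULL, t_s = NULL,
                       subject_id = "subject", group_label = "",
                       test_stage = "") {
  x_cm <- as.numeric(x_cm); y_cm <- as.numeric(y_cm)
  n <- length(x_cm)
  if (n != length(y_cm)) ek_stop("x_cm and y_cm differ in length", "ek_invalid_input")
  if (n < 2L) ek_stop("a trajectory needs at least 2 frames", "ek_invalid_input")
  if (!all(is.finite(x_cm)) || !all(is.finite(y_cm))) {
    ek_stop("trajectory coordinates must be finite", "ek_invalid_input")
  }
  if (is.null(t_s)) {
    if (is.null(dt_s)) ek_stop("supply dt_s or t_s", "ek_invalid_input")
    assert_scalar_num(dt_s, "dt_s", lower = 0, strict_lower = TRUE)
    t_s <- (seq_len(n) - 1) * dt_s
  } else {
    if (length(t_s) != n) ek_stop("t_s length mismatch", "ek_invalid_input")
    steps <- diff(t_s)
    if (any(steps <= 0) || max(steps) - min(steps) > 1e-6) {
      ek_stop("timestamps must be strictly increasing with constant step",
              "ek_invalid_input")
    }
    dt_s <- if (is.null(dt_s)) mean(steps) else dt_s
  }
  out <- data.frame(frame = seq_len(n) - 1L, t_s = t_s,
                    x_cm = x_cm, y_cm = y_cm)
  structure(out,
            dt_s = dt_s,
            subject_id = as.character(subject_id),
            group_label = as.character(group_label),
            test_stage = as.character(test_stage),
            class = c("ek_trajectory", "data.frame"))
}

#' @export
print.ek_trajectory <- function(x, ...) {
  cat(sprintf("<ek_trajectory> %s  %d frames, dt = %.5g s (%.1f s)\n",
              attr(x, "subject_id"), nrow(x), attr(x, "dt_s"),
              nrow(x) * attr(x, "dt_s")))
  cat(sprintf("  group = '%s'  stage = '%s'\n",
              attr(x, "group_label"), attr(x, "test_stage")))
  invisible(x)
}

traj_dt <- function(traj) attr(traj, "dt_s")

#' Write / read a trajectory CSV
#'
#' On-disk format: CSV with header `frame,t_s,x_cm,y_cm` (frame 0-based).
#' Provenance attributes travel as `#key: value` comment lines above the
#' header and are restored on read.
#'
#' @param traj an [trajectory()] object.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns an `ek_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("subject_id", "group_label", "test_stage")) {
    writeLines(sprintf("#%s: %s", key, attr(traj, key)), con)
  }
  writeLines(sprintf("#dt_s: %.12g", attr(traj, "dt_s")), con)
  utils::write.table(as.data.frame(traj), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(subject_id = "subject", group_label = "", test_stage = "",
               dt_s = NA_real_)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#([a-z_]+): ?(.*)$", h))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("frame", "t_s", "x_cm", "y_cm")
  if (!all(need %in% names(df))) {
    ek_stop(sprintf("trajectory CSV must have columns %s",
                    paste(need, collapse = ",")), "ek_invalid_input")
  }
  trajectory(df$x_cm, df$y_cm, t_s = df$t_s,
             subject_id = meta$subject_id, group_label = meta$group_label,
             test_stage = meta$test_stage)
}

# Subset a trajectory by frame indices (1-based, contiguous or not); keeps
# provenance. Used by minute binning; timestamps are preserved, so a
# non-contiguous subset is rejected (spacing would no longer be uniform).
traj_subset <- function(traj, idx) {
  trajectory(traj$x_cm[idx], traj$y_cm[idx], t_s = traj$t_s[idx],
             subject_id = attr(traj, "subject_id"),
             group_label = attr(traj, "group_label"),
             test_stage = attr(traj, "test_stage"))
}
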