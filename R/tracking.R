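#' Grayscale frame stack
#'
#' An ordered sequence of 2-D grayscale intensity grids (integers 0-255),
#' all of identical size, with a per-frame sampling interval. Frames are
#' stored as R matrices; pixel coordinates are 0-based, x along columns,
#' y along rows (image convention).
#'
#' The frame interval is required because every downstream velocity and
#' acceleration unit depends on it; when omitted, 1/30 s is assumed *with a
#' warning* (consumer webcams typically record near 30 frames/s but do not
#' guarantee it).
#'
#' @param frames list of integer matrices (0-255).
#' @param frame_interval_s seconds per frame (> 0); defaults to 1/30 with a
#'   warning.
#' @param source_id free-text provenance.
#' @return `ek_framestack` object.
#' @export
frame_stack <- function(frames, frame_interval_s = NULL,
                        source_id = "unknown") {
  if (!is.list(frames) || length(frames) < 1L) {
    ek_stop("frames must be a non-empty list of matrices", "ek_invalid_input")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ek_stop("all frames must share identical height x width", "ek_invalid_input")
  }
  if (any(dims == 0L)) ek_stop("frames must be non-empty", "ek_invalid_input")
  if (is.null(frame_interval_s)) {
    warning("frame_interval_s not supplied; defaulting to 1/30 s")
    frame_interval_s <- 1 / 30
  }
  assert_scalar_num(frame_interval_s, "frame_interval_s", lower = 0,
                    strict_lower = TRUE)
  structure(list(frames = frames, frame_interval_s = frame_interval_s,
                 source_id = source_id),
            class = "ek_framestack")
}

#' @export
print.ek_framestack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<ek_framestack> %d frames of %d x %d px, dt = %.5g s (%s)\n",
              length(x$frames), d[1], d[2], x$frame_interval_s, x$source_id))
  invisible(x)
}

# label 4-connected components among linear pixel indices `idx` of an
# nr x nc grid; returns integer component labels (1..k) per element of idx,
# labels ordered by each component's smallest linear pixel index
label_components <- function(idx, nr, nc) {
  m <- length(idx)
  if (m == 0L) return(integer(0))
  rank_of <- integer(nr * nc)
  rank_of[idx] <- seq_len(m)
  parent <- seq_len(m)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <- root; i <- nxt }
    parent <<- parent
    root
  }
  row <- (idx - 1L) %% nr + 1L
  up_ok <- row > 1L & rank_of[pmax(idx - 1L, 1L)] > 0L
  left_ok <- idx > nr & rank_of[pmax(idx - nr, 1L)] > 0L
  link <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (j in which(up_ok)) link(j, rank_of[idx[j] - 1L])
  for (j in which(left_ok)) link(j, rank_of[idx[j] - nr])
  roots <- vapply(seq_len(m), find, integer(1))
  # stable labels: by smallest pixel index in component = smallest rank root
  labels <- match(roots, sort(unique(roots)))
  labels
}

#' Extract the animal centroid from one frame
#'
#' Emulates the threshold / analyze-particles chain: pixels strictly darker
#' than `intensity_threshold` are foreground (a dark animal on a light
#' arena; set `invert = TRUE` for the opposite polarity), 4-connected
#' components smaller than `min_area_px` are dropped, and the centroid of
#' the largest surviving component is returned (ties on area broken by the
#' component containing the smallest pixel index — deterministic where the
#' original workflow used manual review). `weighted = TRUE` returns the
#' darkness-weighted center of mass (weights `255 - intensity`) instead of
#' the plain blob centroid.
#'
#' @param frame integer matrix (0-255).
#' @param intensity_threshold threshold in [0, 255].
#' @param min_area_px minimum component area (>= 1).
#' @param invert animal lighter than background.
#' @param weighted intensity-weighted centroid.
#' @return numeric `c(x_px, y_px)` (0-based pixel coordinates), or `NULL`
#'   (MISSING) when no component survives.
#' @examples
#' fr <- matrix(255L, 10, 10); fr[3:5, 4:6] <- 0L
#' extract_centroid(fr, 100)  # c(4, 3): 0-based centroid of the square
#' @export
extract_centroid <- function(frame, intensity_threshold, min_area_px = 1,
                             invert = FALSE, weighted = FALSE) {
  if (!is.matrix(frame) || length(frame) == 0L) {
    ek_stop("frame must be a non-empty matrix", "ek_invalid_input")
  }
  assert_scalar_num(intensity_threshold, "intensity_threshold",
                    lower = 0, upper = 255)
  if (min_area_px < 1) ek_stop("min_area_px must be >= 1", "ek_invalid_input")
  nr <- nrow(frame); nc <- ncol(frame)
  idx <- if (invert) which(frame > intensity_threshold) else
    which(frame < intensity_threshold)
  if (length(idx) == 0L) return(NULL)
  labels <- label_components(idx, nr, nc)
  areas <- tabulate(labels)
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0L) return(NULL)
  best <- keep[which.max(areas[keep])]  # which.max -> smallest label on tie
  sel <- idx[labels == best]
  col0 <- (sel - 1L) %/% nr     # 0-based x
  row0 <- (sel - 1L) %% nr      # 0-based y
  if (weighted) {
    w <- if (invert) as.numeric(frame[sel]) else 255 - as.numeric(frame[sel])
    if (sum(w) <= 0) w <- rep(1, length(sel))
    c(sum(col0 * w) / sum(w), sum(row0 * w) / sum(w))
  } else {
    c(mean(col0), mean(row0))
  }
}

#' Per-frame raw pixel track
#'
#' @param x_px,y_px numeric vectors (NA = MISSING), 0-based pixel
#'   coordinates.
#' @param frame_interval_s seconds per frame.
#' @param source_id provenance.
#' @return `ek_rawtrack`: data.frame `frame` (0-based), `x_px`, `y_px` with
#'   attributes `frame_interval_s`, `source_id`.
#' @export
raw_track <- function(x_px, y_px, frame_interval_s, source_id = "unknown") {
  if (length(x_px) != length(y_px)) {
    ek_stop("x_px and y_px differ in length", "ek_invalid_input")
  }
  if (any(is.na(x_px) != is.na(y_px))) {
    ek_stop("x and y must be MISSING together", "ek_invalid_input")
  }
  assert_scalar_num(frame_interval_s, "frame_interval_s", lower = 0,
                    strict_lower = TRUE)
  structure(data.frame(frame = seq_along(x_px) - 1L,
                       x_px = as.numeric(x_px), y_px = as.numeric(y_px)),
            frame_interval_s = frame_interval_s, source_id = source_id,
            class = c("ek_rawtrack", "data.frame"))
}

#' Track a whole frame stack
#'
#' Applies [extract_centroid()] to every frame in order. MISSING frames are
#' preserved as `NA`, never interpolated here — gap filling is the separate,
#' explicit [fill_missing()] step.
#'
#' @param stack an [frame_stack()].
#' @param intensity_threshold,min_area_px,invert,weighted see
#'   [extract_centroid()].
#' @return `ek_rawtrack` with one row per frame.
#' @export
track_stack <- function(stack, intensity_threshold, min_area_px = 1,
                        invert = FALSE, weighted = FALSE) {
  if (!inherits(stack, "ek_framestack")) {
    ek_stop("stack must be an ek_framestack", "ek_invalid_input")
  }
  pts <- lapply(stack$frames, extract_centroid,
                intensity_threshold = intensity_threshold,
                min_area_px = min_area_px, invert = invert,
                weighted = weighted)
  x <- vapply(pts, function(p) if (is.null(p)) NA_real_ else p[1], numeric(1))
  y <- vapply(pts, function(p) if (is.null(p)) NA_real_ else p[2], numeric(1))
  raw_track(x, y, stack$frame_interval_s, stack$source_id)
}

#' Fill short tracking gaps by linear interpolation
#'
#' Interior runs of MISSING frames of length at most `max_gap` are linearly
#' interpolated between the flanking points; longer runs and leading or
#' trailing gaps are left MISSING. This replaces the manual frame-by-frame
#' correction of the original workflow with a reproducible rule.
#'
#' @param track an `ek_rawtrack`.
#' @param max_gap longest gap (frames) to interpolate (default 5).
#' @return `ek_rawtrack` with attribute `filled_frames`: 0-based indices of
#'   corrected frames.
#' @export
fill_missing <- function(track, max_gap = 5) {
  x <- track$x_px; y <- track$y_px
  miss <- is.na(x)
  filled <- integer(0)
  runs <- true_runs(miss)
  for (r in seq_len(nrow(runs))) {
    s <- runs$start[r]; e <- runs$end[r]
    if (s == 1L || e == length(x)) next          # leading/trailing
    if (e - s + 1L > max_gap) next
    k <- (s:e) - (s - 1L)
    span <- e - s + 2L
    x[s:e] <- x[s - 1L] + (x[e + 1L] - x[s - 1L]) * k / span
    y[s:e] <- y[s - 1L] + (y[e + 1L] - y[s - 1L]) * k / span
    filled <- c(filled, (s:e) - 1L)
  }
  out <- raw_track(x, y, attr(track, "frame_interval_s"),
                   attr(track, "source_id"))
  attr(out, "filled_frames") <- filled
  out
}

#' Pixel-to-arena calibration
#'
#' @param px_per_cm_x,px_per_cm_y positive scale factors (pixels per cm);
#'   `px_per_cm_y` defaults to the x scale.
#' @param origin_px pixel coordinates mapped to arena (0, 0).
#' @return `ek_calibration` list.
#' @export
calibration <- function(px_per_cm_x, px_per_cm_y = px_per_cm_x,
                        origin_px = c(0, 0)) {
  assert_scalar_num(px_per_cm_x, "px_per_cm_x", lower = 0, strict_lower = TRUE)
  assert_scalar_num(px_per_cm_y, "px_per_cm_y", lower = 0, strict_lower = TRUE)
  structure(list(px_per_cm_x = px_per_cm_x, px_per_cm_y = px_per_cm_y,
                 origin_px = as.numeric(origin_px)),
            class = "ek_calibration")
}

#' Calibrate a raw pixel track to arena coordinates
#'
#' `x_cm = (x_px - origin_x) / px_per_cm_x`, likewise for y; the frame
#' interval is propagated. Any remaining MISSING frame is an error (run
#' [fill_missing()] first, or drop the subject): the condition carries the
#' 0-based offending frame indices.
#'
#' @param track an `ek_rawtrack`.
#' @param cal a [calibration()].
#' @param subject_id,group_label,test_stage provenance for the trajectory.
#' @return an [trajectory()].
#' @export
calibrate_track <- function(track, cal, subject_id = "subject",
                            group_label = "", test_stage = "") {
  miss <- which(is.na(track$x_px))
  if (length(miss) > 0L) {
    ek_stop(sprintf("track still has %d MISSING frame(s): %s%s",
                    length(miss),
                    paste(utils::head(miss - 1L, 10), collapse = ","),
                    if (length(miss) > 10) ", ..." else ""),
            "ek_incomplete_track", data = list(frames = miss - 1L))
  }
  if (nrow(track) < 2L) {
    ek_stop("need >= 2 tracked frames to calibrate", "ek_invalid_input")
  }
  trajectory((track$x_px - cal$origin_px[1]) / cal$px_per_cm_x,
             (track$y_px - cal$origin_px[2]) / cal$px_per_cm_y,
             dt_s = attr(track, "frame_interval_s"),
             subject_id = subject_id, group_label = group_label,
             test_stage = test_stage)
}

#' Raw track CSV I/O
#'
#' Format: header `frame,x_px,y_px`, MISSING serialized as empty fields;
#' the frame interval travels as a `#frame_interval_s:` comment line.
#'
#' @param track an `ek_rawtrack`.
#' @param path file path.
#' @return `write_raw_track()` the path, invisibly; `read_raw_track()` an
#'   `ek_rawtrack`.
#' @export
write_raw_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#frame_interval_s: %.12g",
                     attr(track, "frame_interval_s")), con)
  utils::write.table(as.data.frame(track), con, sep = ",",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_raw_track
#' @param frame_interval_s override for files lacking the comment header.
#' @export
read_raw_track <- function(path, frame_interval_s = NULL) {
  lines <- readLines(path)
  m <- regmatches(lines, regexec("^#frame_interval_s: ?([0-9.eE+-]+)", lines))
  dt <- frame_interval_s
  for (mm in m) if (length(mm) == 2L) dt <- as.numeric(mm[2])
  if (is.null(dt)) {
    warning("frame_interval_s not in file; defaulting to 1/30 s")
    dt <- 1 / 30
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  raw_track(df$x_px, df$y_px, dt, source_id = path)
}

#' ASCII PGM (P2) frame-stack I/O
#'
#' Plain-text portable graymap, one file per frame, lexicographic order.
#' This is the package's on-disk frame format (binary image containers are
#' out of scope; frame extraction from video is upstream).
#'
#' @param stack an [frame_stack()].
#' @param dir output directory (created if needed).
#' @return `write_pgm_stack()` the directory; `read_pgm_stack()` an
#'   `ek_framestack`.
#' @export
write_pgm_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    fr <- stack$frames[[i]]
    path <- file.path(dir, sprintf("frame_%05d.pgm", i - 1L))
    con <- file(path, "w")
    writeLines(c("P2", sprintf("%d %d", ncol(fr), nrow(fr)), "255"), con)
    # row-major pixel dump
    writeLines(apply(fr, 1, paste, collapse = " "), con)
    close(con)
  }
  invisible(dir)
}

#' @rdname write_pgm_stack
#' @param frame_interval_s seconds per frame for the stack read back.
#' @export
read_pgm_stack <- function(dir, frame_interval_s = NULL) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) ek_stop("no .pgm files found", "ek_invalid_input")
  frames <- lapply(files, function(p) {
    toks <- scan(p, what = character(), quiet = TRUE, comment.char = "#")
    if (toks[1] != "P2") ek_stop("only ASCII P2 PGM supported", "ek_invalid_input")
    w <- as.integer(toks[2]); h <- as.integer(toks[3])
    px <- as.integer(toks[-(1:4)])
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  })
  frame_stack(frames, frame_interval_s = frame_interval_s,
              source_id = dir)
}
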