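# Synthetic articulated-skeleton sequences with ground truth. The
# simulator emulates the statistical regime the pipeline assumes from an
# upstream pose estimator: anatomically plausible COCO-17 layouts for
# standing / lying / crouching, rigid tipping for falls (fast and
# gradual), walking with limb swing as a daily-living negative, isotropic
# Gaussian keypoint jitter, and random keypoint dropout. Ground-truth
# posture labels switch from standing to lying where the noiseless torso
# inclination crosses 45 degrees (midpoint of the 0-90 range).

# sagittal template geometry, unit height, y negative = up (image coords);
# lateral x offset `d` separates the left (-d) and right (+d) sides
.template_coords <- function(posture, d = 0.04) {
  base <- switch(posture,
    standing = list(
      nose = c(0, -0.94), eye = c(0.02, -0.96), ear = c(0.045, -0.95),
      shoulder = c(0.11, -0.82), elbow = c(0.14, -0.62),
      wrist = c(0.15, -0.44), hip = c(0.07, -0.50),
      knee = c(0.07, -0.25), ankle = c(0.07, 0)),
    crouch = list(
      nose = c(0.20, -0.80), eye = c(0.21, -0.82), ear = c(0.19, -0.81),
      shoulder = c(0.08, -0.70), elbow = c(0.15, -0.55),
      wrist = c(0.25, -0.45), hip = c(0.00, -0.38),
      knee = c(0.27, -0.25), ankle = c(0.05, 0)),
    stop("unknown posture template: ", posture, call. = FALSE))
  # left/right expansion: paired joints get the lateral offset, the head
  # midline points sit symmetric about x = 0
  sym <- function(p, lateral) rbind(left = c(p[1] - lateral, p[2]),
                                    right = c(p[1] + lateral, p[2]))
  out <- matrix(NA_real_, nrow = 17, ncol = 2,
                dimnames = list(coco_keypoint_names(), c("x", "y")))
  out["nose", ] <- base$nose
  if (posture == "standing") {
    out[c("left_eye", "right_eye"), ] <- rbind(
      c(-base$eye[1], base$eye[2]), base$eye)
    out[c("left_ear", "right_ear"), ] <- rbind(
      c(-base$ear[1], base$ear[2]), base$ear)
    for (joint in c("shoulder", "elbow", "wrist", "hip", "knee", "ankle")) {
      p <- base[[joint]]
      out[paste0(c("left_", "right_"), joint), ] <-
        rbind(c(-p[1], p[2]), p)
    }
  } else {
    out[c("left_eye", "right_eye"), ] <- sym(base$eye, d / 2)
    out[c("left_ear", "right_ear"), ] <- sym(base$ear, d / 2)
    for (joint in c("shoulder", "elbow", "wrist", "hip", "knee", "ankle"))
      out[paste0(c("left_", "right_"), joint), ] <- sym(base[[joint]], d)
  }
  out
}

#' Generate a template pose frame
#'
#' Anatomically plausible 17-keypoint layouts anchored at the ankle
#' midpoint. `"standing"` has torso, nose-to-ankle and knee angles all
#' under 5 degrees; `"lying"` is the standing layout rigidly rotated 90
#' degrees about the anchor (torso and nose-to-ankle > 85 degrees);
#' `"crouch"` bends the knees past 70 degrees with a forward-leaning torso
#' in the 20-50 degree band. All confidences are 1.
#'
#' @param posture `"standing"`, `"lying"` or `"crouch"`.
#' @param height_px Body height in pixels (> 0).
#' @param anchor Ankle-midpoint position `c(x, y)` in image coordinates.
#' @param track_id,frame_index Passed through to [pose_frame()].
#' @return A [pose_frame()].
#' @export
#' @examples
#' extract_features(make_pose_template("standing"))["torso"]
#' extract_features(make_pose_template("lying"))["torso"]
make_pose_template <- function(posture = c("standing", "lying", "crouch"),
                               height_px = 170, anchor = c(320, 400),
                               track_id = "sim", frame_index = 0L) {
  posture <- match.arg(posture)
  if (height_px <= 0) stop("height_px must be > 0", call. = FALSE)
  xy <- if (posture == "lying") {
    s <- .template_coords("standing")
    cbind(x = -s[, "y"], y = s[, "x"])   # clockwise 90-degree tip
  } else .template_coords(posture)
  kp <- cbind(x = xy[, 1] * height_px + anchor[1],
              y = xy[, 2] * height_px + anchor[2],
              confidence = 1)
  pose_frame(track_id, frame_index, kp)
}

#' Scenario specification for the simulator
#'
#' @param kind One of `"standing"`, `"walking"`, `"lying"`, `"fall_fast"`,
#'   `"fall_gradual"`, `"crouch_confounder"`.
#' @param duration_frames Sequence length in frames (default 12 s at `fps`).
#' @param fps Frames per second (default 30).
#' @param transition_start First frame of the posture transition, for
#'   transition kinds (default 30% into the sequence).
#' @param transition_len_frames Transition duration. Defaults by kind: a
#'   fast fall takes 0.5 s, a gradual fall 3.5 s, a crouch descent 1 s.
#' @param height_px Body height in pixels.
#' @param jitter_sd Per-coordinate Gaussian noise SD in pixels (default 2).
#' @param dropout_prob Per-keypoint probability of being dropped
#'   (confidence set to 0) in any frame (default 0.02).
#' @param rng_seed Seed making the sequence fully deterministic.
#' @param track_id Track id for the generated person.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("standing", "walking", "lying",
                                   "fall_fast", "fall_gradual",
                                   "crouch_confounder"),
                          duration_frames = NULL, fps = 30,
                          transition_start = NULL,
                          transition_len_frames = NULL,
                          height_px = 170, jitter_sd = 2,
                          dropout_prob = 0.02, rng_seed = 1L,
                          track_id = "p1") {
  kind <- match.arg(kind)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (is.null(duration_frames)) duration_frames <- round(12 * fps)
  duration_frames <- as.integer(duration_frames)
  if (duration_frames < 1L) stop("duration_frames must be >= 1", call. = FALSE)
  if (is.null(transition_start)) transition_start <- round(0.3 * duration_frames)
  if (is.null(transition_len_frames))
    transition_len_frames <- switch(kind,
      fall_fast = max(1L, round(0.5 * fps)),
      fall_gradual = max(1L, round(3.5 * fps)),
      crouch_confounder = max(1L, round(1 * fps)),
      1L)
  transition_start <- as.integer(transition_start)
  transition_len_frames <- as.integer(transition_len_frames)
  if (kind %in% c("fall_fast", "fall_gradual", "crouch_confounder")) {
    need <- if (kind == "crouch_confounder")
      transition_start + 2L * transition_len_frames + round(2 * fps)
    else transition_start + transition_len_frames
    if (need > duration_frames)
      stop("transition does not fit: needs ", need, " frames, have ",
           duration_frames, call. = FALSE)
  }
  if (jitter_sd < 0 || dropout_prob < 0 || dropout_prob >= 1)
    stop("jitter_sd must be >= 0 and dropout_prob in [0, 1)", call. = FALSE)
  structure(list(kind = kind, duration_frames = duration_frames, fps = fps,
                 transition_start = transition_start,
                 transition_len_frames = transition_len_frames,
                 height_px = height_px, jitter_sd = jitter_sd,
                 dropout_prob = dropout_prob,
                 rng_seed = as.integer(rng_seed),
                 track_id = as.character(track_id)),
            class = "scenario_spec")
}

# rigid rotation of keypoint coordinates about a pivot (degrees, clockwise
# in image coordinates = standing body tipping toward +x)
.rotate_xy <- function(xy, pivot, theta_deg) {
  th <- theta_deg * pi / 180
  rel <- sweep(xy, 2, pivot)
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  out <- sweep(rel %*% rot, 2, pivot, `+`)
  dimnames(out) <- dimnames(xy)
  out
}

#' Generate a labeled synthetic sequence
#'
#' Produces one person track of `duration_frames` frames. Falls are rigid
#' rotations of the standing template about the ankle midpoint from 0 to
#' 90 degrees across the transition window; the crouch confounder blends
#' standing into the crouch template, holds it for 2 s and comes back up;
#' walking adds sinusoidal leg swing and lateral drift. Jitter and dropout
#' are applied after the ground-truth label (torso inclination >= 45
#' degrees means lying) has been recorded, so labels are exact.
#'
#' @param spec A [scenario_spec()].
#' @return A `labeled_sequence`: list with `stream` ([track_stream()]),
#'   `frame_labels` (integer, aligned with `stream$frames`), `is_fall`,
#'   `fall_frame` (ground-truth lying onset, or `NA`), and `kind`.
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$rng_seed)
  n <- spec$duration_frames
  h <- spec$height_px
  anchor <- c(320, 400)
  standing <- .template_coords("standing") * h
  standing <- sweep(standing, 2, anchor, `+`)
  crouch <- .template_coords("crouch") * h
  crouch <- sweep(crouch, 2, anchor, `+`)
  ts <- spec$transition_start
  len <- spec$transition_len_frames
  hold <- round(2 * spec$fps)

  frames <- vector("list", n)
  labels <- integer(n)
  fall_frame <- NA_integer_
  for (i in seq_len(n)) {
    t0 <- i - 1L                       # frame index, 0-based
    xy <- standing
    theta <- 0                         # ground-truth torso inclination
    if (spec$kind == "lying") {
      xy <- .rotate_xy(standing, anchor, 90); theta <- 90
    } else if (spec$kind %in% c("fall_fast", "fall_gradual")) {
      prog <- if (t0 < ts) 0 else min(1, (t0 - ts + 1) / len)
      theta <- 90 * prog
      xy <- .rotate_xy(standing, anchor, theta)
    } else if (spec$kind == "crouch_confounder") {
      blend <-
        if (t0 < ts) 0
        else if (t0 < ts + len) (t0 - ts + 1) / len
        else if (t0 < ts + len + hold) 1
        else if (t0 < ts + 2L * len + hold) 1 - (t0 - ts - len - hold + 1) / len
        else 0
      xy <- (1 - blend) * standing + blend * crouch
      # noiseless torso inclination of the blended skeleton
      mh <- (xy["left_hip", ] + xy["right_hip", ]) / 2
      v <- mh - xy["nose", ]
      theta <- acos(v[2] / sqrt(sum(v^2))) * 180 / pi
    } else if (spec$kind == "walking") {
      phase <- 2 * pi * 1.5 * t0 / spec$fps
      swing <- 0.08 * h * sin(phase)
      xy[c("left_knee", "left_ankle"), "x"] <-
        xy[c("left_knee", "left_ankle"), "x"] + swing
      xy[c("right_knee", "right_ankle"), "x"] <-
        xy[c("right_knee", "right_ankle"), "x"] - swing
      xy[, "x"] <- xy[, "x"] + 0.3 * h * t0 / spec$fps   # lateral drift
    }
    lab <- if (theta >= 45) 0L else 1L
    if (lab == 0L && is.na(fall_frame) &&
        spec$kind %in% c("fall_fast", "fall_gradual"))
      fall_frame <- t0
    labels[i] <- lab

    kp <- cbind(x = xy[, "x"] + stats::rnorm(17, 0, spec$jitter_sd),
                y = xy[, "y"] + stats::rnorm(17, 0, spec$jitter_sd),
                confidence = stats::runif(17, 0.8, 1))
    if (spec$dropout_prob > 0) {
      drop <- stats::runif(17) < spec$dropout_prob
      kp[drop, "confidence"] <- 0
    }
    frames[[i]] <- pose_frame(spec$track_id, t0, kp,
                              timestamp_s = t0 / spec$fps)
  }
  structure(list(stream = track_stream(frames, fps = spec$fps),
                 frame_labels = labels,
                 is_fall = spec$kind %in% c("fall_fast", "fall_gradual"),
                 fall_frame = fall_frame,
                 kind = spec$kind),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat(sprintf("<labeled_sequence> %s, %d frames, is_fall=%s%s\n",
              x$kind, length(x$stream$frames), x$is_fall,
              if (!is.na(x$fall_frame))
                sprintf(", lying onset frame %d", x$fall_frame) else ""))
  invisible(x)
}

#' Generate a labeled training table
#'
#' Builds a balanced frame-level training set: `n_per_class` standing and
#' `n_per_class` lying frames with per-frame random body height (120-220
#' px), random image placement, and Gaussian keypoint jitter; features are
#' extracted with [extract_features()] and labels attached (1 standing,
#' 0 lying). By construction the two classes sit ~90 degrees apart in
#' torso angle, well clear of any boundary at moderate jitter. No dropout
#' is applied: training rows are complete.
#'
#' @param n_per_class Frames per class (>= 1).
#' @param jitter_sd Keypoint jitter SD in pixels (default 3).
#' @param seed RNG seed.
#' @return Labeled feature table (`data.frame`) of `2 * n_per_class` rows.
#' @export
generate_training_table <- function(n_per_class, jitter_sd = 3, seed = 1L) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  rows <- vector("list", 2L * n_per_class)
  k <- 0L
  for (posture in c("standing", "lying")) {
    lab <- if (posture == "standing") 1L else 0L
    for (i in seq_len(n_per_class)) {
      h <- stats::runif(1, 120, 220)
      anchor <- c(stats::runif(1, 100, 540), stats::runif(1, 200, 460))
      pf <- make_pose_template(posture, height_px = h, anchor = anchor,
                               frame_index = k)
      kp <- pf$keypoints
      kp[, c("x", "y")] <- kp[, c("x", "y")] +
        matrix(stats::rnorm(34, 0, jitter_sd), ncol = 2)
      pf <- pose_frame(pf$track_id, pf$frame_index, kp)
      k <- k + 1L
      rows[[k]] <- c(extract_features(pf), label = lab)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab$label <- as.integer(tab$label)
  cbind(data.frame(track_id = "sim", frame_index = seq_len(nrow(tab)) - 1L,
                   stringsAsFactors = FALSE), tab)
}

#' Generate a scenario suite on disk
#'
#' Writes `n` independently seeded sequences of one kind as numbered JSONL
#' keypoint streams plus a `manifest.csv` (sequence id, kind, is_fall,
#' fall_frame) into `dir`.
#'
#' @param kind Scenario kind (see [scenario_spec()]).
#' @param n Number of sequences.
#' @param seed Base seed; sequence i uses `seed + i`.
#' @param dir Output directory (created if needed).
#' @param ... Further arguments to [scenario_spec()].
#' @return The manifest data frame, invisibly.
#' @export
simulate_suite <- function(kind, n, seed = 1L, dir = ".", ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(sequence_id = character(0), kind = character(0),
                         is_fall = logical(0), fall_frame = integer(0),
                         path = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sid <- sprintf("%s_%03d", kind, i)
    sp <- scenario_spec(kind, rng_seed = seed + i, track_id = sid, ...)
    seqn <- generate_sequence(sp)
    path <- file.path(dir, paste0(sid, ".jsonl"))
    write_keypoint_stream(seqn$stream, path)
    manifest <- rbind(manifest, data.frame(
      sequence_id = sid, kind = kind, is_fall = seqn$is_fall,
      fall_frame = seqn$fall_frame, path = path, stringsAsFactors = FALSE))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
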