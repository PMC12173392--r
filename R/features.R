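# The nine geometric pose features: normalized center of mass (x, y) plus
# seven angles derived from keypoint vectors. All angles are reported in
# degrees in [0, 180]; arccos arguments are clamped to [-1, 1] so that
# numerically collinear vectors never produce NaN. Features whose required
# keypoints are missing or degenerate come back as NA -- the preprocessing
# layer decides whether to drop or fill, the geometry layer never imputes.

#' Feature column names
#'
#' Names of the nine pose features, in canonical column order.
#' @return Character vector of length 9.
#' @export
feature_names <- function() {
  c("cm_x", "cm_y", "shoulder_nose", "torso", "hip", "shoulder",
    "left_leg", "right_leg", "nose_ankle")
}

# angle between two 2-D vectors, degrees, via clamped arccos
.vec_angle <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
}

# angle of vector v against the +y image axis (vertical reference)
.vertical_angle <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) return(NA_real_)
  acos(max(-1, min(1, v[2] / n))) * 180 / pi
}

# angle of vector v against the +x image axis (horizontal reference)
.horizontal_angle <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (n == 0) return(NA_real_)
  acos(max(-1, min(1, v[1] / n))) * 180 / pi
}

.kp <- function(frame, name) frame$keypoints[name, c("x", "y")]

#' Center of mass of a pose frame
#'
#' Unweighted mean of the coordinates of all *visible* keypoints (those at
#' or above the confidence threshold). A proxy for the body-mass centroid.
#'
#' @param frame A [pose_frame()].
#' @param visibility Minimum keypoint confidence to count as visible.
#' @return Numeric `c(x, y)`, or `c(NA, NA)` if no keypoint is visible.
#' @export
center_of_mass <- function(frame, visibility = 0.5) {
  vis <- .visible(frame, visibility)
  if (!any(vis)) return(c(x = NA_real_, y = NA_real_))
  c(x = mean(frame$keypoints[vis, "x"]), y = mean(frame$keypoints[vis, "y"]))
}

#' Shoulder-nose angle
#'
#' Angle at the nose between the vectors nose->left_shoulder and
#' nose->right_shoulder, in degrees. Wide for an upright subject viewed
#' frontally; collapses when the shoulder line is seen edge-on.
#'
#' @inheritParams center_of_mass
#' @return Degrees in \[0, 180\], or `NA` if a required keypoint is missing
#'   or a shoulder coincides with the nose.
#' @export
shoulder_nose_angle <- function(frame, visibility = 0.5) {
  vis <- .visible(frame, visibility)
  if (!all(vis[c("nose", "left_shoulder", "right_shoulder")])) return(NA_real_)
  b <- .kp(frame, "nose")
  .vec_angle(.kp(frame, "left_shoulder") - b, .kp(frame, "right_shoulder") - b)
}

#' Torso angle
#'
#' Inclination of the nose -> mid-hip axis from the image vertical, in
#' degrees: ~0 for an upright person (y grows downward), ~90 when lying.
#' The single most discriminative standing/lying feature.
#'
#' @inheritParams center_of_mass
#' @return Degrees in \[0, 180\] or `NA`.
#' @export
torso_angle <- function(frame, visibility = 0.5) {
  vis <- .visible(frame, visibility)
  if (!all(vis[c("nose", "left_hip", "right_hip")])) return(NA_real_)
  mh <- midpoint(.kp(frame, "left_hip"), .kp(frame, "right_hip"))
  .vertical_angle(mh - .kp(frame, "nose"))
}

#' Hip-line angle
#'
#' Angle of the left_hip -> right_hip vector against the image horizontal,
#' in degrees. Not folded: a flipped hip line reads > 90.
#'
#' @inheritParams center_of_mass
#' @return Degrees in \[0, 180\] or `NA`.
#' @export
hip_angle <- function(frame, visibility = 0.5) {
  vis <- .visible(frame, visibility)
  if (!all(vis[c("left_hip", "right_hip")])) return(NA_real_)
  .horizontal_angle(.kp(frame, "right_hip") - .kp(frame, "left_hip"))
}

#' Shoulder-line angle
#'
#' Angle of the left_shoulder -> right_shoulder vector against the image
#' horizontal, in degrees; mirrors [hip_angle()].
#'
#' @inheritParams center_of_mass
#' @return Degrees in \[0, 180\] or `NA`.
#' @export
shoulder_angle <- function(frame, visibility = 0.5) {
  vis <- .visible(frame, visibility)
  if (!all(vis[c("left_shoulder", "right_shoulder")])) return(NA_real_)
  .horizontal_angle(.kp(frame, "right_shoulder") - .kp(frame, "left_shoulder"))
}

#' Knee flexion angle
#'
#' Angle at the knee between the thigh direction (hip -> knee) and the shank
#' direction (knee -> ankle), in degrees: 0 for a perfectly straight leg,
#' growing as the knee bends.
#'
#' @inheritParams center_of_mass
#' @param side `"left"` or `"right"`.
#' @return Degrees in \[0, 180\] or `NA`.
#' @export
leg_angle <- function(frame, side = c("left", "right"), visibility = 0.5) {
  side <- match.arg(side)
  hip <- paste0(side, "_hip"); knee <- paste0(side, "_knee")
  ankle <- paste0(side, "_ankle")
  vis <- .visible(frame, visibility)
  if (!all(vis[c(hip, knee, ankle)])) return(NA_real_)
  .vec_angle(.kp(frame, knee) - .kp(frame, hip),
             .kp(frame, ankle) - .kp(frame, knee))
}

#' Nose-to-ankle angle
#'
#' Inclination of the nose -> mid-ankle axis from the image vertical, in
#' degrees: ~0 upright, ~90 horizontal. Captures whole-body orientation.
#'
#' @inheritParams center_of_mass
#' @return Degrees in \[0, 180\] or `NA`.
#' @export
nose_to_ankle_angle <- function(frame, visibility = 0.5) {
  vis <- .visible(frame, visibility)
  if (!all(vis[c("nose", "left_ankle", "right_ankle")])) return(NA_real_)
  ma <- midpoint(.kp(frame, "left_ankle"), .kp(frame, "right_ankle"))
  .vertical_angle(ma - .kp(frame, "nose"))
}

#' Extract the nine-feature vector from a pose frame
#'
#' Computes the full feature vector: bounding-box-normalized center of mass
#' (x, y) and the seven angles. Center-of-mass coordinates are normalized
#' to \[0, 1\] within `bbox` when given, else within the axis-aligned extent
#' of the visible keypoints, so that the feature set is invariant to where
#' and how large the person appears in the image. Features that cannot be
#' computed (missing keypoints, degenerate geometry, zero-extent box) are
#' `NA`; nothing is imputed here.
#'
#' @inheritParams center_of_mass
#' @param bbox Optional person bounding box `c(xmin, ymin, xmax, ymax)`.
#' @return Named numeric vector of length 9 (see [feature_names()]).
#' @export
#' @examples
#' pf <- make_pose_template("standing")
#' extract_features(pf)
extract_features <- function(frame, bbox = NULL, visibility = 0.5) {
  cm <- center_of_mass(frame, visibility)
  if (is.null(bbox)) {
    vis <- .visible(frame, visibility)
    bbox <- if (any(vis))
      c(min(frame$keypoints[vis, "x"]), min(frame$keypoints[vis, "y"]),
        max(frame$keypoints[vis, "x"]), max(frame$keypoints[vis, "y"]))
    else c(NA_real_, NA_real_, NA_real_, NA_real_)
  }
  w <- bbox[3] - bbox[1]; h <- bbox[4] - bbox[2]
  cm_x <- if (is.finite(w) && w > 0) (cm[["x"]] - bbox[1]) / w else NA_real_
  cm_y <- if (is.finite(h) && h > 0) (cm[["y"]] - bbox[2]) / h else NA_real_
  c(cm_x = cm_x, cm_y = cm_y,
    shoulder_nose = shoulder_nose_angle(frame, visibility),
    torso = torso_angle(frame, visibility),
    hip = hip_angle(frame, visibility),
    shoulder = shoulder_angle(frame, visibility),
    left_leg = leg_angle(frame, "left", visibility),
    right_leg = leg_angle(frame, "right", visibility),
    nose_ankle = nose_to_ankle_angle(frame, visibility))
}

#' Build a feature table from a track stream
#'
#' Runs [extract_features()] over every frame of a stream and assembles a
#' data frame with one row per frame-person: `track_id`, `frame_index`, the
#' nine feature columns, and optionally a `label` column.
#'
#' @param stream A [track_stream()].
#' @param labels Optional integer vector of posture labels (0 lying,
#'   1 standing) aligned with `stream$frames`.
#' @param visibility Minimum keypoint confidence to count as visible.
#' @return A `data.frame`; `NA` marks features that could not be computed.
#' @export
feature_table <- function(stream, labels = NULL, visibility = 0.5) {
  stopifnot(inherits(stream, "track_stream"))
  n <- length(stream$frames)
  if (!is.null(labels) && length(labels) != n)
    stop("labels must have one entry per frame", call. = FALSE)
  feats <- matrix(NA_real_, nrow = n, ncol = 9L,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_len(n))
    feats[i, ] <- extract_features(stream$frames[[i]], visibility = visibility)
  out <- data.frame(
    track_id = vapply(stream$frames, `[[`, "", "track_id"),
    frame_index = vapply(stream$frames, `[[`, 0L, "frame_index"),
    feats,
    stringsAsFactors = FALSE)
  if (!is.null(labels)) out$label <- as.integer(labels)
  out
}

#' Write / read a feature table as CSV
#'
#' Plain-text interchange format for labeled or unlabeled feature tables:
#' header `track_id,frame_index,cm_x,...,nose_ankle[,label]`, one row per
#' frame-person.
#'
#' @param table A feature table as produced by [feature_table()].
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns the data frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame_index", feature_names())
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab$track_id <- as.character(tab$track_id)
  tab
}
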