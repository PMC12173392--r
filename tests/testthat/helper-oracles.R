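# Independent geometry oracles (atan2 formulation, no arccos) and small
# fixture builders used across the suite.

# angle between two vectors via atan2(|cross|, dot) -- independent of the
# package's clamped-arccos path
oracle_vec_angle <- function(u, v) {
  u <- unname(u); v <- unname(v)
  atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)) * 180 / pi
}
oracle_vertical_angle <- function(v) oracle_vec_angle(v, c(0, 1))
oracle_horizontal_angle <- function(v) oracle_vec_angle(v, c(1, 0))

# a fully visible random pose frame (uses the ambient RNG stream)
random_pose_frame <- function(track_id = "r", frame_index = 0L,
                              lo = 0, hi = 640) {
  kp <- cbind(x = runif(17, lo, hi), y = runif(17, lo, hi), confidence = 1)
  pose_frame(track_id, frame_index, kp)
}

# frame with specific keypoints placed, everything else hidden
sparse_frame <- function(points, frame_index = 0L) {
  kp <- cbind(x = 0, y = 0, confidence = 0)[rep(1, 17), ]
  nm <- coco_keypoint_names()
  for (name in names(points)) {
    i <- match(name, nm)
    kp[i, ] <- c(points[[name]], 1)
  }
  pose_frame("s", frame_index, kp)
}

# apply an affine map (rotation deg + scale + shift) to all keypoints
transform_frame <- function(frame, rotate_deg = 0, scale = 1,
                            shift = c(0, 0), center = c(0, 0)) {
  th <- rotate_deg * pi / 180
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  kp <- frame$keypoints
  xy <- sweep(kp[, c("x", "y")], 2, center)
  xy <- xy %*% t(rot) * scale
  kp[, c("x", "y")] <- sweep(xy, 2, center + shift, `+`)
  pose_frame(frame$track_id, frame$frame_index, kp)
}

# exhaustive Mann-Whitney AUC: fraction of (pos, neg) pairs ranked
# correctly, ties counting one half
oracle_auc <- function(scores, is_pos) {
  ps <- scores[is_pos]; ns <- scores[!is_pos]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# tiny labeled table: two well-separated torso clusters
toy_feature_table <- function(n = 20, seed = 1) {
  set.seed(seed)
  mk <- function(torso, label) data.frame(
    track_id = "t", frame_index = seq_len(n),
    cm_x = runif(n, .4, .6), cm_y = runif(n, .4, .6),
    shoulder_nose = runif(n, 80, 90), torso = torso + rnorm(n, 0, 2),
    hip = runif(n, 0, 5), shoulder = runif(n, 0, 5),
    left_leg = runif(n, 0, 5), right_leg = runif(n, 0, 5),
    nose_ankle = torso + rnorm(n, 0, 2), label = label)
  rbind(mk(5, 1L), mk(85, 0L))
}
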