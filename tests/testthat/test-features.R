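test_that("analytic spot checks for every angle operator", {
  # center of mass
  f <- sparse_frame(list(nose = c(0, 0), left_hip = c(3, 0),
                         right_hip = c(0, 3)))
  expect_equal(unname(center_of_mass(f)), c(1, 1))
  all_same <- pose_frame("p", 0, cbind(x = 7, y = 9, confidence = 1)[rep(1, 17), ])
  expect_equal(unname(center_of_mass(all_same)), c(7, 9))

  # shoulder-nose angle at the nose
  f <- sparse_frame(list(nose = c(0, 0), left_shoulder = c(-1, 1),
                         right_shoulder = c(1, 1)))
  expect_equal(shoulder_nose_angle(f), 90)
  f <- sparse_frame(list(nose = c(0, 0), left_shoulder = c(-1, 0),
                         right_shoulder = c(1, 0)))
  expect_equal(shoulder_nose_angle(f), 180)

  # torso angle against vertical
  f <- sparse_frame(list(nose = c(100, 50), left_hip = c(90, 150),
                         right_hip = c(110, 150)))
  expect_equal(torso_angle(f), 0)
  f <- sparse_frame(list(nose = c(0, 100), left_hip = c(100, 100),
                         right_hip = c(100, 100)))
  expect_equal(torso_angle(f), 90)
  f <- sparse_frame(list(nose = c(0, 0), left_hip = c(3, 4),
                         right_hip = c(3, 4)))
  expect_equal(torso_angle(f), acos(4 / 5) * 180 / pi)  # 36.8699 deg
  expect_equal(torso_angle(f), 36.86989765, tolerance = 1e-8)

  # hip / shoulder line angles against horizontal (not folded)
  expect_equal(hip_angle(sparse_frame(list(left_hip = c(0, 0),
                                           right_hip = c(2, 0)))), 0)
  expect_equal(hip_angle(sparse_frame(list(left_hip = c(0, 0),
                                           right_hip = c(0, 2)))), 90)
  expect_equal(hip_angle(sparse_frame(list(left_hip = c(0, 0),
                                           right_hip = c(-1, 1)))), 135)
  expect_equal(shoulder_angle(sparse_frame(list(left_shoulder = c(0, 0),
                                                right_shoulder = c(5, 0)))), 0)
  expect_equal(shoulder_angle(sparse_frame(list(left_shoulder = c(0, 0),
                                                right_shoulder = c(0, 5)))), 90)

  # knee flexion
  straight <- sparse_frame(list(left_hip = c(0, 0), left_knee = c(0, 1),
                                left_ankle = c(0, 2)))
  expect_equal(leg_angle(straight, "left"), 0)
  bent <- sparse_frame(list(left_hip = c(0, 0), left_knee = c(0, 1),
                            left_ankle = c(1, 1)))
  expect_equal(leg_angle(bent, "left"), 90)

  # nose-to-ankle against vertical
  f <- sparse_frame(list(nose = c(0, 0), left_ankle = c(-1, 10),
                         right_ankle = c(1, 10)))
  expect_equal(nose_to_ankle_angle(f), 0)
  f <- sparse_frame(list(nose = c(0, 0), left_ankle = c(10, 0),
                         right_ankle = c(10, 0)))
  expect_equal(nose_to_ankle_angle(f), 90)
  f <- sparse_frame(list(nose = c(0, 0), left_ankle = c(-6, 8),
                         right_ankle = c(-6, 8)))
  expect_equal(nose_to_ankle_angle(f), acos(8 / 10) * 180 / pi)
})

test_that("missing keypoints and degenerate geometry come back NA", {
  f <- sparse_frame(list(nose = c(0, 0)))  # only the nose
  expect_true(is.na(shoulder_nose_angle(f)))
  expect_true(is.na(torso_angle(f)))
  # nose coincides with a shoulder: zero-length vector
  f <- sparse_frame(list(nose = c(1, 1), left_shoulder = c(1, 1),
                         right_shoulder = c(2, 2)))
  expect_true(is.na(shoulder_nose_angle(f)))
  # coincident hips
  f <- sparse_frame(list(left_hip = c(1, 1), right_hip = c(1, 1)))
  expect_true(is.na(hip_angle(f)))
  # no visible keypoints at all
  none <- pose_frame("p", 0, cbind(x = 0, y = 0, confidence = 0)[rep(1, 17), ])
  expect_true(all(is.na(center_of_mass(none))))
  expect_true(all(is.na(extract_features(none))))
})

test_that("extract_features flags exactly the uncomputable features", {
  pf <- make_pose_template("standing")
  fv <- extract_features(pf)
  expect_named(fv, feature_names())
  expect_false(anyNA(fv))
  expect_lt(fv[["torso"]], 15)
  expect_lt(fv[["nose_ankle"]], 15)

  kp <- pf$keypoints
  kp[c("left_hip", "right_hip"), "confidence"] <- 0
  no_hips <- pose_frame("p", 0, kp)
  fv2 <- extract_features(no_hips)
  expect_true(is.na(fv2[["torso"]]))
  expect_true(is.na(fv2[["hip"]]))
  expect_true(is.na(fv2[["left_leg"]]))   # left hip feeds the left knee angle
  expect_false(is.na(fv2[["shoulder_nose"]]))
  expect_false(is.na(fv2[["nose_ankle"]]))
})

test_that("every angle matches the independent atan2 oracle (1000 frames)", {
  set.seed(101)
  worst <- 0
  near_degenerate <- function(a) min(a, 180 - a) < 0.05
  for (i in 1:1000) {
    f <- random_pose_frame()
    k <- function(n) f$keypoints[n, c("x", "y")]
    mh <- (k("left_hip") + k("right_hip")) / 2
    ma <- (k("left_ankle") + k("right_ankle")) / 2
    got <- c(shoulder_nose_angle(f), torso_angle(f), hip_angle(f),
             shoulder_angle(f), leg_angle(f, "left"), leg_angle(f, "right"),
             nose_to_ankle_angle(f))
    want <- c(
      oracle_vec_angle(k("left_shoulder") - k("nose"),
                       k("right_shoulder") - k("nose")),
      oracle_vertical_angle(mh - k("nose")),
      oracle_horizontal_angle(k("right_hip") - k("left_hip")),
      oracle_horizontal_angle(k("right_shoulder") - k("left_shoulder")),
      oracle_vec_angle(k("left_knee") - k("left_hip"),
                       k("left_ankle") - k("left_knee")),
      oracle_vec_angle(k("right_knee") - k("right_hip"),
                       k("right_ankle") - k("right_knee")),
      oracle_vertical_angle(ma - k("nose")))
    # arccos conditioning blows up where vectors are numerically collinear;
    # the equivalence claim is for non-degenerate geometry
    ok <- !vapply(want, near_degenerate, TRUE)
    worst <- max(worst, max(abs(got[ok] - want[ok])))
  }
  expect_lt(worst, 1e-9)
})

angle_cols <- setdiff(feature_names(), c("cm_x", "cm_y"))

test_that("similarity invariance: translation and uniform scaling", {
  set.seed(102)
  for (i in 1:200) {
    f <- random_pose_frame()
    g <- transform_frame(f, scale = runif(1, 0.2, 5),
                         shift = runif(2, -1000, 1000))
    fv <- extract_features(f); gv <- extract_features(g)
    expect_equal(fv[angle_cols], gv[angle_cols], tolerance = 1e-9)
    expect_equal(fv[c("cm_x", "cm_y")], gv[c("cm_x", "cm_y")],
                 tolerance = 1e-9)
  }
  # the spec'd concrete case: +(500, 300) shift and x2 scale
  f <- make_pose_template("standing")
  g <- transform_frame(f, scale = 2, shift = c(500, 300))
  expect_equal(extract_features(f), extract_features(g), tolerance = 1e-9)
})

test_that("rotation covariance of vertical-reference angles", {
  set.seed(103)
  for (i in 1:200) {
    f <- random_pose_frame()
    theta <- runif(1, 1, 89)
    g <- transform_frame(f, rotate_deg = theta, center = runif(2, 0, 640))
    # relative angles are rotation-invariant
    expect_equal(shoulder_nose_angle(g), shoulder_nose_angle(f), tolerance = 1e-9)
    expect_equal(leg_angle(g, "left"), leg_angle(f, "left"), tolerance = 1e-9)
    expect_equal(leg_angle(g, "right"), leg_angle(f, "right"), tolerance = 1e-9)
    # vertical-reference angles shift by exactly theta, up to the sign of
    # the rotation relative to the vector and arccos folding at 0/180
    fold <- function(a) { a <- abs(a); if (a > 180) 360 - a else a }
    for (op in c(torso_angle, nose_to_ankle_angle)) {
      a0 <- op(f); a1 <- op(g)
      expect_lt(min(abs(c(fold(a0 + theta), fold(a0 - theta)) - a1)), 1e-9)
    }
  }
  # directional case with no folding: upright template tips by exactly theta
  st <- make_pose_template("standing")
  for (theta in c(10, 45, 80)) {
    tipped <- transform_frame(st, rotate_deg = theta, center = c(320, 400))
    expect_equal(torso_angle(tipped), theta, tolerance = 1e-9)
    expect_equal(nose_to_ankle_angle(tipped), theta, tolerance = 1e-9)
  }
})

test_that("horizontal flip swaps leg angles, fixes vertical angles", {
  set.seed(104)
  pairs <- cbind(c(2, 4, 6, 8, 10, 12, 14, 16), c(3, 5, 7, 9, 11, 13, 15, 17))
  for (i in 1:200) {
    f <- random_pose_frame()
    kp <- f$keypoints
    kp[, "x"] <- -kp[, "x"]
    tmp <- kp[pairs[, 1], ]; kp[pairs[, 1], ] <- kp[pairs[, 2], ]
    kp[pairs[, 2], ] <- tmp
    g <- pose_frame(f$track_id, f$frame_index, kp)
    expect_equal(leg_angle(g, "right"), leg_angle(f, "left"), tolerance = 1e-9)
    expect_equal(leg_angle(g, "left"), leg_angle(f, "right"), tolerance = 1e-9)
    expect_equal(torso_angle(g), torso_angle(f), tolerance = 1e-9)
    expect_equal(nose_to_ankle_angle(g), nose_to_ankle_angle(f),
                 tolerance = 1e-9)
    expect_equal(shoulder_nose_angle(g), shoulder_nose_angle(f),
                 tolerance = 1e-9)
  }
})

test_that("all angles stay inside [0, 180] on arbitrary finite input", {
  set.seed(105)
  for (i in 1:300) {
    f <- random_pose_frame(lo = -1e6, hi = 1e6)
    fv <- extract_features(f)
    ok <- !is.na(fv[angle_cols])
    expect_true(all(fv[angle_cols][ok] >= 0 & fv[angle_cols][ok] <= 180))
  }
})

test_that("feature tables round-trip through CSV", {
  sq <- generate_sequence(scenario_spec("standing", duration_frames = 20,
                                        rng_seed = 5, dropout_prob = 0))
  tab <- feature_table(sq$stream, labels = sq$frame_labels)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$torso, tab$torso, tolerance = 1e-6)
  expect_identical(back$label, tab$label)
  expect_error(read_feature_table(withr::local_tempfile(fileext = ".csv")),
               "not found")
})
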