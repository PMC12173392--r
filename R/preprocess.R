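# Feature-series preprocessing: moving-average smoothing of angle channels,
# normalization, missing-feature resolution, and keypoint-space training
# augmentation (rotation / scale / horizontal flip / Gaussian jitter --
# the exact geometric images of the usual image-space transforms, which is
# all a geometry-only classifier can see).

#' Preprocessing configuration
#'
#' @param smoothing_window Moving-average window in frames (>= 1; 1 = no
#'   smoothing). Default 5.
#' @param smoothing_mode `"causal"` (window ends at the current frame;
#'   usable in live operation, the default) or `"centered"` (symmetric
#'   window, offline only).
#' @param angle_norm `"degrees_over_180"` (angles divided by 180, the
#'   deterministic default), `"zscore"` (per-channel standardization with
#'   statistics fitted on training data), or `"none"`.
#' @param missing_policy `"drop_frame"` (default) removes frames with any
#'   missing feature; `"forward_fill"` carries the last valid value across
#'   gaps of at most `smoothing_window` frames, dropping longer gaps.
#' @param visibility_threshold Minimum keypoint confidence to count a
#'   keypoint as visible. Default 0.5.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(smoothing_window = 5L,
                              smoothing_mode = c("causal", "centered"),
                              angle_norm = c("degrees_over_180", "zscore", "none"),
                              missing_policy = c("drop_frame", "forward_fill"),
                              visibility_threshold = 0.5) {
  smoothing_window <- as.integer(smoothing_window)
  if (is.na(smoothing_window) || smoothing_window < 1L)
    stop("smoothing_window must be >= 1", call. = FALSE)
  if (visibility_threshold < 0 || visibility_threshold > 1)
    stop("visibility_threshold must lie in [0, 1]", call. = FALSE)
  structure(list(smoothing_window = smoothing_window,
                 smoothing_mode = match.arg(smoothing_mode),
                 angle_norm = match.arg(angle_norm),
                 missing_policy = match.arg(missing_policy),
                 visibility_threshold = visibility_threshold),
            class = "preprocess_config")
}

# NA-aware moving average of one numeric channel
.moving_average <- function(x, window, mode) {
  n <- length(x)
  if (window == 1L || n == 0L) return(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (mode == "causal") {
      lo <- max(1L, i - window + 1L); hi <- i
    } else {
      half <- (window - 1L) %/% 2L
      lo <- max(1L, i - half); hi <- min(n, i + half)
    }
    w <- x[lo:hi]
    out[i] <- if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }
  out
}

#' Smooth a per-track feature series
#'
#' Applies an NA-aware moving average to every feature channel of a feature
#' table, each track independently, in frame order. Missing entries are
#' excluded from each window's mean (and stay `NA` themselves when the whole
#' window is missing). A window of 1 is the identity.
#'
#' @param table Feature table ([feature_table()]), any mix of tracks.
#' @param cfg A [preprocess_config()].
#' @return The table with smoothed feature columns.
#' @export
smooth_features <- function(table, cfg = preprocess_config()) {
  if (nrow(table) == 0L) return(table)
  cols <- feature_names()
  for (id in unique(table$track_id)) {
    sel <- which(table$track_id == id)
    sel <- sel[order(table$frame_index[sel])]
    for (cl in cols)
      table[sel, cl] <- .moving_average(table[sel, cl],
                                        cfg$smoothing_window,
                                        cfg$smoothing_mode)
  }
  table
}

#' Fit / apply feature normalization
#'
#' `fit_normalizer` learns a normalization transform on training features;
#' `apply_normalizer` applies a fitted transform to any feature table (the
#' same transform must be used at train and predict time, and the fitted
#' classifier carries it along).
#'
#' Modes: `degrees_over_180` divides each angle by 180 so everything lives
#' in \[0, 1\] next to the already-normalized center-of-mass coordinates;
#' `zscore` standardizes each channel with training mean and population SD
#' (a zero-variance channel is centered and left with unit divisor, with a
#' warning); `none` passes features through.
#'
#' @param table Training feature table.
#' @param cfg A [preprocess_config()].
#' @return `fit_normalizer`: a `feature_normalizer` object.
#' @export
fit_normalizer <- function(table, cfg = preprocess_config()) {
  mode <- cfg$angle_norm
  stats <- NULL
  if (mode == "zscore") {
    cols <- feature_names()
    mu <- vapply(cols, function(cl) mean(table[[cl]], na.rm = TRUE), 0)
    n_eff <- vapply(cols, function(cl) sum(!is.na(table[[cl]])), 0)
    sdev <- vapply(cols, function(cl) {
      v <- table[[cl]][!is.na(table[[cl]])]
      if (length(v) < 1L) return(1)
      sqrt(mean((v - mean(v))^2))  # population SD
    }, 0)
    zero <- sdev == 0 | !is.finite(sdev)
    if (any(zero)) {
      warning("zero-variance channel(s) ", paste(cols[zero], collapse = ", "),
              ": centered with unit divisor", call. = FALSE)
      sdev[zero] <- 1
    }
    mu[!is.finite(mu)] <- 0
    stats <- list(mean = mu, sd = sdev, n = n_eff)
  }
  structure(list(mode = mode, stats = stats), class = "feature_normalizer")
}

#' @rdname fit_normalizer
#' @param normalizer A fitted `feature_normalizer`.
#' @return `apply_normalizer`: the normalized table.
#' @export
apply_normalizer <- function(normalizer, table) {
  stopifnot(inherits(normalizer, "feature_normalizer"))
  angle_cols <- setdiff(feature_names(), c("cm_x", "cm_y"))
  if (normalizer$mode == "degrees_over_180") {
    for (cl in angle_cols) table[[cl]] <- table[[cl]] / 180
  } else if (normalizer$mode == "zscore") {
    for (cl in feature_names())
      table[[cl]] <- (table[[cl]] - normalizer$stats$mean[[cl]]) /
        normalizer$stats$sd[[cl]]
  }
  table
}

#' Resolve missing features in a series
#'
#' Frames can carry `NA` features when keypoints were invisible or geometry
#' degenerate. `drop_frame` removes any row with a missing feature.
#' `forward_fill` carries the last valid value of each channel forward over
#' gaps of at most `smoothing_window` frames (per track, in frame order)
#' and drops rows still incomplete after filling.
#'
#' @param table Feature table.
#' @param cfg A [preprocess_config()].
#' @return The completed table (possibly with fewer rows).
#' @export
resolve_missing <- function(table, cfg = preprocess_config()) {
  cols <- feature_names()
  if (nrow(table) == 0L) return(table)
  if (cfg$missing_policy == "forward_fill") {
    for (id in unique(table$track_id)) {
      sel <- which(table$track_id == id)
      sel <- sel[order(table$frame_index[sel])]
      for (cl in cols) {
        v <- table[sel, cl]
        last_val <- NA_real_; last_at <- -Inf
        for (j in seq_along(v)) {
          if (!is.na(v[j])) {
            last_val <- v[j]; last_at <- j
          } else if (j - last_at <= cfg$smoothing_window) {
            v[j] <- last_val
          }
        }
        table[sel, cl] <- v
      }
    }
  }
  keep <- stats::complete.cases(table[, cols])
  if (!any(keep))
    warning("all frames dropped while resolving missing features",
            call. = FALSE)
  table[keep, , drop = FALSE]
}

#' Augmentation configuration
#'
#' Training-set augmentation in keypoint space. Defaults follow the usual
#' practice for pose data: rotations in \[-15, +15\] degrees, scale factors
#' in \[0.75, 1.25\], horizontal flip with probability 0.5, and Gaussian
#' coordinate noise with SD equal to 0.01 of the person bounding-box
#' diagonal (a scale-free reading of "sigma = 0.01" on normalized images).
#'
#' @param rotation_range Degrees, `c(low, high)`.
#' @param scale_range Unitless, `c(low, high)`, positive.
#' @param hflip_prob Probability of a horizontal flip.
#' @param noise_sigma Coordinate noise SD as a fraction of the bbox diagonal.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotation_range = c(-15, 15),
                           scale_range = c(0.75, 1.25),
                           hflip_prob = 0.5,
                           noise_sigma = 0.01) {
  if (length(rotation_range) != 2L || diff(rotation_range) < 0)
    stop("rotation_range must be an ordered pair", call. = FALSE)
  if (length(scale_range) != 2L || diff(scale_range) < 0 ||
      any(scale_range <= 0))
    stop("scale_range must be an ordered positive pair", call. = FALSE)
  if (hflip_prob < 0 || hflip_prob > 1)
    stop("hflip_prob must lie in [0, 1]", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(rotation_range = as.numeric(rotation_range),
                 scale_range = as.numeric(scale_range),
                 hflip_prob = hflip_prob,
                 noise_sigma = noise_sigma),
            class = "augment_config")
}

#' Augment a pose frame in keypoint space
#'
#' Applies, in order: rotation by an angle drawn uniformly from
#' `rotation_range` about the visible-keypoint centroid; uniform scaling by
#' a factor from `scale_range` about the same centroid; a horizontal flip
#' with probability `hflip_prob` (x reflected about the centroid, left/right
#' keypoint indices swapped); additive isotropic Gaussian noise with SD
#' `noise_sigma` times the visible bounding-box diagonal. Confidences are
#' untouched; the result is a valid [pose_frame()]. Deterministic for a
#' fixed RNG state (set a seed before calling).
#'
#' @param frame A [pose_frame()].
#' @param cfg An [augment_config()].
#' @param visibility Minimum confidence counting a keypoint as visible.
#' @return The augmented [pose_frame()].
#' @export
augment_keypoints <- function(frame, cfg = augment_config(), visibility = 0.5) {
  stopifnot(inherits(frame, "pose_frame"), inherits(cfg, "augment_config"))
  kp <- frame$keypoints
  vis <- .visible(frame, visibility)
  if (!any(vis)) return(frame)
  ctr <- c(mean(kp[vis, "x"]), mean(kp[vis, "y"]))
  theta <- stats::runif(1, cfg$rotation_range[1], cfg$rotation_range[2]) * pi / 180
  s <- stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
  do_flip <- stats::runif(1) < cfg$hflip_prob

  xy <- sweep(kp[, c("x", "y"), drop = FALSE], 2, ctr)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy <- xy %*% t(rot) * s
  if (do_flip) {
    xy[, 1] <- -xy[, 1]
    pairs <- .coco_lr_pairs()
    tmp <- xy[pairs[, "left"], , drop = FALSE]
    xy[pairs[, "left"], ] <- xy[pairs[, "right"], , drop = FALSE]
    xy[pairs[, "right"], ] <- tmp
    cf <- kp[, "confidence"]
    tmpc <- cf[pairs[, "left"]]
    cf[pairs[, "left"]] <- cf[pairs[, "right"]]
    cf[pairs[, "right"]] <- tmpc
    kp[, "confidence"] <- cf
  }
  xy <- sweep(xy, 2, ctr, `+`)
  if (cfg$noise_sigma > 0) {
    visw <- kp[, "confidence"] >= visibility & kp[, "confidence"] > 0
    diag_len <- sqrt(diff(range(xy[visw, 1]))^2 + diff(range(xy[visw, 2]))^2)
    xy <- xy + matrix(stats::rnorm(34, 0, cfg$noise_sigma * diag_len), ncol = 2)
  }
  kp[, c("x", "y")] <- xy
  pose_frame(frame$track_id, frame$frame_index, kp,
             timestamp_s = frame$timestamp_s)
}

#' Augment a labeled training stream
#'
#' Convenience wrapper producing `times` augmented copies of every frame of
#' a stream (labels copied along). Applied to training data only; evaluation
#' data should never be augmented.
#'
#' @param stream A [track_stream()].
#' @param labels Integer labels aligned with `stream$frames`.
#' @param cfg An [augment_config()].
#' @param times Number of augmented copies per frame.
#' @param seed RNG seed for reproducibility.
#' @return A list with `stream` (original + augmented frames, augmented
#'   copies on suffixed track ids) and `labels`.
#' @export
augment_training_stream <- function(stream, labels, cfg = augment_config(),
                                    times = 1L, seed = 1L) {
  stopifnot(length(labels) == length(stream$frames))
  set.seed(seed)
  frames <- stream$frames
  out_labels <- labels
  for (t in seq_len(times)) {
    for (i in seq_along(stream$frames)) {
      f <- stream$frames[[i]]
      af <- augment_keypoints(f, cfg)
      af$track_id <- paste0(f$track_id, "_aug", t)
      frames[[length(frames) + 1L]] <- af
      out_labels <- c(out_labels, labels[i])
    }
  }
  list(stream = track_stream(frames, fps = stream$fps), labels = out_labels)
}
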