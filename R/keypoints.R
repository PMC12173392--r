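# Canonical skeleton data model: COCO 17-keypoint frames grouped into
# per-person track streams. Everything downstream (features, classifier,
# fall engine) consumes these structures, so any pose-estimation backend
# only needs to emit them.

#' COCO keypoint names, in canonical order
#'
#' The 17 landmark names of the COCO human-pose convention, in the fixed
#' index order used throughout the package: nose, eyes, ears, shoulders,
#' elbows, wrists, hips, knees, ankles (left before right within each pair).
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' coco_keypoint_names()
coco_keypoint_names <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

# index pairs swapped under a horizontal flip (left <-> right)
.coco_lr_pairs <- function() {
  cbind(left  = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L),
        right = c(3L, 5L, 7L, 9L, 11L, 13L, 15L, 17L))
}

#' Construct a single pose frame
#'
#' A pose frame is one detected person in one video frame: a 17 x 3 matrix
#' of keypoints (columns `x`, `y`, `confidence`) in COCO order, plus a track
#' id and a frame index. Image coordinates are used: origin at the top-left
#' corner, x rightward, y *downward* -- for an upright person the vector
#' from nose to mid-hip therefore points in the +y direction.
#'
#' A keypoint with `confidence == 0` is *missing*: its coordinates carry no
#' meaning and are ignored by all geometry.
#'
#' @param track_id Opaque person identifier (coerced to character).
#' @param frame_index Non-negative integer frame number.
#' @param keypoints Numeric 17 x 3 matrix (x, y, confidence) or a flat
#'   numeric vector of 51 values `(x1, y1, c1, ..., x17, y17, c17)`.
#' @param timestamp_s Optional timestamp in seconds.
#' @return An object of class `pose_frame`.
#' @export
#' @examples
#' kp <- cbind(x = rnorm(17, 100), y = rnorm(17, 200), confidence = 1)
#' pf <- pose_frame("p1", 0, kp)
#' pf
pose_frame <- function(track_id, frame_index, keypoints, timestamp_s = NULL) {
  if (is.numeric(keypoints) && is.null(dim(keypoints))) {
    if (length(keypoints) != 51L)
      stop("flat keypoint vector must have 51 values (17 x 3), got ",
           length(keypoints), call. = FALSE)
    keypoints <- matrix(keypoints, ncol = 3L, byrow = TRUE)
  }
  keypoints <- as.matrix(keypoints)
  if (!is.numeric(keypoints) || nrow(keypoints) != 17L || ncol(keypoints) != 3L)
    stop("keypoints must be a numeric 17 x 3 matrix, got ",
         paste(dim(keypoints), collapse = " x "), call. = FALSE)
  colnames(keypoints) <- c("x", "y", "confidence")
  rownames(keypoints) <- coco_keypoint_names()
  conf <- keypoints[, "confidence"]
  if (any(!is.finite(conf)) || any(conf < 0) || any(conf > 1))
    stop("keypoint confidences must lie in [0, 1]", call. = FALSE)
  vis <- conf > 0
  if (any(vis & (!is.finite(keypoints[, "x"]) | !is.finite(keypoints[, "y"]))))
    stop("keypoints with confidence > 0 must have finite coordinates",
         call. = FALSE)
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop("frame_index must be a non-negative integer", call. = FALSE)
  structure(
    list(track_id = as.character(track_id),
         frame_index = frame_index,
         timestamp_s = if (is.null(timestamp_s)) NULL else as.numeric(timestamp_s),
         keypoints = keypoints),
    class = "pose_frame")
}

#' @export
print.pose_frame <- function(x, ...) {
  nvis <- sum(x$keypoints[, "confidence"] > 0)
  cat(sprintf("<pose_frame> track %s, frame %d, %d/17 keypoints visible\n",
              x$track_id, x$frame_index, nvis))
  invisible(x)
}

#' Construct a track stream
#'
#' A track stream bundles pose frames from one or more person tracks with
#' the video frame rate. Frames are sorted by `(track_id, frame_index)`;
#' duplicate `(track_id, frame_index)` pairs are rejected.
#'
#' @param frames List of [pose_frame()] objects.
#' @param fps Frames per second of the source video (positive).
#' @return An object of class `track_stream`.
#' @export
track_stream <- function(frames = list(), fps = 30) {
  fps <- as.numeric(fps)
  if (!is.finite(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  if (!is.list(frames)) stop("frames must be a list of pose_frame", call. = FALSE)
  for (f in frames)
    if (!inherits(f, "pose_frame"))
      stop("all elements of frames must be pose_frame objects", call. = FALSE)
  if (length(frames)) {
    ids <- vapply(frames, `[[`, "", "track_id")
    idx <- vapply(frames, `[[`, 0L, "frame_index")
    key <- paste(ids, idx, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (track_id, frame_index) pair: ",
           sub("\r", ", frame ", key[duplicated(key)][1L]), call. = FALSE)
    frames <- frames[order(ids, idx)]
  }
  structure(list(fps = fps, frames = frames), class = "track_stream")
}

#' @export
print.track_stream <- function(x, ...) {
  ids <- track_ids(x)
  cat(sprintf("<track_stream> %d frames, %d track(s) [%s], %.3g fps\n",
              length(x$frames), length(ids),
              paste(utils::head(ids, 5), collapse = ", "), x$fps))
  invisible(x)
}

#' @export
length.track_stream <- function(x) length(x$frames)

#' Track ids present in a stream
#' @param stream A [track_stream()].
#' @return Character vector of unique track ids, sorted.
#' @export
track_ids <- function(stream) {
  stopifnot(inherits(stream, "track_stream"))
  sort(unique(vapply(stream$frames, `[[`, "", "track_id")))
}

#' Midpoint of two keypoints
#'
#' Coordinate-wise mean of two visible keypoints, e.g. the hip or ankle
#' midpoint used by the torso and nose-to-ankle angles.
#'
#' @param a,b Numeric length-2 vectors `(x, y)`, or rows of a pose frame's
#'   keypoint matrix.
#' @return Numeric `c(x, y)`.
#' @export
#' @examples
#' midpoint(c(0, 0), c(2, 4))  # c(1, 2)
midpoint <- function(a, b) {
  a <- as.numeric(a)[1:2]; b <- as.numeric(b)[1:2]
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("midpoint of non-finite coordinates", call. = FALSE)
  (a + b) / 2
}

# visible-keypoint mask at a confidence threshold
.visible <- function(frame, threshold = 0.5) {
  frame$keypoints[, "confidence"] >= threshold &
    frame$keypoints[, "confidence"] > 0
}

## ---- JSON Lines / COCO readers and writers --------------------------------

#' Read a keypoint stream
#'
#' Reads per-person per-frame keypoint records into a validated
#' [track_stream()]. Two dialects are supported:
#'
#' * `"jsonl"` (canonical, read/write): one JSON object per line with keys
#'   `track_id`, `frame_index`, optional `timestamp_s`, and `keypoints` --
#'   a flat array of 51 numbers `(x1, y1, c1, ..., x17, y17, c17)`.
#' * `"coco-json"` (read-only): a COCO keypoint annotation file with
#'   `images` and `annotations`; each annotation's 51-number `keypoints`
#'   array uses visibility flags v in `{0, 1, 2}`, mapped to confidence
#'   0, 0.5, 1. Track id comes from `track_id` if present, else from
#'   the category/instance id.
#'
#' Out-of-order frames within a track are sorted; duplicated
#' `(track_id, frame_index)` pairs and records with a keypoint count other
#' than 17 are rejected with an error naming the offending record.
#'
#' @param path File to read.
#' @param dialect `"jsonl"` or `"coco-json"`.
#' @param fps Frames per second to attach to the stream.
#' @return A [track_stream()].
#' @seealso [write_keypoint_stream()]
#' @export
read_keypoint_stream <- function(path, dialect = c("jsonl", "coco-json"),
                                 fps = 30) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "jsonl") .read_jsonl(path, fps) else .read_coco_json(path, fps)
}

.read_jsonl <- function(path, fps) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  frames <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e)
                      stop("parse error at line ", i, ": ", conditionMessage(e),
                           call. = FALSE))
    for (k in c("track_id", "frame_index", "keypoints"))
      if (is.null(rec[[k]]))
        stop("record at line ", i, " missing field '", k, "'", call. = FALSE)
    kp <- as.numeric(unlist(rec$keypoints))
    if (length(kp) != 51L)
      stop("record at line ", i, " has ", length(kp) / 3,
           " keypoints; exactly 17 required", call. = FALSE)
    frames[[i]] <- tryCatch(
      pose_frame(rec$track_id, rec$frame_index, kp,
                 timestamp_s = rec$timestamp_s),
      error = function(e)
        stop("invalid record at line ", i, ": ", conditionMessage(e),
             call. = FALSE))
  }
  track_stream(frames, fps = fps)
}

.read_coco_json <- function(path, fps) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  anns <- doc$annotations
  if (is.null(anns)) stop("COCO file has no 'annotations'", call. = FALSE)
  img_index <- new.env(parent = emptyenv())
  for (img in doc$images)
    assign(as.character(img$id), img, envir = img_index)
  frames <- vector("list", length(anns))
  for (i in seq_along(anns)) {
    a <- anns[[i]]
    kp <- as.numeric(unlist(a$keypoints))
    if (length(kp) != 51L)
      stop("annotation ", i, " has ", length(kp) / 3,
           " keypoints; exactly 17 required", call. = FALSE)
    m <- matrix(kp, ncol = 3L, byrow = TRUE)
    # COCO v-flag: 0 not labeled, 1 labeled invisible, 2 labeled visible
    m[, 3L] <- c(0, 0.5, 1)[pmin(pmax(round(m[, 3L]), 0), 2) + 1]
    img_id <- as.character(a$image_id)
    frame_index <- if (exists(img_id, envir = img_index)) {
      img <- get(img_id, envir = img_index)
      if (!is.null(img$frame_index)) img$frame_index else a$image_id
    } else a$image_id
    tid <- if (!is.null(a$track_id)) a$track_id else
      if (!is.null(a$id)) a$id else i
    frames[[i]] <- pose_frame(tid, frame_index, m)
  }
  track_stream(frames, fps = fps)
}

#' Write a keypoint stream as JSON Lines
#'
#' Serializes a [track_stream()] in the canonical JSONL dialect; the result
#' round-trips through [read_keypoint_stream()] with coordinates preserved
#' to full double precision.
#'
#' @param stream A [track_stream()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_keypoint_stream <- function(stream, path) {
  stopifnot(inherits(stream, "track_stream"))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e)
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  for (f in stream$frames) {
    rec <- list(track_id = f$track_id, frame_index = f$frame_index)
    if (!is.null(f$timestamp_s)) rec$timestamp_s <- f$timestamp_s
    rec$keypoints <- as.numeric(t(f$keypoints))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Null pose backend
#'
#' The package consumes keypoints from any pose-estimation backend through
#' a minimal adapter contract: a function taking one image (any object) and
#' returning a list of [pose_frame()]s for the people detected in it. This
#' null implementation detects nobody; it documents the contract and serves
#' as a test double. Real detector bindings are deliberately out of scope.
#'
#' @return A function `(image, frame_index) -> list of pose_frame` that
#'   always returns an empty list.
#' @export
null_pose_backend <- function() {
  function(image, frame_index = 0L) list()
}
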