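# Temporal fall confirmation: per-track folding of frame-level posture
# labels through three configurable criteria -- lying duration in seconds,
# lying duration in frames, and standing-to-lying transition speed. A fall
# event is emitted at most once per uninterrupted lying run.

#' Fall-determination criteria
#'
#' Three user-configurable rules decide when a lying run becomes a
#' confirmed fall:
#'
#' * **time rule** -- the person has been continuously classified lying for
#'   at least `time_threshold_s` seconds (e.g. 5 or 10);
#' * **frame rule** -- the lying run has reached `frame_threshold`
#'   consecutive frames (e.g. 200 or 500);
#' * **speed rule** -- the standing-to-lying transition took at most
#'   `speed_threshold_frames` frames *and* the lying run has persisted for
#'   `confirm_frames` frames (the confirmation run suppresses single-frame
#'   flickers).
#'
#' Disable a rule by passing `NULL`. `combine_mode = "any"` (default) fires
#' when any enabled rule is satisfied; `"all"` requires every enabled rule
#' simultaneously. Defaults enable only the time rule at 5 s.
#'
#' @param time_threshold_s Seconds of continuous lying, or `NULL`.
#' @param frame_threshold Frames of continuous lying, or `NULL`.
#' @param speed_threshold_frames Maximum standing-to-lying transition span
#'   in frames, or `NULL`.
#' @param confirm_frames Lying frames required to confirm the speed rule.
#' @param combine_mode `"any"` or `"all"` over the enabled rules.
#' @param gap_tolerance Frames a track may vanish before its state resets.
#' @return A `fall_criteria` object.
#' @export
fall_criteria <- function(time_threshold_s = 5,
                          frame_threshold = NULL,
                          speed_threshold_frames = NULL,
                          confirm_frames = 15L,
                          combine_mode = c("any", "all"),
                          gap_tolerance = 30L) {
  combine_mode <- match.arg(combine_mode)
  for (v in list(time_threshold_s, frame_threshold, speed_threshold_frames))
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("thresholds must be positive (or NULL to disable)", call. = FALSE)
  if (is.null(time_threshold_s) && is.null(frame_threshold) &&
      is.null(speed_threshold_frames))
    stop("at least one criterion must be enabled", call. = FALSE)
  if (confirm_frames < 1L) stop("confirm_frames must be >= 1", call. = FALSE)
  if (gap_tolerance < 0L) stop("gap_tolerance must be >= 0", call. = FALSE)
  structure(list(time_threshold_s = time_threshold_s,
                 frame_threshold = frame_threshold,
                 speed_threshold_frames = speed_threshold_frames,
                 confirm_frames = as.integer(confirm_frames),
                 combine_mode = combine_mode,
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "fall_criteria")
}

#' Fresh per-track state
#'
#' @param track_id Track identifier.
#' @return A `track_state` object: last seen label and frame, current
#'   lying-run onset, last standing frame, and the once-per-run fall flag.
#' @export
new_track_state <- function(track_id) {
  structure(list(track_id = as.character(track_id),
                 last_label = NA_integer_,
                 last_frame = NA_integer_,
                 lying_run_start = NA_integer_,
                 lying_run_len = 0L,
                 last_standing_frame = NA_integer_,
                 fall_flagged = FALSE),
            class = "track_state")
}

.make_event <- function(state, frame_index, criteria_fired) {
  transition <- if (!is.na(state$last_standing_frame))
    state$lying_run_start - state$last_standing_frame else NA_integer_
  structure(list(track_id = state$track_id,
                 trigger_frame = as.integer(frame_index),
                 lying_onset_frame = state$lying_run_start,
                 criterion = criteria_fired,
                 transition_duration_frames = as.integer(transition)),
            class = "fall_event")
}

#' @export
print.fall_event <- function(x, ...) {
  cat(sprintf("<fall_event> track %s: criterion [%s] at frame %d (lying since frame %d)\n",
              x$track_id, paste(x$criterion, collapse = ","),
              x$trigger_frame, x$lying_onset_frame))
  invisible(x)
}

#' Advance a track's fall state by one labeled frame
#'
#' The per-frame transition of the criterion engine. A standing label
#' closes any lying run, records the last standing frame, and clears the
#' fall flag; a lying label opens or extends a run, after which every
#' enabled criterion is evaluated:
#'
#' * time rule: `(frame_index - lying_run_start + 1) / fps >=
#'   time_threshold_s`;
#' * frame rule: lying-run length `>= frame_threshold`;
#' * speed rule: `lying_run_start - last_standing_frame <=
#'   speed_threshold_frames` and run length `>= confirm_frames`.
#'
#' If the track was unseen for more than `gap_tolerance` frames the state
#' resets first. At most one event fires per lying run.
#'
#' @param state A `track_state`.
#' @param frame_index Current frame index (must exceed the previous one).
#' @param label Posture label, 0 lying / 1 standing.
#' @param criteria A [fall_criteria()].
#' @param fps Frames per second (needed by the time rule).
#' @return List with updated `state` and `event` (a `fall_event` or `NULL`).
#' @export
fall_step <- function(state, frame_index, label, criteria, fps = 30) {
  stopifnot(inherits(state, "track_state"), inherits(criteria, "fall_criteria"))
  frame_index <- as.integer(frame_index)
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  if (!is.na(state$last_frame) && frame_index <= state$last_frame)
    stop("non-monotonic frame index for track ", state$track_id, ": ",
         frame_index, " after ", state$last_frame, call. = FALSE)
  if (!is.na(state$last_frame) &&
      frame_index - state$last_frame - 1L > criteria$gap_tolerance) {
    state <- new_track_state(state$track_id)  # track vanished too long
  }
  event <- NULL
  if (label == 1L) {
    state$last_standing_frame <- frame_index
    state$lying_run_start <- NA_integer_
    state$lying_run_len <- 0L
    state$fall_flagged <- FALSE
  } else {
    if (is.na(state$lying_run_start) || state$last_label == 1L) {
      state$lying_run_start <- frame_index
      state$lying_run_len <- 1L
    } else {
      state$lying_run_len <- state$lying_run_len + 1L
    }
    if (!state$fall_flagged) {
      fired <- character(0)
      enabled <- character(0)
      if (!is.null(criteria$time_threshold_s)) {
        enabled <- c(enabled, "time")
        if ((frame_index - state$lying_run_start + 1L) / fps >=
            criteria$time_threshold_s)
          fired <- c(fired, "time")
      }
      if (!is.null(criteria$frame_threshold)) {
        enabled <- c(enabled, "frame")
        if (state$lying_run_len >= criteria$frame_threshold)
          fired <- c(fired, "frame")
      }
      if (!is.null(criteria$speed_threshold_frames)) {
        enabled <- c(enabled, "speed")
        if (!is.na(state$last_standing_frame) &&
            (state$lying_run_start - state$last_standing_frame) <=
              criteria$speed_threshold_frames &&
            state$lying_run_len >= criteria$confirm_frames)
          fired <- c(fired, "speed")
      }
      satisfied <- if (criteria$combine_mode == "any") length(fired) > 0
      else length(fired) == length(enabled) && length(enabled) > 0
      if (satisfied) {
        event <- .make_event(state, frame_index, fired)
        state$fall_flagged <- TRUE
      }
    }
  }
  state$last_label <- label
  state$last_frame <- frame_index
  list(state = state, event = event)
}

#' Detect falls over a labeled frame stream
#'
#' Folds [fall_step()] over every track independently (tracks may be
#' interleaved; each track's frames must be in increasing frame order) and
#' collects the emitted events, sorted by trigger frame.
#'
#' @param labels Data frame with columns `track_id`, `frame_index`,
#'   `label` (0 lying / 1 standing).
#' @param criteria A [fall_criteria()].
#' @param fps Frames per second.
#' @return List of `fall_event` objects (possibly empty).
#' @export
detect_falls <- function(labels, criteria = fall_criteria(), fps = 30) {
  need <- c("track_id", "frame_index", "label")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    stop("labels missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  events <- list()
  for (id in unique(labels$track_id)) {
    sel <- labels[labels$track_id == id, , drop = FALSE]
    sel <- sel[order(sel$frame_index), , drop = FALSE]
    state <- new_track_state(id)
    for (r in seq_len(nrow(sel))) {
      out <- fall_step(state, sel$frame_index[r], sel$label[r], criteria, fps)
      state <- out$state
      if (!is.null(out$event)) events[[length(events) + 1L]] <- out$event
    }
  }
  if (length(events))
    events <- events[order(vapply(events, `[[`, 0L, "trigger_frame"))]
  events
}

#' Sequence-level evaluation of fall events
#'
#' Scores detection at the sequence level: a fall sequence with at least
#' one event is a true positive, a non-fall sequence with at least one
#' event a false positive, and so on; precision, recall, F1 and
#' specificity follow from the counts.
#'
#' @param events List of `fall_event`s (as from [detect_falls()]), whose
#'   `track_id`s identify sequences.
#' @param truth Data frame with columns `track_id` and logical `is_fall`,
#'   one row per sequence.
#' @return An `eval_report` (sequence-level).
#' @export
events_to_report <- function(events, truth) {
  if (is.null(truth$track_id) || is.null(truth$is_fall))
    stop("truth needs columns track_id and is_fall", call. = FALSE)
  flagged <- unique(vapply(events, `[[`, "", "track_id"))
  unknown <- setdiff(flagged, as.character(truth$track_id))
  if (length(unknown))
    stop("event track id(s) not in ground truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  has_event <- truth$track_id %in% flagged
  report_from_counts(tp = sum(truth$is_fall & has_event),
                     tn = sum(!truth$is_fall & !has_event),
                     fp = sum(!truth$is_fall & has_event),
                     fn = sum(truth$is_fall & !has_event))
}

#' Write fall events as JSON
#'
#' @param events List of `fall_event`s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  payload <- lapply(events, function(e)
    list(track_id = e$track_id,
         trigger_frame = e$trigger_frame,
         lying_onset_frame = e$lying_onset_frame,
         criterion = as.list(e$criterion),
         transition_duration_frames =
           if (is.na(e$transition_duration_frames)) NULL
           else e$transition_duration_frames))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
                              digits = NA, pretty = TRUE), path)
  invisible(path)
}
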