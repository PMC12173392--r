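# End-to-end orchestration: keypoints -> features -> smoothing ->
# classification -> temporal fall confirmation, driven by a single YAML
# config. Fail-fast validation: unknown keys and invalid sub-configs are
# rejected before any work happens.

.config_keys <- c("preprocess", "augment", "classifier", "criteria",
                  "fps", "paths", "log_level")

#' Assemble a pipeline configuration
#'
#' @param preprocess A [preprocess_config()].
#' @param augment An [augment_config()].
#' @param classifier A [classifier_spec()].
#' @param criteria A [fall_criteria()].
#' @param fps Frames per second of the keypoint stream; required whenever
#'   the time criterion is enabled and frames carry only indices.
#' @param paths Named list of file locations (`keypoints`, `model`,
#'   `features_out`, `labels_out`, `events_out`, `report_out`, `truth` --
#'   all optional at construction, checked at use).
#' @param log_level `"quiet"`, `"info"` or `"verbose-frames"` (the latter
#'   prints the per-frame "Falling Detected" / "No Fall" decision lines).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            augment = augment_config(),
                            classifier = classifier_spec("svm"),
                            criteria = fall_criteria(),
                            fps = 30,
                            paths = list(),
                            log_level = "info") {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(augment, "augment_config"),
            inherits(classifier, "classifier_spec"),
            inherits(criteria, "fall_criteria"))
  if (!is.null(criteria$time_threshold_s) &&
      (!is.numeric(fps) || fps <= 0))
    stop("fps must be positive when the time criterion is enabled",
         call. = FALSE)
  if (!log_level %in% c("quiet", "info", "verbose-frames"))
    stop("log_level must be quiet, info or verbose-frames", call. = FALSE)
  structure(list(preprocess = preprocess, augment = augment,
                 classifier = classifier, criteria = criteria,
                 fps = fps, paths = paths, log_level = log_level),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the constructor arguments under the top-level keys
#' `preprocess`, `augment`, `classifier`, `criteria`, `fps`, `paths`,
#' `log_level`; every key is optional (defaults apply) but unknown keys
#' are rejected. `write_pipeline_config(read_pipeline_config(f))` is
#' idempotent.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  unknown <- setdiff(names(doc), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  crit_args <- doc$criteria %||% list()
  # YAML has no "disabled" marker; absent threshold keys stay at ctor
  # defaults, explicit ~ (null) disables. Map speed key name.
  classifier_args <- doc$classifier %||% list()
  if (!is.null(classifier_args$family)) {
    fam <- classifier_args$family
    classifier_args$family <- NULL
    classifier_args <- c(list(family = fam), classifier_args)
  }
  pipeline_config(
    preprocess = build(preprocess_config, doc$preprocess),
    augment = build(augment_config, doc$augment),
    classifier = build(classifier_spec, classifier_args),
    criteria = build(fall_criteria, crit_args),
    fps = doc$fps %||% 30,
    paths = doc$paths %||% list(),
    log_level = doc$log_level %||% "info")
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @return `write_pipeline_config` returns `path` invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  doc <- list(preprocess = unclass(config$preprocess),
              augment = unclass(config$augment),
              classifier = list(family = config$classifier$family,
                                rng_seed = config$classifier$rng_seed),
              criteria = unclass(config$criteria),
              fps = config$fps, paths = config$paths,
              log_level = config$log_level)
  doc$classifier <- c(doc$classifier, config$classifier$hyperparameters)
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, `verbose-frames` = 2)
  if (levels[[config$log_level]] >= levels[[level]])
    message(paste0(...))
}

#' Run the full detection pipeline
#'
#' Executes extract -> smooth -> resolve-missing -> classify -> temporal
#' detection on a keypoint stream, writing any outputs whose paths are
#' configured (`features_out`, `labels_out`, `events_out`, `report_out`)
#' and returning everything in memory. Stage failures are re-raised with
#' the stage name attached.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param stream A [track_stream()]; if missing, read from
#'   `config$paths$keypoints`.
#' @param model A fitted `posture_model`; if missing, loaded from
#'   `config$paths$model`.
#' @param truth Optional sequence-level ground truth (data frame with
#'   `track_id`, `is_fall`) for a sequence-level [events_to_report()].
#' @return List with `features` (smoothed, resolved table), `labels`
#'   (per-frame data frame), `events`, and `report` (or `NULL`).
#' @export
run_pipeline <- function(config, stream = NULL, model = NULL, truth = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(stream)) {
    if (is.null(config$paths$keypoints))
      stop("no stream given and paths$keypoints not set", call. = FALSE)
    stream <- stage("read", read_keypoint_stream(config$paths$keypoints,
                                                 fps = config$fps))
  }
  if (is.null(model)) {
    if (is.null(config$paths$model))
      stop("no model given and paths$model not set", call. = FALSE)
    model <- stage("load_model", load_model(config$paths$model))
  }
  .log(config, "info", "pipeline: ", length(stream$frames), " frames, ",
       length(track_ids(stream)), " track(s), fps=", config$fps)

  feats <- stage("extract",
                 feature_table(stream,
                               visibility = config$preprocess$visibility_threshold))
  feats <- stage("smooth", smooth_features(feats, config$preprocess))
  feats <- stage("resolve", resolve_missing(feats, config$preprocess))
  if (!is.null(config$paths$features_out))
    write_feature_table(feats, config$paths$features_out)

  pred <- stage("classify", predict(model, feats))
  labels <- data.frame(track_id = feats$track_id,
                       frame_index = feats$frame_index,
                       label = pred, stringsAsFactors = FALSE)
  if (!is.null(config$paths$labels_out))
    utils::write.csv(labels, config$paths$labels_out, row.names = FALSE)
  if (config$log_level == "verbose-frames")
    for (r in seq_len(nrow(labels)))
      message(sprintf("frame=%d track=%s %s", labels$frame_index[r],
                      labels$track_id[r],
                      if (labels$label[r] == 0L) "laydown" else "standing"))

  events <- stage("detect", detect_falls(labels, config$criteria, config$fps))
  for (e in events)
    .log(config, "info", sprintf(
      "Falling Detected: track=%s frame=%d criterion=%s",
      e$track_id, e$trigger_frame, paste(e$criterion, collapse = ",")))
  if (!is.null(config$paths$events_out))
    write_events(events, config$paths$events_out)

  report <- NULL
  if (!is.null(truth)) {
    report <- stage("report", events_to_report(events, truth))
    if (!is.null(config$paths$report_out))
      writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                                  digits = NA, pretty = TRUE, null = "null"),
                 config$paths$report_out)
  }
  list(features = feats, labels = labels, events = events, report = report)
}
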