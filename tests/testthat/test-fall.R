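labels_df <- function(labels, track = "p1", start = 0L) {
  data.frame(track_id = track,
             frame_index = seq_along(labels) - 1L + start,
             label = as.integer(labels), stringsAsFactors = FALSE)
}

test_that("criteria constructor validates", {
  expect_error(fall_criteria(time_threshold_s = NULL), "at least one")
  expect_error(fall_criteria(time_threshold_s = -5), "positive")
  expect_error(fall_criteria(frame_threshold = 0), "positive")
  expect_error(fall_criteria(confirm_frames = 0), "confirm_frames")
})

test_that("frame rule fires exactly at the threshold frame", {
  crit <- fall_criteria(time_threshold_s = NULL, frame_threshold = 200)
  ev <- detect_falls(labels_df(rep(0, 300)), crit, fps = 30)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$trigger_frame, 199L)   # run length hits 200 here
  expect_equal(ev[[1]]$lying_onset_frame, 0L)
  expect_equal(ev[[1]]$criterion, "frame")
  # one frame short: silence
  expect_length(detect_falls(labels_df(rep(0, 199)), crit, 30), 0)
})

test_that("time rule respects the fps conversion", {
  crit <- fall_criteria(time_threshold_s = 5)
  # 149 lying frames at 30 fps is 4.97 s: no event
  ev <- detect_falls(labels_df(c(rep(0, 149), 1)), crit, fps = 30)
  expect_length(ev, 0)
  ev <- detect_falls(labels_df(rep(0, 150)), crit, fps = 30)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$trigger_frame, 149L)
  expect_equal(ev[[1]]$criterion, "time")
  # same sequence at 25 fps crosses 5 s earlier
  ev25 <- detect_falls(labels_df(rep(0, 150)), crit, fps = 25)
  expect_equal(ev25[[1]]$trigger_frame, 124L)
})

test_that("speed rule measures the standing-to-lying transition span", {
  crit <- fall_criteria(time_threshold_s = NULL, speed_threshold_frames = 10,
                        confirm_frames = 15)
  # standing through frame 100, lying from frame 105 (gap frames unseen)
  lab <- rbind(labels_df(rep(1, 101)),
               labels_df(rep(0, 40), start = 105L))
  ev <- detect_falls(lab, crit, fps = 30)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$transition_duration_frames, 5L)
  expect_equal(ev[[1]]$criterion, "speed")
  expect_equal(ev[[1]]$trigger_frame, 119L)   # 15th lying frame confirms

  # slow transition: span 20 > 10, never fires
  slow <- rbind(labels_df(rep(1, 101)), labels_df(rep(0, 40), start = 120L))
  expect_length(detect_falls(slow, crit, fps = 30), 0)

  # flicker shorter than confirm_frames never fires
  flick <- labels_df(c(rep(1, 50), rep(0, 5), rep(1, 50)))
  expect_length(detect_falls(flick, crit, fps = 30), 0)
})

test_that("combine_mode all needs every enabled rule at once", {
  both <- fall_criteria(time_threshold_s = 2, frame_threshold = 100,
                        combine_mode = "all")
  # at 30 fps the time rule is met at run length 60, the frame rule at 100
  ev <- detect_falls(labels_df(rep(0, 120)), both, fps = 30)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$trigger_frame, 99L)
  expect_setequal(ev[[1]]$criterion, c("time", "frame"))
  expect_length(detect_falls(labels_df(rep(0, 99)), both, fps = 30), 0)
})

test_that("exactly one event per lying run; standing resets the flag", {
  crit <- fall_criteria(time_threshold_s = NULL, frame_threshold = 10)
  ev <- detect_falls(labels_df(rep(0, 500)), crit, 30)
  expect_length(ev, 1)
  # two separate runs give two events
  lab <- labels_df(c(rep(0, 20), rep(1, 5), rep(0, 20)))
  ev2 <- detect_falls(lab, crit, 30)
  expect_length(ev2, 2)
  expect_equal(vapply(ev2, `[[`, 0L, "lying_onset_frame"), c(0L, 25L))
})

test_that("monotonicity: longer runs never lose events, short runs stay silent", {
  crit <- fall_criteria(time_threshold_s = NULL, frame_threshold = 50)
  set.seed(31)
  for (i in 1:25) {
    run <- sample(1:120, 1)
    ev <- detect_falls(labels_df(c(rep(1, 3), rep(0, run))), crit, 30)
    expect_length(ev, if (run >= 50) 1 else 0)
    if (run >= 50) {
      longer <- detect_falls(labels_df(c(rep(1, 3), rep(0, run + 40))),
                             crit, 30)
      expect_length(longer, 1)
      expect_equal(longer[[1]]$trigger_frame, ev[[1]]$trigger_frame)
    }
  }
})

test_that("time/frame duality over random label sequences", {
  fps <- 30
  time_crit <- fall_criteria(time_threshold_s = 2)
  frame_crit <- fall_criteria(time_threshold_s = NULL,
                              frame_threshold = 2 * fps)
  set.seed(32)
  for (i in 1:500) {
    lab <- labels_df(sample(0:1, 200, replace = TRUE, prob = c(0.6, 0.4)))
    et <- detect_falls(lab, time_crit, fps)
    ef <- detect_falls(lab, frame_crit, fps)
    expect_equal(vapply(et, `[[`, 0L, "trigger_frame"),
                 vapply(ef, `[[`, 0L, "trigger_frame"))
  }
})

test_that("tracks are isolated: interleaving order is irrelevant", {
  crit <- fall_criteria(time_threshold_s = NULL, frame_threshold = 30)
  a <- labels_df(rep(0, 60), "a")
  b <- labels_df(rep(1, 60), "b")
  c1 <- labels_df(c(rep(1, 20), rep(0, 40)), "c")
  whole <- rbind(a, b, c1)
  set.seed(33)
  shuffled <- whole[sample(nrow(whole)), ]
  ev1 <- detect_falls(whole, crit, 30)
  ev2 <- detect_falls(shuffled, crit, 30)
  key <- function(evs) lapply(evs, function(e)
    list(e$track_id, e$trigger_frame, e$criterion))
  expect_equal(key(ev1), key(ev2))
  expect_setequal(vapply(ev1, `[[`, "", "track_id"), c("a", "c"))
})

test_that("gap handling: short gaps keep the run, long gaps reset", {
  crit <- fall_criteria(time_threshold_s = NULL, frame_threshold = 50,
                        gap_tolerance = 30)
  # 20 lying, 10-frame gap, 30 more lying: index span keeps counting
  lab <- rbind(labels_df(rep(0, 20)), labels_df(rep(0, 30), start = 30L))
  ev <- detect_falls(lab, crit, 30)
  expect_length(ev, 1)         # observed run length reaches 50
  # a gap beyond tolerance resets state: only 45 observed frames after it
  lab2 <- rbind(labels_df(rep(0, 20)), labels_df(rep(0, 45), start = 100L))
  expect_length(detect_falls(lab2, crit, 30), 0)
})

test_that("step API rejects non-monotonic frames and bad labels", {
  st <- new_track_state("x")
  out <- fall_step(st, 5, 0, fall_criteria(), 30)
  expect_error(fall_step(out$state, 5, 0, fall_criteria(), 30),
               "non-monotonic")
  expect_error(fall_step(out$state, 6, 2, fall_criteria(), 30), "label")
})

test_that("events_to_report scores at the sequence level", {
  mk_ev <- function(id) structure(list(track_id = id, trigger_frame = 10L,
                                       lying_onset_frame = 0L,
                                       criterion = "time",
                                       transition_duration_frames = NA_integer_),
                                  class = "fall_event")
  truth <- data.frame(track_id = c(paste0("fall", 1:10), paste0("adl", 1:10)),
                      is_fall = rep(c(TRUE, FALSE), each = 10))
  r <- events_to_report(lapply(paste0("fall", 1:10), mk_ev), truth)
  expect_equal(c(r$precision, r$recall, r$specificity), c(1, 1, 1))

  # one missed fall, no false alarms
  r2 <- events_to_report(lapply(paste0("fall", 1:9), mk_ev), truth)
  expect_equal(r2$recall, 0.9)

  # TP=16 FN=1 FP=2 TN=43 -> specificity 43/45
  truth3 <- data.frame(track_id = c(paste0("f", 1:17), paste0("n", 1:45)),
                       is_fall = rep(c(TRUE, FALSE), c(17, 45)))
  ev3 <- lapply(c(paste0("f", 1:16), paste0("n", 1:2)), mk_ev)
  r3 <- events_to_report(ev3, truth3)
  expect_equal(unlist(r3[c("tp", "fn", "fp", "tn")]),
               c(tp = 16, fn = 1, fp = 2, tn = 43))
  expect_equal(r3$specificity, 43 / 45)
  expect_equal(round(r3$specificity, 3), 0.956)

  expect_error(events_to_report(list(mk_ev("ghost")), truth), "ghost")
})
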