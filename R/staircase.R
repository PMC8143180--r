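# Adaptive assessment of recognition span and required fixation time.
#
# The staircase starts at 4-letter pseudowords shown for 250 ms.  A list
# passes when at least 19 of its 20 items are read correctly (the 95%
# criterion).  Failing lists first earn 50 ms more presentation time up to
# 500 ms; failing at 500 ms drops the word length by one and restarts the
# time ladder.  Passing at the shortest time before any demotion promotes
# the length by one; any other pass terminates and fixes the reader's
# profile at the current (length, time) pair.

#' Assessment configuration
#'
#' @param list_size items per stimulus list (default 20).
#' @param pass_threshold correct items required to pass (default 19, the
#'   95% criterion on a 20-item list).
#' @param time_step_ms presentation-time increment (default 50).
#' @param time_min_ms,time_max_ms presentation-time grid bounds
#'   (defaults 250 and 500; temporal summation is effective up to ~500 ms).
#' @param length_min,length_max word-length bounds (defaults 2 and 6).
#' @param tone_ms delay of the go-signal tone after stimulus onset
#'   (default 700); responses must not start before the tone.
#' @param max_lists budget of list administrations per assessment
#'   (default 30, bounding the session length).
#' @param inter_trial_s allowed pause range between trials, seconds
#'   (metadata only).
#' @return list of class `assessment_config`.
#' @export
assessment_config <- function(list_size = 20L, pass_threshold = 19L,
                              time_step_ms = 50L, time_min_ms = 250L,
                              time_max_ms = 500L, length_min = 2L,
                              length_max = 6L, tone_ms = 700L,
                              max_lists = 30L, inter_trial_s = c(5, 10)) {
  if (pass_threshold > list_size) {
    stop("`pass_threshold` cannot exceed `list_size`", call. = FALSE)
  }
  structure(list(list_size = as.integer(list_size),
                 pass_threshold = as.integer(pass_threshold),
                 time_step_ms = as.integer(time_step_ms),
                 time_min_ms = as.integer(time_min_ms),
                 time_max_ms = as.integer(time_max_ms),
                 length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 tone_ms = as.integer(tone_ms),
                 max_lists = as.integer(max_lists),
                 inter_trial_s = inter_trial_s),
            class = "assessment_config")
}

#' Initial staircase state
#'
#' The first list always uses 4-letter pseudowords at 250 ms, regardless of
#' the configured length bounds.
#'
#' @param config an [assessment_config()].
#' @return list of class `staircase_state` with fields `length`,
#'   `presentation_ms`, `demoted_once`, `lists_used`, `history`,
#'   `terminated`, `profile`.
#' @export
initial_state <- function(config = assessment_config()) {
  structure(list(length = 4L, presentation_ms = config$time_min_ms,
                 demoted_once = FALSE, lists_used = 0L,
                 history = list(), terminated = FALSE, profile = NULL,
                 config = config),
            class = "staircase_state")
}

#' Advance the staircase after one scored list
#'
#' Transition rules, with `pass` meaning `n_correct >= pass_threshold`:
#' * pass at the minimum time, before any demotion, below the maximum
#'   length: promote length by one, keep the minimum time;
#' * any other pass (longer time, after a demotion, or at the maximum
#'   length): terminate; the profile is the current (length, time);
#' * fail below the maximum time: add one time step at the same length;
#' * fail at the maximum time above the minimum length: demote length by
#'   one, reset the time ladder, latch `demoted_once`;
#' * fail at the maximum time at the minimum length: terminate at the
#'   floor (minimum length, maximum time) with `at_floor` set.
#'
#' @param state a `staircase_state`.
#' @param n_correct number of correctly read items in the list.
#' @return updated `staircase_state`.
#' @export
update_state <- function(state, n_correct) {
  cfg <- state$config
  if (state$terminated) stop("staircase already terminated", call. = FALSE)
  assert_scalar_number(n_correct, "n_correct", 0, cfg$list_size)
  state$lists_used <- state$lists_used + 1L
  state$history[[length(state$history) + 1L]] <-
    list(length = state$length, presentation_ms = state$presentation_ms,
         n_correct = as.integer(n_correct))
  pass <- n_correct >= cfg$pass_threshold
  if (pass) {
    if (state$presentation_ms == cfg$time_min_ms && !state$demoted_once &&
        state$length < cfg$length_max) {
      state$length <- state$length + 1L
    } else {
      state$terminated <- TRUE
      state$profile <- reader_profile(
        span = state$length, fixation_time_ms = state$presentation_ms,
        at_ceiling = state$length == cfg$length_max && !state$demoted_once)
    }
  } else {
    if (state$presentation_ms < cfg$time_max_ms) {
      state$presentation_ms <- state$presentation_ms + cfg$time_step_ms
    } else if (state$length > cfg$length_min) {
      state$length <- state$length - 1L
      state$presentation_ms <- cfg$time_min_ms
      state$demoted_once <- TRUE
    } else {
      state$terminated <- TRUE
      state$profile <- reader_profile(
        span = cfg$length_min, fixation_time_ms = cfg$time_max_ms,
        at_floor = TRUE)
    }
  }
  state
}

#' Reader profile
#'
#' The outcome of an assessment: the number of letters the reader can
#' recognize simultaneously and the presentation (fixation) time needed to
#' do so at the 95% criterion.
#'
#' @param span letters recognized simultaneously.
#' @param fixation_time_ms required presentation time, ms.
#' @param speech_onset_mean_ms mean latency from stimulus onset to speech
#'   onset, ms (optional).
#' @param at_floor,at_ceiling flags marking termination at the grid floor
#'   (failed even the easiest condition) or ceiling.
#' @param budget_exhausted `TRUE` when the list budget ran out before a
#'   pass.
#' @return list of class `reader_profile`.
#' @export
reader_profile <- function(span, fixation_time_ms,
                           speech_onset_mean_ms = NA_real_,
                           at_floor = FALSE, at_ceiling = FALSE,
                           budget_exhausted = FALSE) {
  structure(list(span = as.integer(span),
                 fixation_time_ms = as.integer(fixation_time_ms),
                 speech_onset_mean_ms = as.numeric(speech_onset_mean_ms),
                 at_floor = at_floor, at_ceiling = at_ceiling,
                 budget_exhausted = budget_exhausted),
            class = "reader_profile")
}

#' Mean speech-onset latency over trials
#'
#' @param trials list of trial records, each with a `speech_onset_ms`
#'   field, or a numeric vector of latencies.
#' @return arithmetic mean latency in ms.
#' @export
estimate_speech_onset <- function(trials) {
  onsets <- if (is.numeric(trials)) trials else
    vapply(trials, `[[`, 0, "speech_onset_ms")
  if (length(onsets) == 0L) stop("no trials supplied", call. = FALSE)
  mean(onsets)
}

#' Run a full adaptive assessment against a synthetic reader
#'
#' Repeatedly generates a fresh stimulus list for the current condition,
#' simulates all trials with the reader model, scores the list, and steps
#' the staircase until termination or until the list budget is exhausted.
#' The profile's speech-onset mean is taken over the trials of the terminal
#' condition.
#'
#' @param reader [sim_reader_params()] describing the synthetic reader.
#' @param config an [assessment_config()].
#' @param seed integer master seed for stimulus and response sampling.
#' @return list with `profile` (a `reader_profile`) and `trials` (data
#'   frame log: list_index, length, presentation_ms, target, response,
#'   correct, speech_onset_ms).
#' @export
run_assessment <- function(reader, config = assessment_config(), seed = 1L) {
  state <- initial_state(config)
  logs <- list()
  best_pass <- NULL
  while (!state$terminated && state$lists_used < config$max_lists) {
    list_index <- state$lists_used + 1L
    stim <- generate_list(state$length, config$list_size,
                          seed = derive_seed(seed, list_index * 2L))
    cond <- list(length = state$length, presentation_ms = state$presentation_ms)
    trials <- with_seed(derive_seed(seed, list_index * 2L + 1L), {
      lapply(stim$items, function(w) {
        simulate_pseudoword_trial(cond, w, reader, tone_ms = config$tone_ms)
      })
    })
    n_correct <- sum(vapply(trials, `[[`, TRUE, "correct"))
    logs[[list_index]] <- data.frame(
      list_index = list_index, length = cond$length,
      presentation_ms = cond$presentation_ms,
      target = vapply(trials, `[[`, "", "target"),
      response = vapply(trials, `[[`, "", "response"),
      correct = vapply(trials, `[[`, TRUE, "correct"),
      speech_onset_ms = vapply(trials, `[[`, 0, "speech_onset_ms"),
      stringsAsFactors = FALSE
    )
    if (n_correct >= config$pass_threshold) {
      best_pass <- cond
    }
    state <- update_state(state, n_correct)
  }
  trial_log <- do.call(rbind, logs)
  if (!state$terminated) {
    # budget exhausted: fall back to the best passing condition seen
    prof <- if (!is.null(best_pass)) {
      reader_profile(best_pass$length, best_pass$presentation_ms,
                     budget_exhausted = TRUE)
    } else {
      reader_profile(state$length, state$presentation_ms,
                     budget_exhausted = TRUE)
    }
  } else {
    prof <- state$profile
  }
  terminal <- trial_log$length == prof$span &
    trial_log$presentation_ms == prof$fixation_time_ms
  prof$speech_onset_mean_ms <- if (any(terminal)) {
    mean(trial_log$speech_onset_ms[terminal])
  } else {
    mean(trial_log$speech_onset_ms)
  }
  list(profile = prof, trials = trial_log, state = state)
}
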