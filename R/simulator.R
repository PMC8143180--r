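# Synthetic reader model.
#
# Recognition of a letter string is governed by temporal summation: the
# probability of recognizing n letters in one fixation rises with fixation
# time t.  Each reader has a true simultaneous-recognition span s* and a
# threshold fixation time T*; strings longer than the span need extra time
# per additional letter (and quickly become unrecognizable), shorter
# strings need less, down to a 150 ms floor.  Failed recognitions produce
# letter errors whose positions are graded from left to right, emulating
# the rising per-position misread rates observed empirically.

#' Parameters of a synthetic reader
#'
#' @param true_span s*: letters recognizable simultaneously (1-8).
#' @param threshold_time_ms T*: fixation time needed to recognize a
#'   `true_span`-letter string, ms.
#' @param slope psychometric steepness per ms; `Inf` gives a deterministic
#'   threshold reader (recognition iff `t >= tau(n)`).
#' @param p_at_threshold recognition probability of a span-sized string at
#'   exactly the threshold time for finite slopes (default 0.99; must stay
#'   at or above 0.95, the pass criterion the thresholds are defined by).
#' @param extra_letter_cost_ms extra threshold time per letter beyond the
#'   span (default 300; with this cost, strings one letter over the span
#'   stay unrecognizable anywhere on the 250-500 ms grid, while strings
#'   under the span need no more than the minimum time).
#' @param attempted_span letters the reader tries to take in per fixation
#'   in free reading; values above `true_span` leave unrecognized gap
#'   letters that can only be guessed.
#' @param premature_speech_p probability that a free-reading fixation is
#'   cut short (saccade/speech initiated too early).
#' @param regression_rate per-chunk probability of a backward saccade in
#'   free reading.
#' @param position_gradient g >= 0; victim positions for letter errors are
#'   drawn with weights 1 + g * (i-1)/(len-1), so larger g concentrates
#'   errors toward the word end.
#' @param error_mixture named probabilities over omission, substitution,
#'   transposition, addition; must sum to 1.
#' @param guess_p probability that an unrecognized gap letter is guessed
#'   correctly (about 1/alphabet-size for pseudowords; substantially
#'   higher for meaningful text).
#' @param duration_factor,duration_cv free-reading fixation durations are
#'   `T* * duration_factor * exp(rnorm(1, 0, duration_cv))`; premature
#'   fixations instead use `T* * runif(1, 0.5, 0.9)`.
#' @param compliance_lapse_p per-segment probability of a compliance lapse
#'   (regression) in guided reading.
#' @param retrieval_mean_ms,retrieval_sd_ms distribution of the time to
#'   retrieve the phoneme sequence from memory.
#' @param reaction_mean_ms mean of the exponential reaction delay added
#'   after the go signal.
#' @param age_months,id,group optional cohort metadata.
#' @return list of class `sim_reader_params`.
#' @export
sim_reader_params <- function(true_span = 4L, threshold_time_ms = 300,
                              slope = Inf, p_at_threshold = 0.99,
                              extra_letter_cost_ms = 300,
                              attempted_span = true_span,
                              premature_speech_p = 0,
                              regression_rate = 0,
                              position_gradient = 1,
                              error_mixture = c(omission = 0.40,
                                                substitution = 0.35,
                                                transposition = 0.15,
                                                addition = 0.10),
                              guess_p = 0.05,
                              duration_factor = 1.2, duration_cv = 0.1,
                              compliance_lapse_p = 0,
                              retrieval_mean_ms = 1400,
                              retrieval_sd_ms = 500,
                              reaction_mean_ms = 50,
                              age_months = NA_real_, id = NA_character_,
                              group = NA_character_) {
  params <- as.list(environment())
  assert_scalar_number(true_span, "true_span", 1, 8)
  assert_scalar_number(attempted_span, "attempted_span", 1, 12)
  assert_scalar_number(threshold_time_ms, "threshold_time_ms", 1)
  for (p in c(premature_speech_p, regression_rate, guess_p, compliance_lapse_p)) {
    assert_scalar_number(p, "probability", 0, 1)
  }
  assert_scalar_number(p_at_threshold, "p_at_threshold", 0.95, 1 - 1e-12)
  if (abs(sum(error_mixture) - 1) > 1e-8 || any(error_mixture < 0)) {
    stop("`error_mixture` must be nonnegative and sum to 1", call. = FALSE)
  }
  req <- c("omission", "substitution", "transposition", "addition")
  if (!all(names(error_mixture) %in% req)) {
    stop("`error_mixture` names must be among ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  assert_scalar_number(position_gradient, "position_gradient", 0)
  structure(params, class = "sim_reader_params")
}

# Threshold fixation time for an n-letter string.
tau_threshold <- function(n, params) {
  s <- params$true_span
  k <- params$extra_letter_cost_ms
  if (n >= s) params$threshold_time_ms + k * (n - s)
  else max(150, params$threshold_time_ms - k * (s - n))
}

#' Probability of recognizing an n-letter string in one fixation of t ms
#'
#' `p = logistic(slope * (t - tau(n)) + logit(p0))` with
#' `tau(n) = T* + cost * (n - s*)` for strings at or beyond the span,
#' `tau(n) = max(150, T* - cost * (s* - n))` below it, and `p0` the
#' calibration constant `p_at_threshold`: by construction the reader
#' recognizes span-sized strings at the threshold time with probability
#' `p0` (default 0.99, consistent with passing the 19-of-20 criterion
#' there).  An infinite slope yields the step function (recognition iff
#' `t >= tau(n)`).  The probability is nondecreasing in `t` and
#' nonincreasing in `n`.
#'
#' @param n letters in the string (>= 1).
#' @param t fixation time in ms (> 0).
#' @param params a [sim_reader_params()].
#' @return probability in \[0, 1\].
#' @export
recognition_probability <- function(n, t, params) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.numeric(t) || t <= 0) stop("`t` must be positive", call. = FALSE)
  tau <- tau_threshold(n, params)
  if (is.infinite(params$slope)) as.numeric(t >= tau)
  else stats::plogis(params$slope * (t - tau) +
                       stats::qlogis(params$p_at_threshold))
}

sim_alphabet <- function() unlist(default_alphabet(), use.names = FALSE)

#' Corrupt a word that failed recognition
#'
#' Applies at least one letter error drawn from the reader's error mixture
#' to a victim position drawn with left-to-right graded weights
#' `1 + position_gradient * (i-1)/(len-1)`.  The response always differs
#' from the target.
#'
#' @param target word that failed to be recognized.
#' @param params a [sim_reader_params()].
#' @return corrupted response string.
#' @export
corrupt_word <- function(target, params) {
  len <- nchar(target)
  alphabet <- sim_alphabet()
  weights <- if (len == 1L) 1 else
    1 + params$position_gradient * (seq_len(len) - 1) / (len - 1)
  mixture <- params$error_mixture
  for (attempt in 1:25) {
    chars <- strsplit(target, "")[[1]]
    kind <- sample(names(mixture), 1L, prob = mixture)
    victim <- sample.int(len, 1L, prob = weights)
    if (kind == "transposition" && len < 2L) kind <- "substitution"
    response <- switch(
      kind,
      omission = paste(chars[-victim], collapse = ""),
      substitution = {
        chars[victim] <- sample(setdiff(alphabet, chars[victim]), 1L)
        paste(chars, collapse = "")
      },
      transposition = {
        v <- min(victim, len - 1L)
        chars[c(v, v + 1L)] <- chars[c(v + 1L, v)]
        paste(chars, collapse = "")
      },
      addition = {
        extra <- sample(alphabet, 1L)
        paste(c(chars[seq_len(victim)], extra,
                if (victim < len) chars[(victim + 1L):len]), collapse = "")
      }
    )
    if (!identical(response, target)) return(response)
  }
  # degenerate mixtures (e.g. pure transposition of a repeated pair):
  # fall back to dropping the final letter
  substr(target, 1, len - 1L)
}

#' Simulate a single pseudoword trial
#'
#' Recognition succeeds with [recognition_probability()] at the trial's
#' length and presentation time; failures produce a corrupted response.
#' The speech onset is the phoneme-retrieval time, but never before the
#' go-signal tone, plus a reaction delay.
#'
#' @param condition list with `length` and `presentation_ms`.
#' @param target the presented pseudoword.
#' @param params a [sim_reader_params()].
#' @param tone_ms go-signal delay after stimulus onset (default 700 ms).
#' @return list with `target`, `response`, `correct`, `speech_onset_ms`.
#' @export
simulate_pseudoword_trial <- function(condition, target, params,
                                      tone_ms = 700) {
  p <- recognition_probability(condition$length, condition$presentation_ms,
                               params)
  correct <- stats::runif(1) < p
  response <- if (correct) target else corrupt_word(target, params)
  retrieval <- max(0, stats::rnorm(1, params$retrieval_mean_ms,
                                   params$retrieval_sd_ms))
  onset <- max(retrieval, tone_ms) +
    stats::rexp(1, 1 / params$reaction_mean_ms)
  list(target = target, response = response, correct = correct,
       speech_onset_ms = onset)
}

# Sample one free-reading fixation duration.
free_duration <- function(params) {
  if (stats::runif(1) < params$premature_speech_p) {
    params$threshold_time_ms * stats::runif(1, 0.5, 0.9)
  } else {
    params$threshold_time_ms * params$duration_factor *
      exp(stats::rnorm(1, 0, params$duration_cv))
  }
}

#' Simulate free (unguided) reading of a text
#'
#' The reader advances through each word in chunks of `attempted_span`
#' letters with self-chosen fixation durations.  The first
#' `min(true_span, chunk)` letters of a chunk are recognized with the
#' temporal-summation probability at the sampled duration; letters in the
#' gap between the recognized prefix and the next fixation are guessed
#' correctly with probability `guess_p`.  Backward saccades (regressions)
#' are interspersed with `regression_rate` and cost extra time without
#' changing the outcome.
#'
#' @param text a [text_material()] (or any object with a `words` field).
#' @param params a [sim_reader_params()].
#' @param seed optional integer seed.
#' @return object of class `session_log`: list with `outcomes` (one
#'   [classify_response()] outcome per word), `fixations` (data frame:
#'   t_start_ms, duration_ms, offset), `saccades` (signed character
#'   amplitudes), `speech_onsets_ms`, `n_words`, `n_errors`,
#'   `total_time_s`, `mode = "free"`.
#' @export
simulate_free_reading <- function(text, params, seed = NULL) {
  with_seed(seed, {
    words <- text$words
    alphabet <- sim_alphabet()
    outcomes <- vector("list", length(words))
    fix_t <- fix_dur <- fix_off <- numeric(0)
    onsets <- numeric(length(words))
    t_now <- 0
    word_offset <- 0
    for (wi in seq_along(words)) {
      word <- words[[wi]]
      len <- nchar(word)
      pos <- 1L
      parts <- character(0)
      while (pos <= len) {
        chunk_len <- min(params$attempted_span, len - pos + 1L)
        duration <- free_duration(params)
        prefix_len <- min(params$true_span, chunk_len)
        p <- recognition_probability(prefix_len, duration, params)
        prefix <- substr(word, pos, pos + prefix_len - 1L)
        parts <- c(parts, if (stats::runif(1) < p) prefix else
          corrupt_word(prefix, params))
        gap <- chunk_len - prefix_len
        if (gap > 0L) {
          gap_chars <- strsplit(substr(word, pos + prefix_len,
                                       pos + chunk_len - 1L), "")[[1]]
          guessed <- stats::runif(gap) < params$guess_p
          for (gi in which(!guessed)) {   # a failed guess is always wrong
            gap_chars[gi] <- sample(setdiff(alphabet, gap_chars[gi]), 1L)
          }
          parts <- c(parts, paste(gap_chars, collapse = ""))
        }
        offset <- word_offset + pos - 1L + (chunk_len %/% 2L)
        fix_t <- c(fix_t, t_now); fix_dur <- c(fix_dur, duration)
        fix_off <- c(fix_off, offset)
        t_now <- t_now + duration + 30   # saccade latency
        if (stats::runif(1) < params$regression_rate) {
          back <- max(0, offset - params$true_span)
          rdur <- stats::runif(1, 100, 250)
          fix_t <- c(fix_t, t_now); fix_dur <- c(fix_dur, rdur)
          fix_off <- c(fix_off, back)
          t_now <- t_now + rdur + 30
          # return fixation to the reading position
          fix_t <- c(fix_t, t_now); fix_dur <- c(fix_dur, 80)
          fix_off <- c(fix_off, offset)
          t_now <- t_now + 80 + 30
        }
        pos <- pos + chunk_len
      }
      response <- paste(parts, collapse = "")
      outcomes[[wi]] <- classify_response(word, response)
      speech <- 120 * len    # pronunciation, ~120 ms per letter
      onsets[wi] <- t_now
      t_now <- t_now + speech
      word_offset <- word_offset + len + 1L   # single inter-word space
    }
    n_errors <- sum(!vapply(outcomes, `[[`, TRUE, "correct"))
    structure(list(
      outcomes = outcomes,
      fixations = data.frame(t_start_ms = fix_t, duration_ms = fix_dur,
                             offset = fix_off),
      saccades = diff(fix_off),
      speech_onsets_ms = onsets,
      n_words = length(words), n_errors = n_errors,
      total_time_s = t_now / 1000, mode = "free", seed = seed
    ), class = "session_log")
  })
}

#' Simulate computer-guided reading of a prepared guidance script
#'
#' Fixations follow the script's offsets and planned durations, so every
#' segment receives at least the profiled fixation time; recognition per
#' segment uses the temporal-summation probability at the planned
#' duration.  A failed segment is repeated once before the script
#' advances.  Speech for a segment never starts before its tone plus the
#' minimum reaction time.  Regressions occur only through compliance
#' lapses, which also spoil the lapsed segment's pronunciation.
#'
#' @param script a [build_script()] result.
#' @param params a [sim_reader_params()]; if any script segment is longer
#'   than the reader's true span the log is flagged with
#'   `span_mismatch = TRUE`.
#' @param seed optional integer seed.
#' @return a `session_log` (see [simulate_free_reading()]) with
#'   `mode = "guided"`.
#' @export
simulate_guided_reading <- function(script, params, seed = NULL) {
  with_seed(seed, {
    segs <- script$segments
    cfg <- script$config
    duration <- script$planned_fixation_ms
    mismatch <- any(segs$length > params$true_span)
    n_words <- max(segs$word_index)
    word_parts <- rep("", n_words)
    fix_t <- fix_dur <- fix_off <- numeric(0)
    onsets <- numeric(nrow(segs))
    t_now <- 0
    for (si in seq_len(nrow(segs))) {
      seg_len <- segs$length[si]
      target <- substr(script$line, segs$absolute_start[si] + 1L,
                       segs$absolute_start[si] + seg_len)
      attempts <- 1L
      p <- recognition_probability(seg_len, duration, params)
      lapse <- stats::runif(1) < params$compliance_lapse_p
      # a compliance lapse (stray regression, mistimed speech) spoils the
      # segment outright; otherwise a failed segment is retried once
      ok <- !lapse && stats::runif(1) < p
      if (!ok && !lapse) {
        attempts <- 2L
        ok <- stats::runif(1) < p
      }
      piece <- if (ok) target else corrupt_word(target, params)
      word_parts[segs$word_index[si]] <-
        paste0(word_parts[segs$word_index[si]], piece)
      for (a in seq_len(attempts)) {
        fix_t <- c(fix_t, t_now); fix_dur <- c(fix_dur, duration)
        fix_off <- c(fix_off, segs$fixation_offset[si])
        # cursor move -> tone (1 s) -> speech window (reaction) -> speech
        onset <- t_now + cfg$tone_after_move_ms + cfg$reaction_ms +
          stats::rexp(1, 1 / params$reaction_mean_ms)
        t_now <- onset + cfg$pronounce_ms
      }
      if (lapse) {                     # compliance lapse: brief regression
        back <- max(0, segs$fixation_offset[si] - params$true_span)
        rdur <- stats::runif(1, 100, 250)
        fix_t <- c(fix_t, t_now); fix_dur <- c(fix_dur, rdur)
        fix_off <- c(fix_off, back)
        t_now <- t_now + rdur
        fix_t <- c(fix_t, t_now); fix_dur <- c(fix_dur, 80)
        fix_off <- c(fix_off, segs$fixation_offset[si])
        t_now <- t_now + 80
      }
      onsets[si] <- onset
    }
    words <- script$words
    outcomes <- lapply(seq_len(n_words), function(wi) {
      classify_response(words[[wi]], word_parts[[wi]])
    })
    n_errors <- sum(!vapply(outcomes, `[[`, TRUE, "correct"))
    structure(list(
      outcomes = outcomes,
      fixations = data.frame(t_start_ms = fix_t, duration_ms = fix_dur,
                             offset = fix_off),
      saccades = diff(fix_off),
      speech_onsets_ms = onsets,
      n_words = n_words, n_errors = n_errors,
      total_time_s = t_now / 1000, mode = "guided",
      span_mismatch = mismatch, seed = seed
    ), class = "session_log")
  })
}

#' Write a session log's word outcomes and fixations to delimited files
#'
#' @param log a `session_log`.
#' @param path base path; `<path>_words.csv` and `<path>_fixations.csv`
#'   are written.
#' @export
write_session_log <- function(log, path) {
  write_outcomes(log$outcomes, paste0(path, "_words.csv"))
  utils::write.csv(log$fixations, paste0(path, "_fixations.csv"),
                   row.names = FALSE)
  invisible(path)
}
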