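test_that("recognition probability is a step function for threshold readers", {
  r <- threshold_reader(4, 350)
  expect_identical(recognition_probability(4, 350, r), 1)
  expect_identical(recognition_probability(4, 349, r), 0)
  # one letter over the span exceeds the whole time grid
  expect_identical(recognition_probability(5, 500, r), 0)
  # strings under the span pass at the grid minimum
  expect_identical(recognition_probability(3, 250, r), 1)
})

test_that("recognition probability is monotone in time and length", {
  for (slope in c(0.05, 0.25, Inf)) {
    r <- sim_reader_params(true_span = 4, threshold_time_ms = 350,
                           slope = slope)
    grid_t <- seq(150, 600, 50)
    for (n in 2:8) {
      p <- vapply(grid_t, function(t) recognition_probability(n, t, r), 0)
      expect_true(all(diff(p) >= 0), info = paste(slope, n))
    }
    for (t in grid_t) {
      p <- vapply(2:8, function(n) recognition_probability(n, t, r), 0)
      expect_true(all(diff(p) <= 0), info = paste(slope, t))
    }
  }
})

test_that("finite-slope readers stay calibrated at their threshold", {
  r <- sim_reader_params(true_span = 4, threshold_time_ms = 350, slope = 0.2)
  expect_equal(recognition_probability(4, 350, r), 0.99, tolerance = 1e-10)
})

test_that("corruption always changes the word as drawn from the mixture", {
  omitter <- sim_reader_params(error_mixture = c(omission = 1, substitution = 0,
                                                 transposition = 0, addition = 0))
  set.seed(41)
  for (i in 1:50) {
    resp <- corrupt_word("belor", omitter)
    expect_lt(nchar(resp), 5)
  }
  mixed <- sim_reader_params()
  for (i in 1:100) {
    target <- generate_pseudoword(4)$letters
    expect_false(identical(corrupt_word(target, mixed), target))
  }
})

test_that("victim positions follow the configured gradient", {
  set.seed(42)
  flat <- sim_reader_params(position_gradient = 0,
                            error_mixture = c(omission = 0, substitution = 1,
                                              transposition = 0, addition = 0))
  hits <- integer(5)
  n_draw <- 10000
  for (i in seq_len(n_draw)) {
    resp <- corrupt_word("aaaaa", flat)
    hits[which(strsplit(resp, "")[[1]] != "a")] <-
      hits[which(strsplit(resp, "")[[1]] != "a")] + 1L
  }
  # uniform victim draw: chi-square GOF should not reject
  expect_gt(stats::chisq.test(hits)$p.value, 0.001)

  graded <- sim_reader_params(position_gradient = 2,
                              error_mixture = c(omission = 0, substitution = 1,
                                                transposition = 0, addition = 0))
  hits2 <- integer(5)
  for (i in seq_len(n_draw)) {
    resp <- corrupt_word("aaaaa", graded)
    hits2[which(strsplit(resp, "")[[1]] != "a")] <-
      hits2[which(strsplit(resp, "")[[1]] != "a")] + 1L
  }
  expect_true(all(diff(hits2) > 0))
})

test_that("pseudoword trials respect the threshold and the tone floor", {
  r <- threshold_reader(3, 400)
  set.seed(7)
  below <- replicate(30, simulate_pseudoword_trial(
    list(length = 3, presentation_ms = 350), "mul", r)$correct)
  expect_false(any(below))
  onsets <- replicate(50, simulate_pseudoword_trial(
    list(length = 3, presentation_ms = 400), "mul", r)$speech_onset_ms)
  expect_true(all(onsets >= 700))
})

test_that("list pass rates track the recognition probability", {
  r <- sim_reader_params(true_span = 4, threshold_time_ms = 300, slope = 0.05)
  p <- recognition_probability(4, 300, r)
  set.seed(13)
  correct <- replicate(400, simulate_pseudoword_trial(
    list(length = 4, presentation_ms = 300),
    "belo", r)$correct)
  expect_lt(abs(mean(correct) - p), 0.03)
})

test_that("well-calibrated free reading makes no errors", {
  r <- sim_reader_params(true_span = 4, threshold_time_ms = 300,
                         attempted_span = 4, premature_speech_p = 0,
                         duration_cv = 0, duration_factor = 1.1,
                         regression_rate = 0)
  text <- text_part(study_texts()[[1]], 1)
  log <- simulate_free_reading(text, r, seed = 5)
  expect_identical(log$n_errors, 0L)
  expect_identical(log$n_words, 29L)
  expect_gte(log$total_time_s, sum(log$fixations$duration_ms) / 1000)
})

test_that("overreaching without guessing fails every word beyond the span", {
  r <- sim_reader_params(true_span = 3, threshold_time_ms = 300,
                         attempted_span = 7, guess_p = 0,
                         premature_speech_p = 0, duration_cv = 0,
                         duration_factor = 1.1, regression_rate = 0)
  text <- text_part(study_texts()[[2]], 1)
  log <- simulate_free_reading(text, r, seed = 9)
  long_words <- nchar(text$words) > 3
  correct <- vapply(log$outcomes, `[[`, TRUE, "correct")
  expect_true(all(!correct[long_words]))
  expect_true(all(correct[!long_words]))
})

test_that("regression rate reproduces in the saccade record", {
  r <- sim_reader_params(true_span = 4, threshold_time_ms = 300,
                         attempted_span = 4, regression_rate = 0.3,
                         premature_speech_p = 0, duration_cv = 0)
  text <- text_material(rep("belora", 170))   # ~500 chunks
  log <- simulate_free_reading(text, r, seed = 17)
  neg_rate <- mean(log$saccades < 0)
  # each regression contributes one negative saccade among ~three
  expect_gt(neg_rate, 0.05)
  n_chunks <- sum(nchar(text$words) %/% 4 + (nchar(text$words) %% 4 > 0))
  n_regressions <- sum(log$saccades < 0)
  expect_equal(n_regressions / n_chunks, 0.3, tolerance = 0.25)
})

test_that("compliant guided reading of a calibrated script is error free", {
  r <- threshold_reader(4, 350, compliance_lapse_p = 0)
  profile <- reader_profile(span = 4, fixation_time_ms = 350)
  text <- text_part(study_texts()[[1]], 1)
  script <- build_script(text, profile)
  log <- simulate_guided_reading(script, r, seed = 23)
  expect_identical(log$n_errors, 0L)
  expect_true(all(log$saccades > 0))
  expect_false(log$span_mismatch)
  # speech never precedes each segment's tone + minimum reaction time
  expect_true(all(diff(c(0, log$speech_onsets_ms)) >= 1250))
})

test_that("guided reading is slower but more accurate than overreaching free reading", {
  r <- sim_reader_params(true_span = 3, threshold_time_ms = 350,
                         attempted_span = 6, premature_speech_p = 0.1,
                         guess_p = 0.3, regression_rate = 0.3)
  profile <- reader_profile(span = 3, fixation_time_ms = 350)
  text <- text_part(study_texts()[[1]], 1)
  script <- build_script(text, profile)
  free_wins <- 0L
  for (i in 1:20) {
    free <- simulate_free_reading(text, r, seed = 100 + i)
    guided <- simulate_guided_reading(script, r, seed = 200 + i)
    expect_gt(guided$total_time_s, free$total_time_s)
    free_wins <- free_wins + (guided$n_errors < free$n_errors)
  }
  expect_gte(free_wins, 19L)
})

test_that("a script beyond the reader's span is flagged", {
  r <- threshold_reader(3, 300)
  script <- build_script(text_material("belora"),
                         reader_profile(span = 5, fixation_time_ms = 300))
  log <- simulate_guided_reading(script, r, seed = 3)
  expect_true(log$span_mismatch)
})

test_that("session logs serialize to delimited files", {
  r <- threshold_reader(4, 300)
  log <- simulate_free_reading(text_material(c("belo", "rami")), r, seed = 1)
  base <- withr::local_tempfile()
  write_session_log(log, base)
  words <- read.csv(paste0(base, "_words.csv"))
  expect_identical(nrow(words), 2L)
  fix <- read.csv(paste0(base, "_fixations.csv"))
  expect_true(all(fix$duration_ms > 0))
})
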