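test_that("words split greedily into span-sized segments with remainder last", {
  s <- segment_word("apfelbaum", 3)
  expect_identical(s$start, c(0L, 3L, 6L))
  expect_identical(s$end, c(2L, 5L, 8L))

  s2 <- segment_word("apfelba", 3)
  expect_identical(s2$start, c(0L, 3L, 6L))
  expect_identical(s2$end, c(2L, 5L, 6L))
  expect_identical(s2$length, c(3L, 3L, 1L))

  short <- segment_word("neun", 5)
  expect_identical(nrow(short), 1L)
  expect_identical(short$end, 3L)
})

test_that("segments tile every word for all spans", {
  set.seed(31)
  words <- replicate(30, paste(sample(letters, sample(1:12, 1),
                                      replace = TRUE), collapse = ""))
  for (span in 1:6) {
    for (w in words) {
      s <- segment_word(w, span)
      expect_identical(s$start[1], 0L)
      expect_identical(s$end[nrow(s)], nchar(w) - 1L)
      if (nrow(s) > 1) {
        expect_identical(s$start[-1], s$end[-nrow(s)] + 1L)
      }
      expect_true(all(s$length >= 1 & s$length <= span))
      pieces <- substring(w, s$start + 1, s$end + 1)
      expect_identical(paste(pieces, collapse = ""), w)
    }
  }
})

test_that("fixation offsets sit on the (left-of-)middle letter", {
  expect_identical(fixation_offset(0, 3), 1L)
  expect_identical(fixation_offset(10, 4), 11L)
  expect_identical(fixation_offset(7, 1), 7L)
  expect_identical(fixation_offset(0, 2), 0L)
})

test_that("scripts schedule tone and speech at the stated offsets", {
  text <- text_material("haus")
  profile <- reader_profile(span = 5, fixation_time_ms = 300)
  script <- build_script(text, profile)
  expect_identical(nrow(script$segments), 1L)
  ev <- script$events
  expect_identical(ev$t_ms[ev$kind == "cursor_move"], 0)
  expect_identical(ev$t_ms[ev$kind == "tone"], 1000)
  expect_identical(ev$t_ms[ev$kind == "speech_window_open"], 1250)
})

test_that("script invariants hold on a realistic text", {
  text <- study_texts()[[1]]
  for (span in c(3L, 4L, 6L)) {
    profile <- reader_profile(span = span, fixation_time_ms = 350)
    script <- build_script(text, profile)
    segs <- script$segments

    # fixation offsets strictly increase; hidden region never retreats
    expect_true(all(diff(segs$fixation_offset) > 0))
    expect_true(all(diff(script$display_start) >= 0))

    # per-segment event triple at +1000 / +250 exactly
    ev <- script$events
    for (kind in c("tone", "speech_window_open")) {
      offs <- ev$t_ms[ev$kind == kind] - ev$t_ms[ev$kind == "cursor_move"]
      expect_true(all(offs == if (kind == "tone") 1000 else 1250))
    }
    expect_true(all(diff(ev$t_ms) >= 0))
    expect_false(any(duplicated(ev$t_ms)))

    # planned fixation time covers the profiled requirement
    expect_gte(script$planned_fixation_ms, profile$fixation_time_ms)

    # concatenated segments reproduce each word
    for (wi in unique(segs$word_index)) {
      rows <- segs[segs$word_index == wi, ]
      pieces <- substring(script$line, rows$absolute_start + 1,
                          rows$absolute_start + rows$length)
      expect_identical(paste(pieces, collapse = ""), text$words[[wi]])
    }

    # within-word saccades never exceed the span
    amp <- saccade_plan(script)
    within <- diff(segs$word_index) == 0
    expect_true(all(amp[within] <= span))
    expect_true(all(amp > 0))
  }
})

test_that("adjacent full segments give span-sized saccades", {
  text <- text_material("abcdef")   # two segments of 3
  script <- build_script(text, reader_profile(span = 3, fixation_time_ms = 250))
  expect_identical(saccade_plan(script), 3L)
})

test_that("text material counts words and letters per part", {
  tm <- text_material(c("ein", "haus", "am", "see"), part_boundary = 2)
  expect_identical(tm$word_count, c(2L, 2L))
  expect_identical(tm$letter_count, c(7L, 5L))
  p2 <- text_part(tm, 2)
  expect_identical(p2$words, c("am", "see"))
  expect_error(text_material(character(0)))
})

test_that("study texts carry the published word and letter counts", {
  texts <- study_texts()
  counts <- study_text_counts()
  for (tx in 1:4) {
    expect_identical(texts[[tx]]$word_count,
                     as.integer(counts$words[counts$text == tx]))
    expect_identical(texts[[tx]]$letter_count,
                     as.integer(counts$letters[counts$text == tx]))
  }
  expect_equal(sum(counts$words), 216)
  # regeneration is deterministic
  expect_identical(study_texts()[[2]]$words, texts[[2]]$words)
})

test_that("texts and scripts round-trip through their file formats", {
  text <- study_texts()[[3]]
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_text_material(text, tpath)
  back <- read_text_material(tpath)
  expect_identical(back$words, text$words)
  expect_identical(back$part_boundary, text$part_boundary)

  script <- build_script(text, reader_profile(4, 300))
  spath <- withr::local_tempfile(fileext = ".json")
  write_guidance_script(script, spath)
  restored <- read_guidance_script(spath)
  expect_equal(restored$segments$fixation_offset,
               script$segments$fixation_offset)
  expect_equal(restored$planned_fixation_ms, script$planned_fixation_ms)
  expect_identical(restored$line, script$line)
})
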