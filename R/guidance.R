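# Guidance engine: segment a text according to a reader profile and emit
# the timed script of cursor moves, go-signal tones and speech windows
# that steers fixations and reading saccades.
#
# The text is rendered as a single line with single inter-word spaces;
# character offsets are 0-based.  Each word is split into left-to-right
# segments of at most the profiled span.  A yellow fixation mark sits on
# the middle letter of each segment, the tone sounds 1 s after the cursor
# moves, and speech may start 250 ms after the tone.  Text left of the
# current segment is hidden so regressions have no target.

#' Text material for a reading session
#'
#' @param words character vector of words (tokens; punctuation stays
#'   attached to its word).
#' @param part_boundary index of the last word of part 1; defaults to an
#'   even split.
#' @return object of class `text_material`: list with `words`,
#'   `part_boundary`, `word_count` and `letter_count` (length-2 vectors
#'   for parts 1 and 2).
#' @export
text_material <- function(words, part_boundary = ceiling(length(words) / 2)) {
  words <- as.character(words)
  if (length(words) == 0L) stop("text has no words", call. = FALSE)
  assert_scalar_number(part_boundary, "part_boundary", 1, length(words))
  letters_of <- function(w) nchar(gsub("[^[:alpha:]]", "", w))
  p1 <- seq_len(part_boundary)
  structure(list(
    words = words,
    part_boundary = as.integer(part_boundary),
    word_count = c(length(p1), length(words) - length(p1)),
    letter_count = c(sum(letters_of(words[p1])),
                     sum(letters_of(words[-p1])))
  ), class = "text_material")
}

#' Extract one part of a text as its own material
#'
#' @param text a [text_material()].
#' @param part 1 or 2.
#' @return a `text_material` holding only that part.
#' @export
text_part <- function(text, part) {
  idx <- if (part == 1) seq_len(text$part_boundary) else
    seq.int(text$part_boundary + 1L, length(text$words))
  text_material(text$words[idx], part_boundary = length(idx))
}

#' Read text material from a UTF-8 file
#'
#' Tokenization is on whitespace.  If the file contains a blank line, the
#' words before it form part 1; otherwise the text is split evenly.
#'
#' @param path file path.
#' @return a [text_material()].
#' @export
read_text_material <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  blank <- which(trimws(lines) == "")
  tokens_of <- function(ls) {
    toks <- unlist(strsplit(paste(ls, collapse = " "), "[[:space:]]+"))
    toks[nzchar(toks)]
  }
  if (length(blank)) {
    first <- tokens_of(lines[seq_len(blank[1] - 1L)])
    rest <- tokens_of(lines[-seq_len(blank[1])])
    text_material(c(first, rest), part_boundary = length(first))
  } else {
    text_material(tokens_of(lines))
  }
}

#' Split one word into reading segments
#'
#' Greedy left-to-right split into pieces of exactly `span` letters; the
#' final piece holds the remainder.  Segments never cross word boundaries.
#'
#' @param word character word.
#' @param span maximum letters per segment (>= 1).
#' @return data frame with 0-based inclusive `start` and `end` offsets
#'   within the word and the segment `length`.
#' @export
#' @examples
#' segment_word("apfelbaum", 3) # [0..2] [3..5] [6..8]
segment_word <- function(word, span) {
  assert_scalar_number(span, "span", 1)
  len <- nchar(word)
  if (len == 0L) stop("word is empty", call. = FALSE)
  starts <- seq.int(0L, len - 1L, by = span)
  ends <- pmin(starts + span - 1L, len - 1L)
  data.frame(start = as.integer(starts), end = as.integer(ends),
             length = as.integer(ends - starts + 1L))
}

#' Fixation offset of a segment
#'
#' The middle letter; for even segment lengths the letter left of the
#' middle (0-based index `start + ceil(k/2) - 1`).
#'
#' @param absolute_start 0-based character offset of the segment in the
#'   rendered line.
#' @param length segment length in letters.
#' @return absolute 0-based character index of the fixation mark.
#' @export
fixation_offset <- function(absolute_start, length) {
  as.integer(absolute_start + ceiling(length / 2) - 1L)
}

#' Guidance timing configuration
#'
#' @param tone_after_move_ms delay from cursor move to the go-signal tone
#'   (default 1000 ms).
#' @param reaction_ms minimum reaction time from tone to the speech
#'   window (default 250 ms).
#' @param pronounce_ms time allotted to pronounce a segment before the
#'   cursor advances (default 500 ms).
#' @param saccade_ms gap between a segment advance and the next cursor
#'   move (default 40 ms), keeping events strictly ordered.
#' @param min_fixation_ms lower bound on the planned fixation duration
#'   (default 250 ms).
#' @return list of class `guidance_config`.
#' @export
guidance_config <- function(tone_after_move_ms = 1000, reaction_ms = 250,
                            pronounce_ms = 500, saccade_ms = 40,
                            min_fixation_ms = 250) {
  structure(list(tone_after_move_ms = tone_after_move_ms,
                 reaction_ms = reaction_ms, pronounce_ms = pronounce_ms,
                 saccade_ms = saccade_ms,
                 min_fixation_ms = min_fixation_ms),
            class = "guidance_config")
}

#' Build the guidance script for a text and a reader profile
#'
#' Segments every word with [segment_word()] at the profile's span and
#' schedules, for each segment: a cursor move, the tone 1000 ms later,
#' the speech window 250 ms after the tone, and the segment advance after
#' the pronunciation window.  The planned fixation duration is
#' `max(profile$fixation_time_ms, min_fixation_ms)`.  The display start
#' of each segment equals its absolute start: text to its left is hidden.
#'
#' @param text a [text_material()].
#' @param profile a [reader_profile()].
#' @param config a [guidance_config()].
#' @return object of class `guidance_script`: list with `segments` (data
#'   frame: word_index, start_letter, end_letter, length, absolute_start,
#'   fixation_offset), `events` (data frame: t_ms, kind, segment_index),
#'   `display_start` (per-segment hidden-region boundary),
#'   `planned_fixation_ms`, `span`, `line`, `words`, `config`.
#' @export
build_script <- function(text, profile, config = guidance_config()) {
  if (!length(text$words)) stop("text has no words", call. = FALSE)
  span <- profile$span
  line <- paste(text$words, collapse = " ")
  lens <- nchar(text$words)
  word_starts <- c(0L, cumsum(lens + 1L))
  n_segs <- (lens + span - 1L) %/% span
  word_index <- rep.int(seq_along(lens), n_segs)
  start_letter <- as.integer(unlist(lapply(lens, function(len) {
    seq.int(0L, len - 1L, by = span)
  }), use.names = FALSE))
  end_letter <- pmin(start_letter + as.integer(span) - 1L,
                     lens[word_index] - 1L)
  seg_len <- end_letter - start_letter + 1L
  abs_start <- word_starts[word_index] + start_letter
  segments <- data.frame(
    word_index = word_index, start_letter = start_letter,
    end_letter = end_letter, length = seg_len,
    absolute_start = abs_start,
    fixation_offset = fixation_offset(abs_start, seg_len))
  n <- nrow(segments)
  planned <- max(profile$fixation_time_ms, config$min_fixation_ms)
  period <- config$tone_after_move_ms + config$reaction_ms +
    config$pronounce_ms
  t_move <- (seq_len(n) - 1L) * (period + config$saccade_ms)
  events <- data.frame(
    t_ms = c(t_move,
             t_move + config$tone_after_move_ms,
             t_move + config$tone_after_move_ms + config$reaction_ms,
             t_move + period),
    kind = rep(c("cursor_move", "tone", "speech_window_open",
                 "segment_advance"), each = n),
    segment_index = rep(seq_len(n), 4L),
    stringsAsFactors = FALSE
  )
  events <- events[order(events$t_ms, events$segment_index), ]
  rownames(events) <- NULL
  structure(list(segments = segments, events = events,
                 display_start = segments$absolute_start,
                 planned_fixation_ms = planned, span = span,
                 line = line, words = text$words, config = config),
            class = "guidance_script")
}

#' Saccade plan of a guidance script
#'
#' @param script a [build_script()] result with at least two segments.
#' @return signed character amplitudes between consecutive fixation
#'   offsets; all positive for a valid script.
#' @export
saccade_plan <- function(script) {
  offs <- script$segments$fixation_offset
  if (length(offs) < 2L) stop("need at least two segments", call. = FALSE)
  diff(offs)
}

#' Serialize / restore a guidance script
#'
#' Scripts are stored as JSON holding the segment table, event table and
#' scalar schedule parameters.
#'
#' @param script a `guidance_script`.
#' @param path file path.
#' @return `read_guidance_script` returns a `guidance_script`.
#' @export
write_guidance_script <- function(script, path) {
  payload <- list(segments = script$segments, events = script$events,
                  display_start = script$display_start,
                  planned_fixation_ms = script$planned_fixation_ms,
                  span = script$span, line = script$line,
                  words = script$words,
                  config = unclass(script$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_guidance_script
#' @export
read_guidance_script <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(segments = as.data.frame(p$segments),
                 events = as.data.frame(p$events),
                 display_start = p$display_start,
                 planned_fixation_ms = p$planned_fixation_ms,
                 span = p$span, line = p$line, words = p$words,
                 config = structure(p$config, class = "guidance_config")),
            class = "guidance_script")
}
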