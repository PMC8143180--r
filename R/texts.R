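# Synthetic reading materials.
#
# The four study texts themselves are not published; the package ships a
# synthetic stand-in generator producing four pronounceable texts whose
# per-part word and letter counts equal the published material counts, so
# that error percentages use the same denominators (216 words in total).

study_text_counts_tbl <- function() {
  data.frame(
    text = rep(1:4, each = 2),
    part = rep(1:2, 4),
    words = c(29, 30, 33, 34, 26, 25, 20, 19),
    letters = c(142, 139, 156, 161, 129, 130, 131, 127)
  )
}

#' Word and letter counts of the study texts
#'
#' @return data frame with columns `text`, `part`, `words`, `letters`;
#'   the word counts sum to 216.
#' @export
study_text_counts <- function() study_text_counts_tbl()

# Alternating C/V template of arbitrary length, starting with a consonant.
text_pattern <- function(len) {
  paste(rep(c("C", "V"), length.out = len), collapse = "")
}

# Word lengths for a part with W words and L letters: start from the
# near-uniform split and move letters between words for variety, keeping
# lengths in [2, 9].
part_word_lengths <- function(W, L) {
  base <- L %/% W
  lengths <- rep(base, W)
  extra <- L - base * W
  if (extra > 0) lengths[seq_len(extra)] <- lengths[seq_len(extra)] + 1L
  for (k in seq_len(3L * W)) {
    i <- sample.int(W, 1L); j <- sample.int(W, 1L)
    if (i != j && lengths[i] < 9L && lengths[j] > 2L) {
      lengths[i] <- lengths[i] + 1L
      lengths[j] <- lengths[j] - 1L
    }
  }
  sample(lengths)
}

#' Generate the four synthetic study texts
#'
#' Pronounceable placeholder texts with exactly the published per-part
#' word and letter counts, generated reproducibly from a seed.
#'
#' @param seed integer seed (defaults to a fixed fixture seed so that the
#'   shipped materials are stable).
#' @return list of four [text_material()] objects.
#' @export
study_texts <- function(seed = 526L) {
  counts <- study_text_counts_tbl()
  alphabet <- default_alphabet()
  bigrams <- default_bigrams(alphabet)
  with_seed(seed, {
    lapply(1:4, function(tx) {
      rows <- counts[counts$text == tx, ]
      words <- unlist(lapply(1:2, function(pt) {
        row <- rows[rows$part == pt, ]
        lens <- part_word_lengths(row$words, row$letters)
        vapply(lens, function(len) {
          generate_pseudoword(len, alphabet, bigrams,
                              pattern = text_pattern(len))$letters
        }, "")
      }))
      text_material(words, part_boundary = rows$words[rows$part == 1])
    })
  })
}

#' Write text material to a plain UTF-8 file
#'
#' Part 1 and part 2 are separated by a blank line; round-trips through
#' [read_text_material()].
#'
#' @param text a [text_material()].
#' @param path file path.
#' @export
write_text_material <- function(text, path) {
  p1 <- text$words[seq_len(text$part_boundary)]
  p2 <- text$words[-seq_len(text$part_boundary)]
  writeLines(c(paste(p1, collapse = " "), "", paste(p2, collapse = " ")),
             path, useBytes = TRUE)
  invisible(path)
}
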