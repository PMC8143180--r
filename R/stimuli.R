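# Pseudoword stimulus generation.
#
# Assessment lists use pronounceable pseudowords: each letter corresponds to
# one phoneme, so letter-level reading errors can be identified from the
# spoken response.  Within one list every item shares a single
# consonant/vowel template, and phonotactic plausibility is enforced through
# a permitted-bigram table rather than a lexicon.

#' Default alphabet for pseudoword generation
#'
#' Lowercase German-compatible alphabet without umlauts; vowels are the five
#' plain vowels, consonants exclude letters whose pronunciation is ambiguous
#' in isolation (c, j, q, v, x, y).
#'
#' @return list with components `vowels` and `consonants`.
#' @export
default_alphabet <- function() {
  list(
    vowels = c("a", "e", "i", "o", "u"),
    consonants = c("b", "d", "f", "g", "h", "k", "l", "m",
                   "n", "p", "r", "s", "t", "w", "z")
  )
}

#' Default permitted-bigram table
#'
#' Adjacent letter pairs allowed in generated pseudowords.  All
#' consonant-vowel and vowel-consonant pairs over [default_alphabet()] are
#' permitted; consonant clusters are restricted to a fixed list of clusters
#' that occur word-medially in German.
#'
#' @param alphabet alphabet list as returned by [default_alphabet()].
#' @return character vector of two-letter strings.
#' @export
default_bigrams <- function(alphabet = default_alphabet()) {
  cv <- as.vector(outer(alphabet$consonants, alphabet$vowels, paste0))
  vc <- as.vector(outer(alphabet$vowels, alphabet$consonants, paste0))
  cc <- c("bs", "ft", "gs", "ks", "lb", "ld", "lf", "lk", "lm", "ln",
          "lp", "ls", "lt", "lz", "mp", "ms", "nd", "nf", "ng", "nk",
          "ns", "nt", "nz", "pf", "ps", "rb", "rd", "rf", "rg", "rk",
          "rl", "rm", "rn", "rp", "rs", "rt", "rz", "sp", "st", "tz")
  cc <- cc[substr(cc, 1, 1) %in% alphabet$consonants &
             substr(cc, 2, 2) %in% alphabet$consonants]
  unique(c(cv, vc, cc))
}

#' Canonical consonant/vowel template for a pseudoword length
#'
#' Every list of a given length uses one fixed template so that all items
#' place the same number of consonants and vowels at the same positions.
#'
#' @param length integer word length, 2 to 6.
#' @return string over `C` and `V`, e.g. `"CVCVC"` for length 5.
#' @export
#' @examples
#' canonical_pattern(4) # "CVCV"
canonical_pattern <- function(length) {
  assert_scalar_number(length, "length", 2, 6)
  if (length != as.integer(length)) stop("`length` must be an integer", call. = FALSE)
  c(`2` = "CV", `3` = "CVC", `4` = "CVCV", `5` = "CVCVC", `6` = "CVCCVC")[[as.character(length)]]
}

#' Generate one pronounceable pseudoword
#'
#' Samples letters left to right under the canonical template for the
#' requested length; at each position the candidate set is the letters of
#' the required class whose bigram with the previous letter appears in the
#' permitted-bigram table.
#'
#' @param length word length, 2 to 6.
#' @param alphabet alphabet list; see [default_alphabet()].
#' @param bigrams permitted-bigram table; see [default_bigrams()].
#' @param pattern consonant/vowel template; defaults to
#'   [canonical_pattern()] of `length`.
#' @return object of class `pseudoword`: a list with `letters` and
#'   `cv_pattern`.
#' @export
generate_pseudoword <- function(length,
                                alphabet = default_alphabet(),
                                bigrams = default_bigrams(alphabet),
                                pattern = canonical_pattern(length)) {
  if (length(bigrams) == 0L) stop("permitted-bigram table is empty", call. = FALSE)
  classes <- strsplit(pattern, "")[[1]]
  if (length(classes) != length) stop("pattern length must equal `length`", call. = FALSE)
  for (attempt in 1:50) {
    word <- character(length)
    ok <- TRUE
    for (i in seq_len(length)) {
      pool <- if (classes[i] == "V") alphabet$vowels else alphabet$consonants
      if (i > 1L) pool <- pool[paste0(word[i - 1L], pool) %in% bigrams]
      if (length(pool) == 0L) { ok <- FALSE; break }
      word[i] <- pool[sample.int(length(pool), 1L)]
    }
    if (ok) {
      return(structure(list(letters = paste(word, collapse = ""),
                            cv_pattern = pattern),
                       class = "pseudoword"))
    }
  }
  stop("could not generate a pseudoword under the bigram constraints", call. = FALSE)
}

#' Generate a stimulus list of unique pseudowords
#'
#' @param length word length, 2 to 6.
#' @param n number of items (default 20, the standard list size).
#' @param seed integer seed; fixed seeds reproduce lists exactly.
#' @param alphabet,bigrams see [generate_pseudoword()].
#' @return object of class `stimulus_list`: list with `length`, `pattern`,
#'   `seed` and `items` (character vector of words).
#' @export
#' @examples
#' gl <- generate_list(4, 20, seed = 7)
#' length(gl$items)
generate_list <- function(length, n = 20, seed = NULL,
                          alphabet = default_alphabet(),
                          bigrams = default_bigrams(alphabet)) {
  assert_scalar_number(n, "n", 1)
  pattern <- canonical_pattern(length)
  items <- with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      w <- generate_pseudoword(length, alphabet, bigrams, pattern)$letters
      if (!(w %in% out)) out <- c(out, w)
      tries <- tries + 1L
      if (tries > 200L * n) {
        stop("could not assemble ", n, " unique pseudowords of length ", length,
             call. = FALSE)
      }
    }
    out
  })
  structure(list(length = as.integer(length), pattern = pattern,
                 seed = seed, items = items),
            class = "stimulus_list")
}

#' Validate a pseudoword against template and bigram table
#'
#' @param word character word.
#' @param pattern template string over C/V.
#' @param alphabet,bigrams see [generate_pseudoword()].
#' @return `TRUE` if the word matches the template and every adjacent pair
#'   is permitted.
#' @export
validate_pseudoword <- function(word, pattern,
                                alphabet = default_alphabet(),
                                bigrams = default_bigrams(alphabet)) {
  chars <- strsplit(word, "")[[1]]
  classes <- strsplit(pattern, "")[[1]]
  if (length(chars) != length(classes)) return(FALSE)
  class_ok <- vapply(seq_along(chars), function(i) {
    pool <- if (classes[i] == "V") alphabet$vowels else alphabet$consonants
    chars[i] %in% pool
  }, logical(1))
  if (!all(class_ok)) return(FALSE)
  if (length(chars) > 1L) {
    pairs <- paste0(chars[-length(chars)], chars[-1])
    if (!all(pairs %in% bigrams)) return(FALSE)
  }
  TRUE
}

#' Write / read a stimulus list as plain text
#'
#' One word per line, preceded by a header line
#' `#length=<n> seed=<s> pattern=<p>`.
#'
#' @param x a `stimulus_list`.
#' @param path file path.
#' @return `read_stimulus_list` returns a `stimulus_list`.
#' @export
write_stimulus_list <- function(x, path) {
  stopifnot(inherits(x, "stimulus_list"))
  header <- sprintf("#length=%d seed=%s pattern=%s",
                    x$length, format(x$seed %||% NA), x$pattern)
  writeLines(c(header, x$items), path)
  invisible(path)
}

#' @rdname write_stimulus_list
#' @export
read_stimulus_list <- function(path) {
  lines <- readLines(path)
  header <- lines[[1]]
  m <- regmatches(header,
                  regexec("^#length=(\\d+) seed=([^ ]+) pattern=([CV]+)$", header))[[1]]
  if (length(m) != 4L) stop("malformed stimulus-list header: ", header, call. = FALSE)
  seed <- suppressWarnings(as.integer(m[3]))
  structure(list(length = as.integer(m[2]), pattern = m[4],
                 seed = if (is.na(seed)) NULL else seed,
                 items = lines[-1]),
            class = "stimulus_list")
}
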