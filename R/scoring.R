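# Letter-level scoring of spoken responses.
#
# A word counts as read incorrectly if at least one letter was omitted,
# replaced by a letter not present at that position, shifted to another
# location, or added.  Errors are attributed to target letter positions via
# a minimal edit alignment so that per-position misread rates can be
# tabulated by word length.

#' Minimal edit alignment between target and response
#'
#' Computes a minimal-cost alignment (unit costs for substitution, deletion
#' and insertion).  Ties are broken by preferring match, then substitution,
#' then deletion, then insertion, resolved left to right.
#'
#' @param target,response character strings.
#' @return object of class `letter_alignment`: list with `ops` (data frame
#'   with columns `op`, `target_pos`, `response_pos`, `target_char`,
#'   `response_char`) and `cost` (the edit distance).
#' @export
#' @examples
#' align_letters("abc", "axc")$cost # 1
align_letters <- function(target, response) {
  t_chars <- strsplit(target, "")[[1]]
  r_chars <- strsplit(response, "")[[1]]
  n <- length(t_chars)
  m <- length(r_chars)
  # D[i+1, j+1] = edit distance between target[i..n] and response[j..m]
  D <- matrix(0L, n + 1L, m + 1L)
  D[n + 1L, ] <- (m:0)
  D[, m + 1L] <- (n:0)
  if (n > 0L && m > 0L) {
    for (i in n:1) {
      for (j in m:1) {
        sub_cost <- if (t_chars[i] == r_chars[j]) 0L else 1L
        D[i, j] <- min(D[i + 1L, j + 1L] + sub_cost,
                       D[i + 1L, j] + 1L,
                       D[i, j + 1L] + 1L)
      }
    }
  }
  ops <- vector("list", n + m)
  k <- 0L
  i <- 1L; j <- 1L
  while (i <= n || j <= m) {
    k <- k + 1L
    if (i <= n && j <= m && t_chars[i] == r_chars[j] &&
        D[i + 1L, j + 1L] == D[i, j]) {
      ops[[k]] <- list("match", i, j, t_chars[i], r_chars[j])
      i <- i + 1L; j <- j + 1L
    } else if (i <= n && j <= m && D[i + 1L, j + 1L] + 1L == D[i, j]) {
      ops[[k]] <- list("substitute", i, j, t_chars[i], r_chars[j])
      i <- i + 1L; j <- j + 1L
    } else if (i <= n && D[i + 1L, j] + 1L == D[i, j]) {
      ops[[k]] <- list("delete", i, NA_integer_, t_chars[i], NA_character_)
      i <- i + 1L
    } else {
      ops[[k]] <- list("insert", NA_integer_, j, NA_character_, r_chars[j])
      j <- j + 1L
    }
  }
  ops <- ops[seq_len(k)]
  ops_df <- data.frame(
    op = vapply(ops, `[[`, "", 1),
    target_pos = vapply(ops, function(o) as.integer(o[[2]]), 1L),
    response_pos = vapply(ops, function(o) as.integer(o[[3]]), 1L),
    target_char = vapply(ops, function(o) as.character(o[[4]]), ""),
    response_char = vapply(ops, function(o) as.character(o[[5]]), ""),
    stringsAsFactors = FALSE
  )
  structure(list(ops = ops_df, cost = D[1L, 1L]), class = "letter_alignment")
}

# Identify substitution pairs that realize a transposition: two substituted
# target positions no more than two apart whose letters appear swapped in
# the response.  Returns indices (rows of ops) that belong to a swap.
transposition_rows <- function(ops) {
  subs <- which(ops$op == "substitute")
  flagged <- integer(0)
  if (length(subs) >= 2L) {
    for (a in seq_along(subs)[-length(subs)]) {
      for (b in (a + 1L):length(subs)) {
        ra <- subs[a]; rb <- subs[b]
        if (ra %in% flagged || rb %in% flagged) next
        if (abs(ops$target_pos[rb] - ops$target_pos[ra]) > 2L) next
        if (ops$target_char[ra] == ops$response_char[rb] &&
            ops$target_char[rb] == ops$response_char[ra]) {
          flagged <- c(flagged, ra, rb)
        }
      }
    }
  }
  flagged
}

#' Classify a response against a target word
#'
#' The comparison is case-insensitive after trimming whitespace.  A correct
#' response is an exact match; otherwise the error kinds are derived from
#' the minimal alignment: deletions are omissions, insertions are
#' additions, and substitutions are reported as substitutions unless a pair
#' of nearby substituted letters appears swapped, in which case the pair is
#' a transposition.
#'
#' @param target,response character strings; `target` must be nonempty.
#' @return object of class `word_outcome`: list with `target`, `response`,
#'   `correct`, `error_kinds` (character subset of omission, substitution,
#'   transposition, addition) and `flags` (logical vector over target
#'   positions, see [position_error_flags()]).
#' @export
#' @examples
#' classify_response("belo", "bleo")$error_kinds # "transposition"
classify_response <- function(target, response) {
  target <- tolower(trimws(target))
  response <- tolower(trimws(response))
  if (nchar(target) == 0L) stop("`target` must be nonempty", call. = FALSE)
  if (identical(target, response)) {
    return(structure(list(target = target, response = response,
                          correct = TRUE, error_kinds = character(0),
                          flags = rep(FALSE, nchar(target))),
                     class = "word_outcome"))
  }
  if (nchar(response) == 0L) {
    return(structure(list(target = target, response = response,
                          correct = FALSE, error_kinds = "omission",
                          flags = rep(TRUE, nchar(target))),
                     class = "word_outcome"))
  }
  al <- align_letters(target, response)
  ops <- al$ops
  trans <- transposition_rows(ops)
  kinds <- character(0)
  if (any(ops$op == "delete")) kinds <- c(kinds, "omission")
  if (any(ops$op == "substitute" & !(seq_len(nrow(ops)) %in% trans))) {
    kinds <- c(kinds, "substitution")
  }
  if (length(trans)) kinds <- c(kinds, "transposition")
  if (any(ops$op == "insert")) kinds <- c(kinds, "addition")
  structure(list(target = target, response = response, correct = FALSE,
                 error_kinds = kinds,
                 flags = flags_from_ops(ops, nchar(target))),
            class = "word_outcome")
}

flags_from_ops <- function(ops, n) {
  flags <- rep(FALSE, n)
  hit <- ops$target_pos[ops$op %in% c("delete", "substitute")]
  flags[hit] <- TRUE
  # insertions charge the nearest following target position; insertions at
  # the end of the word charge the last position
  ins <- which(ops$op == "insert")
  for (r in ins) {
    later <- ops$target_pos[seq_len(nrow(ops)) > r]
    later <- later[!is.na(later)]
    flags[if (length(later)) later[1] else n] <- TRUE
  }
  flags
}

#' Per-position error flags for one word
#'
#' Position `i` is flagged when the minimal alignment deletes or substitutes
#' target letter `i` (including letters participating in a transposition);
#' an inserted letter flags the nearest following target position (end
#' insertions flag the last position).
#'
#' @param target,response character strings.
#' @return logical vector of length `nchar(target)`.
#' @export
position_error_flags <- function(target, response) {
  classify_response(target, response)$flags
}

#' Per-position misread rates for a set of same-length words
#'
#' @param targets,responses character vectors of equal length; all targets
#'   must share one word length.  Correctly read words contribute zeros.
#' @return object of class `position_error_profile`: list with `length`,
#'   `rate_by_position` (fractions in \[0, 1\]) and `n_words`.
#' @export
position_error_profile <- function(targets, responses) {
  if (length(targets) == 0L) stop("no outcomes supplied", call. = FALSE)
  if (length(targets) != length(responses)) {
    stop("`targets` and `responses` must have equal length", call. = FALSE)
  }
  lens <- nchar(trimws(targets))
  if (length(unique(lens)) != 1L) {
    stop("all targets must share one word length", call. = FALSE)
  }
  n <- lens[[1]]
  counts <- rep(0, n)
  for (i in seq_along(targets)) {
    counts <- counts + position_error_flags(targets[i], responses[i])
  }
  structure(list(length = n, rate_by_position = counts / length(targets),
                 n_words = length(targets)),
            class = "position_error_profile")
}

#' Write word outcomes to a delimited file
#'
#' Columns: target, response, correct, error_kinds (semicolon separated),
#' flags (run of 0/1 characters, one per target position).
#'
#' @param outcomes list of `word_outcome` objects.
#' @param path output file path.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- data.frame(
    target = vapply(outcomes, `[[`, "", "target"),
    response = vapply(outcomes, `[[`, "", "response"),
    correct = vapply(outcomes, `[[`, TRUE, "correct"),
    error_kinds = vapply(outcomes, function(o) paste(o$error_kinds, collapse = ";"), ""),
    flags = vapply(outcomes, function(o) paste(as.integer(o$flags), collapse = ""), ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
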