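# In-silico reproduction of the study designs: the 60-reader cohort whose
# span-by-fixation-time cross-tabulation matches the published assessment
# results, matched two-group assignment, the crossover text halves, and
# end-to-end runs of the assessment and guided-reading experiments.

# Published cross-tabulation: readers per (span, fixation time) cell with
# therapy-group (tg) / control-group (cg) membership, plus the per-span
# speech-onset latency summaries.
table1_cells_tbl <- function() {
  df <- rbind(
    data.frame(span = 3, time = c(250, 300, 350, 400, 450, 500),
               tg = c(3, 2, 1, 1, 1, 1), cg = c(3, 3, 2, 1, 0, 1)),
    data.frame(span = 4, time = c(250, 300, 350, 400, 450, 500),
               tg = c(2, 1, 3, 1, 0, 2), cg = c(3, 1, 2, 1, 1, 1)),
    data.frame(span = 5, time = c(250, 300, 350, 400, 450, 500),
               tg = c(3, 3, 1, 1, 0, 1), cg = c(4, 2, 1, 0, 0, 2)),
    data.frame(span = 6, time = c(250, 400), tg = c(2, 1), cg = c(1, 1))
  )
  df[df$tg + df$cg > 0, ]
}

speech_onset_summaries_tbl <- function() {
  data.frame(span = 3:6,
             mean_ms = c(1456.45, 1404.84, 1466.39, 1393.86),
             sd_ms = c(473.08, 705.60, 562.96, 484.52),
             n = c(19, 18, 18, 5))
}

#' Reference cohort cross-tabulation
#'
#' Cell counts of the 60-reader cohort by recognition span and required
#' fixation time, with therapy/control membership, and the per-span
#' speech-onset latency summaries.
#'
#' @return list with `cells` (data frame: span, time, tg, cg) and
#'   `speech_onset` (data frame: span, mean_ms, sd_ms, n).
#' @export
table1_reference <- function() {
  list(cells = table1_cells_tbl(), speech_onset = speech_onset_summaries_tbl())
}

#' Build the 60-reader synthetic cohort
#'
#' One deterministic threshold reader per cohort cell: true span and
#' threshold time equal the cell's values, so an adaptive assessment
#' recovers the generating cross-tabulation exactly.  Speech-retrieval
#' parameters are set so that mean trial speech onsets match the per-span
#' latency summaries within sampling error.  Free-reading behavior is
#' miscalibrated in the way poor readers read: the attempted span exceeds
#' the true span and fixations are sometimes cut short.
#'
#' @param seed integer seed (ages and ordering).
#' @param attempted_span_offset letters attempted beyond the true span in
#'   free reading (default 2).
#' @param premature_speech_p,regression_rate,compliance_lapse_p,guess_p
#'   free/guided reading parameters passed to every reader; the default
#'   `guess_p` of 0.9 reflects guessing of meaningful words from partial
#'   letter information (unlike pseudowords).
#' @return list of 60 [sim_reader_params()] objects with `id`, `group`
#'   and `age_months` set.
#' @export
table1_cohort <- function(seed = 1L, attempted_span_offset = 2,
                          premature_speech_p = 0.05,
                          regression_rate = 0.3,
                          compliance_lapse_p = 0.02,
                          guess_p = 0.9) {
  cells <- table1_cells_tbl()
  onsets <- speech_onset_summaries_tbl()
  with_seed(seed, {
    readers <- list()
    idx <- 0L
    for (ci in seq_len(nrow(cells))) {
      row <- cells[ci, ]
      groups <- c(rep("therapy", row$tg), rep("control", row$cg))
      for (g in groups) {
        idx <- idx + 1L
        lat <- onsets[onsets$span == row$span, ]
        readers[[idx]] <- sim_reader_params(
          true_span = row$span, threshold_time_ms = row$time,
          slope = Inf, attempted_span = row$span + attempted_span_offset,
          premature_speech_p = premature_speech_p,
          regression_rate = regression_rate,
          compliance_lapse_p = compliance_lapse_p,
          guess_p = guess_p,
          retrieval_mean_ms = lat$mean_ms - 50,  # reaction delay mean
          retrieval_sd_ms = lat$sd_ms,
          age_months = round(min(180, max(96, stats::rnorm(1, 122.4, 19.3)))),
          id = sprintf("r%02d", idx), group = g)
      }
    }
    readers
  })
}

#' Match readers into two balanced groups
#'
#' Stratifies by (span, fixation time), orders readers within each stratum
#' by age after a seeded shuffle, and splits age-adjacent pairs between
#' the two groups; a stratum's odd leftover joins whichever group is
#' currently smaller overall (seeded coin on ties).  Group sizes therefore
#' differ by at most one per stratum and at most one overall, and ages
#' balance within strata.
#'
#' @param cohort list of [sim_reader_params()].
#' @param seed integer seed.
#' @return object of class `cohort_assignment`: list with `therapy` and
#'   `control` (reader ids).
#' @export
match_groups <- function(cohort, seed = 1L) {
  if (length(cohort) < 2L) stop("need at least two readers", call. = FALSE)
  ids <- vapply(cohort, `[[`, "", "id")
  span <- vapply(cohort, `[[`, 0, "true_span")
  time <- vapply(cohort, `[[`, 0, "threshold_time_ms")
  age <- vapply(cohort, `[[`, 0, "age_months")
  with_seed(seed, {
    strata <- split(seq_along(cohort), list(span, time), drop = TRUE)
    # fixed stratum order: by span then time
    key <- vapply(strata, function(ix) span[ix[1]] * 1000 + time[ix[1]], 0)
    strata <- strata[order(key)]
    therapy <- control <- integer(0)
    for (ix in strata) {
      ix <- ix[sample.int(length(ix))]
      if (!all(is.na(age[ix]))) ix <- ix[order(age[ix])]
      # split age-adjacent pairs between the groups (coin decides which
      # member goes where); a leftover reader joins whichever group is
      # smaller overall, by seeded coin on ties
      k <- 1L
      while (k + 1L <= length(ix)) {
        flip <- stats::runif(1) < 0.5
        therapy <- c(therapy, ix[k + !flip])
        control <- c(control, ix[k + flip])
        k <- k + 2L
      }
      if (k == length(ix)) {
        nt <- length(therapy); nc <- length(control)
        to_therapy <- if (nt < nc) TRUE else if (nt > nc) FALSE else
          stats::runif(1) < 0.5
        if (to_therapy) therapy <- c(therapy, ix[k])
        else control <- c(control, ix[k])
      }
    }
    structure(list(therapy = ids[therapy], control = ids[control]),
              class = "cohort_assignment")
  })
}

#' Assign crossover reading orders
#'
#' Within each group, half of the readers read part 1 first and part 2
#' second, the other half the reverse (an odd reader's order is decided by
#' the seed).  Therapy readers read their second part with computer
#' guidance; controls are never aided.
#'
#' @param assignment a [match_groups()] result.
#' @param seed integer seed.
#' @return object of class `crossover_plan`: data frame with columns
#'   `reader`, `group`, `first_part`, `second_part`, `aided_part` (NA for
#'   controls).
#' @export
crossover_assign <- function(assignment, seed = 1L) {
  with_seed(seed, {
    plan_group <- function(ids, group) {
      ids <- sample(ids)
      n <- length(ids)
      n_ab <- n %/% 2L + (n %% 2L) * (stats::runif(1) < 0.5)
      first <- c(rep(1L, n_ab), rep(2L, n - n_ab))
      data.frame(reader = ids, group = group, first_part = first,
                 second_part = 3L - first,
                 aided_part = if (group == "therapy") 3L - first else
                   NA_integer_,
                 stringsAsFactors = FALSE)
    }
    plan <- rbind(plan_group(assignment$therapy, "therapy"),
                  plan_group(assignment$control, "control"))
    rownames(plan) <- NULL
    structure(plan, class = c("crossover_plan", "data.frame"))
  })
}

#' Assess a whole cohort and tabulate the outcomes
#'
#' Runs [run_assessment()] for every reader and cross-tabulates the
#' recovered spans and fixation times.
#'
#' @param cohort list of [sim_reader_params()].
#' @param config an [assessment_config()].
#' @param seed integer master seed.
#' @return list with `profiles` (list of [reader_profile()]s),
#'   `tabulation` (span-by-time contingency table) and `speech_onset`
#'   (data frame of per-span mean latencies).
#' @export
run_experiment1_cohort <- function(cohort, config = assessment_config(),
                                   seed = 1L) {
  if (!length(cohort)) stop("cohort is empty", call. = FALSE)
  profiles <- lapply(seq_along(cohort), function(i) {
    run_assessment(cohort[[i]], config, seed = derive_seed(seed, i))$profile
  })
  span <- vapply(profiles, `[[`, 0L, "span")
  time <- vapply(profiles, `[[`, 0L, "fixation_time_ms")
  onset <- vapply(profiles, `[[`, 0, "speech_onset_mean_ms")
  tab <- table(span = span, time = time)
  by_span <- data.frame(span = sort(unique(span)),
                        mean_ms = vapply(sort(unique(span)), function(s) {
                          mean(onset[span == s])
                        }, 0))
  list(profiles = profiles, tabulation = tab, speech_onset = by_span)
}

# Deterministic profile of a threshold reader, used when skipping the
# staircase: the span capped at the length grid and the threshold time
# snapped up to the time grid.
oracle_profile <- function(params, config = assessment_config()) {
  span <- min(params$true_span, config$length_max)
  tt <- max(config$time_min_ms,
            min(config$time_max_ms,
                ceiling(params$threshold_time_ms / config$time_step_ms) *
                  config$time_step_ms))
  reader_profile(span = span, fixation_time_ms = tt)
}

#' Run the full crossover guided-reading experiment
#'
#' Simulates the two-session crossover: every reader reads one half of the
#' four texts unaided; the therapy group reads the remaining halves under
#' computer guidance with a script built from its profile while controls
#' read them unaided again.  Computes per-reader misread-word counts and
#' reading times per condition, group summaries, pooled-SD effect sizes
#' (signed so that an error decrease is positive), their contrast, error
#' percentages of the 216-word material, and signed-rank p-values.
#'
#' @param cohort list of [sim_reader_params()] (e.g. [table1_cohort()]).
#' @param texts list of four [text_material()]s (default [study_texts()]).
#' @param seed integer master seed.
#' @param profiles optional list of [reader_profile()]s, one per reader;
#'   by default the profile of each deterministic threshold reader is
#'   derived directly from its generative parameters.
#' @param assess if `TRUE`, profile every reader by running the adaptive
#'   assessment instead.
#' @return object of class `experiment_result`: list with `per_reader`
#'   (data frame), `therapy`, `control` (each: summaries, effect size,
#'   p-value, percentages), `contrast`, `word_total`.
#' @export
run_experiment2 <- function(cohort, texts = study_texts(), seed = 1L,
                            profiles = NULL, assess = FALSE) {
  ids <- vapply(cohort, `[[`, "", "id")
  if (is.null(profiles)) {
    profiles <- if (assess) {
      lapply(seq_along(cohort), function(i) {
        run_assessment(cohort[[i]], seed = derive_seed(seed, 1000L + i))$profile
      })
    } else {
      lapply(cohort, oracle_profile)
    }
  }
  if (length(profiles) != length(cohort)) {
    stop("need one profile per reader", call. = FALSE)
  }
  names(profiles) <- ids
  assignment <- match_groups(cohort, seed = derive_seed(seed, 1L))
  plan <- crossover_assign(assignment, seed = derive_seed(seed, 2L))
  word_total <- sum(vapply(texts, function(tx) length(tx$words), 0L))

  # scripts depend only on (text, part, span, fixation time): cache them
  parts <- lapply(texts, function(tx) list(text_part(tx, 1), text_part(tx, 2)))
  script_cache <- new.env(parent = emptyenv())
  cached_script <- function(tx, part, profile) {
    key <- paste(tx, part, profile$span, profile$fixation_time_ms, sep = "_")
    if (is.null(script_cache[[key]])) {
      script_cache[[key]] <- build_script(parts[[tx]][[part]], profile)
    }
    script_cache[[key]]
  }

  rows <- vector("list", nrow(plan))
  for (ri in seq_len(nrow(plan))) {
    reader_id <- plan$reader[ri]
    params <- cohort[[match(reader_id, ids)]]
    profile <- profiles[[reader_id]]
    err <- c(0L, 0L); tm <- c(0, 0)
    for (session in 1:2) {
      part <- if (session == 1) plan$first_part[ri] else plan$second_part[ri]
      aided <- !is.na(plan$aided_part[ri]) && part == plan$aided_part[ri]
      for (tx in seq_along(texts)) {
        material <- parts[[tx]][[part]]
        log <- if (aided) {
          simulate_guided_reading(cached_script(tx, part, profile), params,
                                  seed = derive_seed(seed, ri * 100L + tx * 10L + session))
        } else {
          simulate_free_reading(material, params,
                                seed = derive_seed(seed, ri * 100L + tx * 10L + session))
        }
        err[session] <- err[session] + log$n_errors
        tm[session] <- tm[session] + log$total_time_s
      }
    }
    rows[[ri]] <- data.frame(
      reader = reader_id, group = plan$group[ri],
      first_part = plan$first_part[ri],
      errors_session1 = err[1], errors_session2 = err[2],
      time_s_session1 = tm[1], time_s_session2 = tm[2],
      stringsAsFactors = FALSE)
  }
  per_reader <- do.call(rbind, rows)

  analyze_group <- function(df, label) {
    g1 <- summarize_group(df$errors_session1)
    g2 <- summarize_group(df$errors_session2)
    es <- cohens_d(g1, g2)   # positive when errors decreased
    list(label = label,
         unaided = g1, second = g2, effect = es,
         p_value = wilcoxon_signed_rank(df$errors_session1,
                                        df$errors_session2)$p_value,
         percent_session1 = percent_of_total(g1$mean, word_total),
         percent_session2 = percent_of_total(g2$mean, word_total),
         mean_time_s = c(mean(df$time_s_session1), mean(df$time_s_session2)))
  }
  therapy <- analyze_group(per_reader[per_reader$group == "therapy", ],
                           "therapy")
  control <- analyze_group(per_reader[per_reader$group == "control", ],
                           "control")
  structure(list(per_reader = per_reader, therapy = therapy,
                 control = control,
                 contrast = d_contrast(therapy$effect, control$effect),
                 word_total = word_total, seed = seed),
            class = "experiment_result")
}
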