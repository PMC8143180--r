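# Serialization of profiles, reader parameters and analysis reports, and
# the command-line front end.  Structured documents use YAML; tabular logs
# are comma-separated files with headers.

#' Write / read a reader profile as YAML
#'
#' @param profile a [reader_profile()].
#' @param path file path.
#' @param seed optional seed recorded alongside the profile.
#' @return `read_profile` returns a `reader_profile`.
#' @export
write_profile <- function(profile, path, seed = NULL) {
  doc <- list(span = profile$span,
              fixation_time_ms = profile$fixation_time_ms,
              speech_onset_mean_ms = profile$speech_onset_mean_ms,
              at_floor = profile$at_floor, at_ceiling = profile$at_ceiling,
              budget_exhausted = profile$budget_exhausted,
              seed = seed)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  for (f in c("span", "fixation_time_ms")) {
    if (is.null(doc[[f]])) stop("profile file lacks field `", f, "`", call. = FALSE)
  }
  reader_profile(span = doc$span, fixation_time_ms = doc$fixation_time_ms,
                 speech_onset_mean_ms = doc$speech_onset_mean_ms %||% NA_real_,
                 at_floor = isTRUE(doc$at_floor),
                 at_ceiling = isTRUE(doc$at_ceiling),
                 budget_exhausted = isTRUE(doc$budget_exhausted))
}

#' Write / read synthetic reader parameters as YAML
#'
#' @param params a [sim_reader_params()].
#' @param path file path.
#' @return `read_reader_params` returns a `sim_reader_params`.
#' @export
write_reader_params <- function(params, path) {
  doc <- unclass(params)
  doc$error_mixture <- as.list(doc$error_mixture)
  doc$slope <- if (is.infinite(doc$slope)) ".inf" else doc$slope
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_reader_params
#' @export
read_reader_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$true_span) || is.null(doc$threshold_time_ms)) {
    stop("reader-parameter file needs `true_span` and `threshold_time_ms`",
         call. = FALSE)
  }
  defaults <- formals(sim_reader_params)
  args <- doc[intersect(names(doc), names(defaults))]
  if (!is.null(args$error_mixture)) {
    args$error_mixture <- unlist(args$error_mixture)
  }
  if (identical(args$slope, ".inf")) args$slope <- Inf
  args$true_span <- as.numeric(args$true_span)
  if (is.null(args$attempted_span)) args$attempted_span <- args$true_span
  do.call(sim_reader_params, args)
}

#' Write an analysis report of an experiment result
#'
#' @param result an `experiment_result` from [run_experiment2()].
#' @param path YAML output path.
#' @export
write_experiment_report <- function(result, path) {
  grp <- function(g) list(
    n = g$unaided$n,
    mean_errors = c(g$unaided$mean, g$second$mean),
    sd_errors = c(g$unaided$sd, g$second$sd),
    percent = c(g$percent_session1, g$percent_session2),
    mean_time_s = g$mean_time_s,
    cohen_d = g$effect$d, pooled_sd = g$effect$sw,
    ci = c(g$effect$ci_low, g$effect$ci_high),
    wilcoxon_p = g$p_value)
  yaml::write_yaml(list(seed = result$seed, word_total = result$word_total,
                        therapy = grp(result$therapy),
                        control = grp(result$control),
                        d_contrast = result$contrast), path)
  invisible(path)
}

cli_usage <- function() {
  paste(
    "usage: readguide <command> [--key value ...]",
    "",
    "commands:",
    "  assess        --params <yaml> [--seed N] --out <dir>",
    "  segment       --text <file> --profile <yaml> --out <file.json>",
    "  simulate      [--seed N] --out <dir>",
    "  analyze       --log <per-reader csv> --out <yaml>",
    "  gen-materials [--seed N] --out <dir>",
    "  demo          [--seed N] --out <dir>",
    sep = "\n")
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!startsWith(key, "--")) stop("unexpected argument: ", key, call. = FALSE)
    if (i == length(args)) stop("missing value for ", key, call. = FALSE)
    opts[[substring(key, 3)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see
#' `system.file("cli", "readguide", package = "readguide")` for the
#' executable wrapper.  Machine output goes to files; log messages go to
#' standard error.
#'
#' @param args character vector of command-line arguments (a command
#'   followed by `--key value` pairs).
#' @return integer exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      message(cli_usage())
      return(invisible(1L))
    }
    cmd <- args[[1]]
    opts <- parse_cli_args(args[-1])
    seed <- as.integer(opts$seed %||% "1")
    out <- opts$out %||% stop("--out is required", call. = FALSE)
    switch(
      cmd,
      assess = {
        params <- read_reader_params(opts$params %||%
                                       stop("--params is required", call. = FALSE))
        res <- run_assessment(params, seed = seed)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_profile(res$profile, file.path(out, "profile.yaml"), seed = seed)
        utils::write.csv(res$trials, file.path(out, "trials.csv"),
                         row.names = FALSE)
        message("profile: span ", res$profile$span, ", fixation ",
                res$profile$fixation_time_ms, " ms")
      },
      segment = {
        text <- read_text_material(opts$text %||%
                                     stop("--text is required", call. = FALSE))
        profile <- read_profile(opts$profile %||%
                                  stop("--profile is required", call. = FALSE))
        script <- build_script(text, profile)
        write_guidance_script(script, out)
        cat(nrow(script$segments), "\n")
      },
      simulate = {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        cohort <- table1_cohort(seed = seed)
        result <- run_experiment2(cohort, study_texts(), seed = seed)
        write_experiment_report(result, file.path(out, "summary.yaml"))
        utils::write.csv(result$per_reader,
                         file.path(out, "per_reader.csv"), row.names = FALSE)
        message("therapy d = ", round(result$therapy$effect$d, 3),
                ", contrast = ", round(result$contrast, 3))
      },
      analyze = {
        log <- utils::read.csv(opts$log %||%
                                 stop("--log is required", call. = FALSE))
        needed <- c("group", "errors_session1", "errors_session2")
        if (!all(needed %in% names(log))) {
          stop("log must have columns ", paste(needed, collapse = ", "),
               call. = FALSE)
        }
        res <- list(per_reader = log, word_total = sum(study_text_counts()$words))
        grp <- function(g) {
          df <- log[log$group == g, ]
          g1 <- summarize_group(df$errors_session1)
          g2 <- summarize_group(df$errors_session2)
          list(label = g, unaided = g1, second = g2,
               effect = cohens_d(g1, g2),
               p_value = wilcoxon_signed_rank(df$errors_session1,
                                              df$errors_session2)$p_value,
               percent_session1 = percent_of_total(g1$mean, res$word_total),
               percent_session2 = percent_of_total(g2$mean, res$word_total),
               mean_time_s = c(NA_real_, NA_real_))
        }
        res$therapy <- grp("therapy"); res$control <- grp("control")
        res$contrast <- d_contrast(res$therapy$effect, res$control$effect)
        res$seed <- seed
        write_experiment_report(structure(res, class = "experiment_result"), out)
      },
      `gen-materials` = {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        texts <- study_texts()
        for (i in seq_along(texts)) {
          write_text_material(texts[[i]], file.path(out, sprintf("text%d.txt", i)))
        }
        for (len in 2:6) {
          write_stimulus_list(generate_list(len, seed = derive_seed(seed, len)),
                              file.path(out, sprintf("list_%d.txt", len)))
        }
      },
      demo = {
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        reader <- sim_reader_params(true_span = 3, threshold_time_ms = 350)
        res <- run_assessment(reader, seed = seed)
        write_profile(res$profile, file.path(out, "profile.yaml"), seed = seed)
        script <- build_script(text_part(study_texts()[[1]], 1), res$profile)
        write_guidance_script(script, file.path(out, "script.json"))
        message("demo profile: span ", res$profile$span, " at ",
                res$profile$fixation_time_ms, " ms; ",
                nrow(script$segments), " segments")
      },
      stop("unknown command: ", cmd, "\n", cli_usage(), call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
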