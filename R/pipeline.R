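#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

default_config <- function() {
  list(
    seed = 0L,
    cohort = list(
      profiles = list(
        effective_efficient = 72L,
        effective_inefficient = 14L,
        ineffective_efficient = 152L,
        ineffective_inefficient = 22L
      )
    ),
    analysis = list(
      min_support = 0.30,
      max_len = 4L,
      alpha = 0.5,
      reps_transitions = 1000L,
      reps_entropy = 2000L,
      edge_threshold = 0.30,
      fdr_alpha = 0.05,
      k_max = 4L
    ),
    task = NULL,     # path to a YAML task config; NULL = built-in defaults
    out_dir = "inquiryflow-out"
  )
}

check_range <- function(value, name, lo, hi, open_lo = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      (open_lo && value <= lo) || (!open_lo && value < lo) || value > hi) {
    abort(paste0("Config value `", name, "` = ", value,
                 " is outside its allowed range (", if (open_lo) "(" else "[",
                 lo, ", ", hi, "])."))
  }
  invisible(value)
}

validate_config <- function(cfg) {
  known_top <- c("seed", "cohort", "analysis", "task", "out_dir")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) abort(paste0("Unknown config keys: ", paste(extra, collapse = ", ")))
  known_an <- names(default_config()$analysis)
  extra <- setdiff(names(cfg$analysis), known_an)
  if (length(extra)) abort(paste0("Unknown analysis keys: ", paste(extra, collapse = ", ")))
  if (is.null(cfg$seed)) abort("`seed` is mandatory.")
  an <- cfg$analysis
  check_range(an$min_support, "analysis.min_support", 0, 1, open_lo = TRUE)
  check_range(an$max_len, "analysis.max_len", 2, 10)
  check_range(an$alpha, "analysis.alpha", 0, 100)
  check_range(an$reps_transitions, "analysis.reps_transitions", 10, 1e6)
  check_range(an$reps_entropy, "analysis.reps_entropy", 10, 1e6)
  check_range(an$edge_threshold, "analysis.edge_threshold", 0, 1, open_lo = TRUE)
  check_range(an$fdr_alpha, "analysis.fdr_alpha", 0, 1, open_lo = TRUE)
  check_range(an$k_max, "analysis.k_max", 1, 8)
  bad <- setdiff(names(cfg$cohort$profiles), names(builtin_profiles()))
  if (length(bad)) abort(paste0("Unknown profiles in config: ", paste(bad, collapse = ", ")))
  if (any(unlist(cfg$cohort$profiles) < 1)) abort("Profile counts must be >= 1.")
  cfg
}

merge_defaults <- function(cfg, defaults = default_config()) {
  if (is.null(cfg)) return(defaults)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[nm] <- defaults[nm]
    } else if (is.list(defaults[[nm]]) && nm != "cohort") {
      cfg[[nm]] <- merge_defaults(cfg[[nm]], defaults[[nm]])
    }
  }
  cfg
}

#' Load (or build) a pipeline configuration
#'
#' Reads a YAML configuration, fills unset fields with the documented
#' defaults (support threshold 0.30, pattern length cap 4, smoothing
#' concentration 0.5, 1000/2000 bootstrap resamples, edge display threshold
#' 0.30, FDR 0.05, seed 0), and validates ranges. An empty file yields the
#' pure defaults; unknown keys or out-of-range values are rejected with the
#' offenders listed.
#'
#' @param path YAML file path; `NULL` for pure defaults.
#' @return Validated config list of class `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_defaults(cfg)
  cfg <- validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname load_config
#' @param config A `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# deterministic per-stage child seeds from the single pipeline seed, so each
# stage is also reproducible standalone
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, profile = 2L, entropy = 3L, transitions = 4L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% 2147483647L
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", as.character(signif(x, digits)))
}

write_table <- function(df, path, digits = 6) {
  df <- mutate(df, across(dplyr::where(is.numeric), ~ fmt_num(.x, digits)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order: simulate (or ingest) raw event logs, code
#' them into micro/macro sequences, form the 2 x 2 performance subgroups,
#' run the macro-level analyses (rate models, state distributions, pattern
#' mining) across effectiveness groups, run the micro-level analyses
#' (entropy comparison, smoothed transition models, delta probability maps,
#' process graphs) across efficiency profiles within each effectiveness
#' group, and write all artifacts as fixed-format text files into the
#' configured output directory. Identical config and seed yield identical
#' artifacts.
#'
#' @param config A `pipeline_config` from [load_config()].
#' @param events Optional user-supplied raw events tibble; if `NULL`, a
#'   cohort is simulated from the configured profiles.
#' @return A `run_report` list: per-stage artifact paths and summary
#'   statistics (also written as `report.json`).
#' @export
run_pipeline <- function(config, events = NULL) {
  config <- validate_config(merge_defaults(unclass(config)))
  an <- config$analysis
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  task <- if (is.null(config$task)) hpp_task() else read_task_config(config$task)
  artifacts <- list()
  summaries <- list()

  # -- simulate ----------------------------------------------------------
  if (is.null(events)) {
    profs <- builtin_profiles()[names(config$cohort$profiles)]
    cohort <- generate_cohort(profs, n = unlist(config$cohort$profiles),
                              task = task, seed = stage_seed(config$seed, "simulate"))
    events <- cohort$events
    artifacts$events <- write_event_log(events, file.path(out, "events.jsonl"))
    artifacts$truth <- write_table(cohort$truth, file.path(out, "truth.csv"))
  }
  summaries$n_students <- dplyr::n_distinct(events$student_id)
  summaries$n_events <- nrow(events)

  # -- code --------------------------------------------------------------
  coded <- code_events(events)
  artifacts$coded <- write_table(coded, file.path(out, "coded_sequences.csv"))
  summ <- sequence_summary(coded)
  artifacts$summary <- write_table(summ, file.path(out, "sequence_summary.csv"))

  # -- profile -----------------------------------------------------------
  answers <- final_answers(events)
  sg <- performance_subgroups(coded, answers, task = task, K_max = an$k_max,
                              seed = stage_seed(config$seed, "profile"))
  artifacts$assignments <- write_table(sg$assignments, file.path(out, "assignments.csv"))
  artifacts$model_selection <- write_table(sg$selection, file.path(out, "model_selection.csv"))
  summaries$subgroups <- as.list(table(sg$assignments$subgroup))
  summaries$prop_effective <- mean(sg$assignments$effectiveness == "Effective")

  groups <- select(sg$assignments, "student_id", group = "effectiveness")

  # -- macro -------------------------------------------------------------
  rates <- rate_comparison(coded, groups, reference = "Effective")
  artifacts$rates <- write_table(rates, file.path(out, "macro_rates.csv"))
  for (g in unique(groups$group)) {
    sd_g <- state_distribution(
      coded[coded$student_id %in% groups$student_id[groups$group == g], ]
    )
    artifacts[[paste0("state_distribution_", g)]] <-
      write_table(sd_g, file.path(out, paste0("state_distribution_", tolower(g), ".csv")))
  }
  patterns <- mine_patterns(coded, groups, min_support = an$min_support,
                            max_len = an$max_len, alpha = an$fdr_alpha)
  artifacts$patterns <- write_table(patterns, file.path(out, "macro_patterns.csv"))
  summaries$n_patterns_retained <- sum(patterns$retained)

  # -- micro -------------------------------------------------------------
  ent <- entropy_by_student(coded) |>
    left_join(select(sg$assignments, "student_id", "effectiveness", "efficiency"),
              by = "student_id")
  artifacts$entropy <- write_table(ent, file.path(out, "entropy.csv"))
  ec <- entropy_group_comparison(ent, B = an$reps_entropy,
                                 seed = stage_seed(config$seed, "entropy"))
  artifacts$entropy_summary <- {
    p <- file.path(out, "entropy_summary.json")
    jsonlite::write_json(
      list(means = ec$means, anova = ec$anova),
      p, dataframe = "rows", auto_unbox = TRUE, digits = 8, null = "null"
    )
    p
  }

  prior <- estimate_transitions(coded, prior = NULL)
  seqs <- sequences_of(coded, "micro")
  asg <- sg$assignments
  tseed <- stage_seed(config$seed, "transitions")
  for (g in unique(asg$effectiveness)) {
    eff_lv <- unique(asg$efficiency[asg$effectiveness == g])
    if (length(eff_lv) < 2L) next
    ids_a <- asg$student_id[asg$effectiveness == g & asg$efficiency == "Efficient"]
    ids_b <- asg$student_id[asg$effectiveness == g & asg$efficiency != "Efficient"]
    if (length(ids_a) < 2L || length(ids_b) < 2L) next
    dm <- bootstrap_deltas(seqs[ids_a], seqs[ids_b], prior = prior,
                           alpha = an$alpha, B = an$reps_transitions, seed = tseed)
    tag <- tolower(g)
    artifacts[[paste0("delta_map_", tag)]] <-
      write_table(tidy.hpp_delta_map(dm), file.path(out, paste0("delta_map_", tag, ".csv")))
    for (side in c("a", "b")) {
      tm <- if (side == "a") dm$matrix_a else dm$matrix_b
      lab <- paste0(tag, "_", ifelse(side == "a", "efficient", "inefficient"))
      artifacts[[paste0("transitions_", lab)]] <-
        write_table(tidy.hpp_transitions(tm), file.path(out, paste0("transitions_", lab, ".csv")))
      gr <- build_process_graph(tm, threshold = an$edge_threshold, comparison = dm)
      artifacts[[paste0("graph_", lab)]] <-
        write_process_dot(gr, file.path(out, paste0("process_", lab, ".dot")))
    }
  }

  report <- list(
    seed = config$seed,
    parameters = an,
    artifacts = lapply(artifacts, normalizePath),
    summaries = summaries,
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  report$artifacts$report <- file.path(out, "report.json")
  missing <- !vapply(report$artifacts, file.exists, logical(1))
  if (any(missing)) {
    abort(paste0("Pipeline finished but artifacts missing: ",
                 paste(names(report$artifacts)[missing], collapse = ", ")))
  }
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "|", length(x$artifacts), "artifacts\n")
  cat("students:", x$summaries$n_students,
      "| effective:", round(x$summaries$prop_effective, 3),
      "| retained patterns:", x$summaries$n_patterns_retained, "\n")
  invisible(x)
}
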