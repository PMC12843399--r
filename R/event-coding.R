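#' Behavior code alphabets
#'
#' The two-level coding scheme maps raw interface events onto a closed
#' alphabet of eight micro-level behavior codes, each of which belongs to
#' exactly one of six macro-level inquiry phases:
#'
#' * DESIGN: Adjust Gate, Adjust Diameter
#' * CONDUCT: Run Trial
#' * ANSWER: Initial Answer, Revise Answer
#' * MANAGE: Remove Record
#' * START / END: Start Task / End Task
#'
#' @return Character vectors of code names.
#' @export
micro_codes <- function() {
  c("Start Task", "Adjust Gate", "Adjust Diameter", "Run Trial",
    "Initial Answer", "Revise Answer", "Remove Record", "End Task")
}

#' @rdname micro_codes
#' @export
macro_codes <- function() {
  c("START", "DESIGN", "CONDUCT", "ANSWER", "MANAGE", "END")
}

#' @rdname micro_codes
#' @param micro Character vector of micro-level codes.
#' @export
macro_of <- function(micro) {
  map <- c(
    "Start Task" = "START",
    "Adjust Gate" = "DESIGN",
    "Adjust Diameter" = "DESIGN",
    "Run Trial" = "CONDUCT",
    "Initial Answer" = "ANSWER",
    "Revise Answer" = "ANSWER",
    "Remove Record" = "MANAGE",
    "End Task" = "END"
  )
  bad <- !micro %in% names(map)
  if (any(bad)) abort(paste0("Unknown micro code: ", paste(unique(micro[bad]), collapse = ", ")))
  unname(map[micro])
}

event_types <- function() {
  c("start_task", "adjust_gate", "adjust_diameter", "run_trial",
    "edit_answer", "delete_record", "end_task")
}

coding_error <- function(student, position, msg) {
  abort(paste0("Invalid event stream for student ", student,
               " at position ", position, ": ", msg))
}

validate_events_one <- function(ev, student) {
  n <- nrow(ev)
  if (n < 2L) coding_error(student, n, "fewer than two events")
  bad <- which(!ev$event %in% event_types())
  if (length(bad)) coding_error(student, bad[1], paste0("unknown event type '", ev$event[bad[1]], "'"))
  if (ev$event[1] != "start_task") coding_error(student, 1, "first event is not start_task")
  if (ev$event[n] != "end_task") coding_error(student, n, "last event is not end_task")
  extra_start <- which(ev$event == "start_task")[-1]
  if (length(extra_start)) coding_error(student, extra_start[1], "repeated start_task")
  ends <- which(ev$event == "end_task")
  if (length(ends) > 1L) coding_error(student, ends[2], "event after end_task")
  if (any(diff(ev$t) < 0)) {
    coding_error(student, which(diff(ev$t) < 0)[1] + 1L, "timestamps decrease")
  }
  invisible(TRUE)
}

code_one <- function(ev, student) {
  validate_events_one(ev, student)
  is_edit <- ev$event == "edit_answer"
  # collapse maximal runs of consecutive edit_answer events into episodes
  r <- rle(is_edit)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  keep <- !is_edit | !duplicated(run_id)
  kept <- ev[keep, , drop = FALSE]
  ep_rank <- cumsum(kept$event == "edit_answer")
  micro <- dplyr::case_when(
    kept$event == "start_task" ~ "Start Task",
    kept$event == "adjust_gate" ~ "Adjust Gate",
    kept$event == "adjust_diameter" ~ "Adjust Diameter",
    kept$event == "run_trial" ~ "Run Trial",
    kept$event == "delete_record" ~ "Remove Record",
    kept$event == "edit_answer" & ep_rank == 1L ~ "Initial Answer",
    kept$event == "edit_answer" ~ "Revise Answer",
    kept$event == "end_task" ~ "End Task"
  )
  tibble(
    student_id = student,
    position = seq_along(micro),
    micro = micro,
    macro = macro_of(micro),
    t = kept$t
  )
}

#' Code raw interface event logs into behavior sequences
#'
#' Translates each student's chronologically ordered interface events into
#' parallel micro- and macro-level behavior sequences. Variable adjustments,
#' trial runs and record deletions map one-to-one onto micro codes; maximal
#' runs of consecutive answer-element edits collapse into a single answer
#' episode, the first of which is coded Initial Answer and every later one
#' Revise Answer. Event streams violating the task grammar (missing or
#' repeated start/end, events after end, decreasing timestamps) raise a
#' coding error naming the offending position.
#'
#' @param events Tibble of raw events with columns `student_id`, `t`
#'   (seconds), `event` (one of start_task, adjust_gate, adjust_diameter,
#'   run_trial, edit_answer, delete_record, end_task); extra payload columns
#'   are ignored.
#' @return A tibble of class `hpp_coded` with one row per coded behavior:
#'   `student_id`, `position`, `micro`, `macro`, `t`.
#' @seealso [sequence_summary()] for per-student length/time metadata.
#' @export
code_events <- function(events) {
  events <- as_tibble(events)
  stopifnot(all(c("student_id", "t", "event") %in% names(events)))
  out <- events |>
    group_by(.data$student_id) |>
    dplyr::group_map(~ code_one(.x, .y$student_id)) |>
    bind_rows()
  class(out) <- c("hpp_coded", class(out))
  out
}

#' Per-student sequence metadata
#'
#' Summarises a coded cohort into one row per student: completion time
#' (seconds between Start Task and End Task) and sequence length (total
#' number of micro-level behaviors).
#'
#' @param coded Output of [code_events()].
#' @return Tibble with columns `student_id`, `completion_time`,
#'   `sequence_length`.
#' @export
sequence_summary <- function(coded) {
  coded |>
    group_by(.data$student_id) |>
    summarise(
      completion_time = dplyr::last(.data$t) - dplyr::first(.data$t),
      sequence_length = dplyr::n(),
      .groups = "drop"
    )
}

#' Split a coded cohort into per-student micro sequences
#'
#' @param coded Output of [code_events()].
#' @param level `"micro"` or `"macro"`.
#' @return Named list of character vectors, one per student.
#' @export
sequences_of <- function(coded, level = c("micro", "macro")) {
  level <- match.arg(level)
  split(coded[[level]], coded$student_id)
}

#' Cohen's kappa for two aligned codings
#'
#' Chance-corrected agreement between two raters' code sequences over the
#' same events, together with raw percent agreement. Used to validate
#' alternative coder implementations against fixtures.
#'
#' @param codes_a,codes_b Equal-length character vectors of codes.
#' @return A list with elements `kappa`, `agreement` (proportion in
#'   \[0, 1\]) and `table` (the confusion matrix).
#' @export
cohens_kappa <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) abort("Code vectors must have equal length.")
  if (length(codes_a) < 2L) abort("Need at least two paired codes.")
  lev <- sort(union(codes_a, codes_b))
  tab <- table(factor(codes_a, levels = lev), factor(codes_b, levels = lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, agreement = po, table = tab)
}

#' Groupwise sequence statistics with Welch comparisons
#'
#' Means and standard deviations of per-student metrics (completion time,
#' sequence length) by group, plus Welch's t-tests (unequal variances,
#' Satterthwaite degrees of freedom) for all pairwise group contrasts.
#'
#' @param summary_df Tibble with one row per student, e.g. from
#'   [sequence_summary()], plus a grouping column.
#' @param group Name of the grouping column (string).
#' @param metrics Character vector of metric columns to summarise.
#' @return A list with `summary` (group x metric means/SDs) and `tests`
#'   (pairwise Welch results: `t`, `df`, `p`); groups with fewer than two
#'   students, or zero-variance contrasts, are skipped with a notice column.
#' @export
sequence_stats <- function(summary_df,
                           group,
                           metrics = c("completion_time", "sequence_length")) {
  summary_df <- as_tibble(summary_df)
  stopifnot(group %in% names(summary_df), all(metrics %in% names(summary_df)))
  long <- summary_df |>
    tidyr::pivot_longer(all_of(metrics), names_to = "metric", values_to = "value")
  summ <- long |>
    group_by(.data$metric, grp = .data[[group]]) |>
    summarise(n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop") |>
    rename(!!group := "grp")

  grps <- unique(summary_df[[group]])
  tests <- NULL
  if (length(grps) >= 2L) {
    pairs <- utils::combn(as.character(grps), 2L, simplify = FALSE)
    tests <- purrr::map_dfr(pairs, function(pr) {
      purrr::map_dfr(metrics, function(m) {
        xa <- summary_df[[m]][summary_df[[group]] == pr[1]]
        xb <- summary_df[[m]][summary_df[[group]] == pr[2]]
        base <- tibble(metric = m, group_a = pr[1], group_b = pr[2])
        if (length(xa) < 2L || length(xb) < 2L) {
          return(mutate(base, t = NA_real_, df = NA_real_, p = NA_real_,
                        note = "skipped: fewer than 2 per group"))
        }
        if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
          if (mean(xa) == mean(xb)) {
            return(mutate(base, t = 0, df = NA_real_, p = NA_real_,
                          note = "zero variance in both groups"))
          }
          return(mutate(base, t = NA_real_, df = NA_real_, p = NA_real_,
                        note = "skipped: zero variance"))
        }
        ht <- stats::t.test(xa, xb, var.equal = FALSE)
        mutate(base, t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, note = NA_character_)
      })
    })
  }
  list(summary = summ, tests = tests)
}

# Rebuild a minimal raw event stream from a coded sequence (one edit per
# answer episode); used to check that coding is idempotent.
events_from_coded <- function(coded_one) {
  ev <- dplyr::case_match(
    coded_one$micro,
    "Start Task" ~ "start_task",
    "Adjust Gate" ~ "adjust_gate",
    "Adjust Diameter" ~ "adjust_diameter",
    "Run Trial" ~ "run_trial",
    "Initial Answer" ~ "edit_answer",
    "Revise Answer" ~ "edit_answer",
    "Remove Record" ~ "delete_record",
    "End Task" ~ "end_task"
  )
  tibble(student_id = coded_one$student_id, t = coded_one$t, event = ev)
}
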