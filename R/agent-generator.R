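#' Construct a behavioral profile for the agent simulator
#'
#' A profile is a stationary first-order Markov chain over the eight
#' micro-level behavior codes together with per-behavior dwell-time
#' distributions and an answer policy. Agents sample behavior order from
#' the chain (with light grammar repairs, see [generate_cohort()]), dwell
#' times from a log-normal distribution per behavior, and submit the
#' optimal answer triple with probability `answer_policy` (otherwise a
#' random non-optimal safe condition).
#'
#' @param name Profile label, e.g. `"effective_efficient"`.
#' @param transition_matrix 8 x 8 row-stochastic matrix with
#'   [micro_codes()] dimnames. The Start Task column must be zero (no
#'   incoming mass) and the End Task row must be zero (absorbing).
#' @param dwell_meanlog Named numeric vector: log-normal meanlog per
#'   behavior (seconds scale); a single unnamed value is recycled.
#' @param dwell_sdlog Log-normal sdlog, single value or per behavior.
#' @param answer_policy Probability in \[0, 1\] that the submitted final
#'   triple is the optimum.
#' @param time_mean,time_sd Optional completion-time distribution (seconds):
#'   when supplied, each student's total time is drawn from a
#'   positive-truncated Normal(time_mean, time_sd) and the per-behavior
#'   dwell draws are rescaled to sum to it, so the dwell parameters set the
#'   relative pacing of behaviors while cohort completion times follow the
#'   stated normal component (students pacing themselves to a time budget).
#'   When `NULL`, timestamps are the raw cumulative dwell sums.
#' @param max_steps Cap on chain length before generation fails.
#' @return Object of class `behavior_profile`.
#' @export
behavior_profile <- function(name, transition_matrix, dwell_meanlog,
                             dwell_sdlog = 0.5, answer_policy = 0.5,
                             time_mean = NULL, time_sd = NULL,
                             max_steps = 200L) {
  codes <- micro_codes()
  tm <- as.matrix(transition_matrix)
  if (!identical(dim(tm), c(8L, 8L)) ||
      !identical(rownames(tm), codes) || !identical(colnames(tm), codes)) {
    abort("`transition_matrix` must be 8 x 8 with micro_codes() dimnames.")
  }
  if (any(tm < 0)) abort("Transition probabilities must be non-negative.")
  if (any(tm[, "Start Task"] != 0)) abort("Start Task must have no incoming mass.")
  if (any(tm["End Task", ] != 0)) abort("End Task must be absorbing (no outgoing mass).")
  active <- setdiff(codes, "End Task")
  rs <- rowSums(tm[active, ])
  if (any(abs(rs - 1) > 1e-9)) {
    abort(paste0("Rows must sum to 1; offending: ",
                 paste(active[abs(rs - 1) > 1e-9], collapse = ", ")))
  }
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 8L), codes)
    if (!all(codes %in% names(x))) abort(paste0("`", what, "` must cover all micro codes."))
    x[codes]
  }
  dwell_meanlog <- expand(dwell_meanlog, "dwell_meanlog")
  dwell_sdlog <- expand(dwell_sdlog, "dwell_sdlog")
  if (any(dwell_sdlog < 0)) abort("`dwell_sdlog` must be non-negative.")
  if (answer_policy < 0 || answer_policy > 1) abort("`answer_policy` must be in [0, 1].")
  if (!is.null(time_mean) && (time_mean <= 0 || is.null(time_sd) || time_sd <= 0)) {
    abort("`time_mean` and `time_sd` must both be positive when supplied.")
  }
  structure(
    list(name = name, transition_matrix = tm, dwell_meanlog = dwell_meanlog,
         dwell_sdlog = dwell_sdlog, answer_policy = answer_policy,
         time_mean = time_mean, time_sd = time_sd,
         max_steps = as.integer(max_steps)),
    class = "behavior_profile"
  )
}

#' @export
print.behavior_profile <- function(x, ...) {
  cat("<behavior_profile>", x$name,
      "| answer_policy", x$answer_policy,
      "| E[length] ~", round(expected_sequence_length(x), 1), "\n")
  invisible(x)
}

#' Expected micro sequence length of a profile
#'
#' Computed from the fundamental matrix of the absorbing chain: the expected
#' number of behavior codes (including Start Task and End Task) in a
#' sequence generated from the profile, ignoring grammar repairs.
#'
#' @param profile A [behavior_profile()].
#' @return Expected sequence length (numeric).
#' @export
expected_sequence_length <- function(profile) {
  codes <- micro_codes()
  transient <- setdiff(codes, "End Task")
  Q <- profile$transition_matrix[transient, transient]
  N <- solve(diag(length(transient)) - Q)
  sum(N["Start Task", ]) + 1
}

profile_matrix <- function(rows) {
  codes <- micro_codes()
  tm <- matrix(0, 8, 8, dimnames = list(codes, codes))
  for (nm in names(rows)) tm[nm, names(rows[[nm]])] <- rows[[nm]]
  tm
}

#' Built-in behavioral profiles
#'
#' Four presets spanning the 2 x 2 performance design (effectiveness x
#' efficiency). Their qualitative signatures mirror the field's typical
#' findings for this task family: efficient-effective agents open with a
#' tentative answer and then iterate tight design-trial cycles; inefficient
#' but effective agents run default trials, cycle through diameter
#' adjustments and record deletions, and take much longer; ineffective
#' agents answer almost immediately (efficient) or wander through
#' unsystematic adjustments (inefficient). Dwell scales are set so mean
#' completion times are ordered efficient < inefficient within each
#' effectiveness level, and answer policies give high correctness for the
#' effective presets only.
#'
#' The transition matrices are the process law of the grammar-constrained
#' agent (the Initial/Revise split of each row's answer mass matches the
#' realized first/later-answer shares), so empirical coded transition
#' frequencies converge to these matrices.
#'
#' @return Named list of four [behavior_profile()] objects.
#' @export
builtin_profiles <- function() {
  list(
    effective_efficient = behavior_profile(
      name = "effective_efficient",
      transition_matrix = builtin_matrix("effective_efficient"),
      dwell_meanlog = builtin_dwell("effective_efficient"),
      dwell_sdlog = 0.45,
      answer_policy = 0.97,
      time_mean = 81.01, time_sd = 27.58
    ),
    effective_inefficient = behavior_profile(
      name = "effective_inefficient",
      transition_matrix = builtin_matrix("effective_inefficient"),
      dwell_meanlog = builtin_dwell("effective_inefficient"),
      dwell_sdlog = 0.45,
      answer_policy = 0.95,
      time_mean = 196.71, time_sd = 45.59
    ),
    ineffective_efficient = behavior_profile(
      name = "ineffective_efficient",
      transition_matrix = builtin_matrix("ineffective_efficient"),
      dwell_meanlog = builtin_dwell("ineffective_efficient"),
      dwell_sdlog = 0.45,
      answer_policy = 0.02,
      time_mean = 62.09, time_sd = 20.05
    ),
    ineffective_inefficient = behavior_profile(
      name = "ineffective_inefficient",
      transition_matrix = builtin_matrix("ineffective_inefficient"),
      dwell_meanlog = builtin_dwell("ineffective_inefficient"),
      dwell_sdlog = 0.45,
      answer_policy = 0.02,
      time_mean = 144.09, time_sd = 42.63
    )
  )
}

sample_from <- function(probs) {
  sample(names(probs), 1L, prob = probs)
}

other_levels <- function(current, levels) setdiff(levels, current)

simulate_micro_path <- function(profile) {
  tm <- profile$transition_matrix
  path <- "Start Task"
  cur <- "Start Task"
  answered <- FALSE
  n_records <- 0L
  repeat {
    if (length(path) >= profile$max_steps) {
      abort(paste0("Profile '", profile$name,
                   "' failed to reach End Task within max_steps (",
                   profile$max_steps, ")."))
    }
    row <- tm[cur, ]
    nxt <- sample_from(row)
    if (nxt == "Remove Record" && n_records == 0L) {
      row2 <- row
      row2["Remove Record"] <- 0
      if (sum(row2) <= 0) {
        abort(paste0("Profile '", profile$name,
                     "' is stuck: only Remove Record available with no records."))
      }
      nxt <- sample_from(row2 / sum(row2))
    }
    # answer identity follows episode order regardless of the sampled label
    if (nxt == "Initial Answer" && answered) nxt <- "Revise Answer"
    if (nxt == "Revise Answer" && !answered) nxt <- "Initial Answer"
    if (nxt == "End Task" && !answered) {
      # the interface refuses an incomplete submission: force an answer first
      path <- c(path, "Initial Answer")
      answered <- TRUE
    }
    path <- c(path, nxt)
    if (nxt == "Initial Answer") answered <- TRUE
    if (nxt == "Run Trial") n_records <- n_records + 1L
    if (nxt == "Remove Record") n_records <- n_records - 1L
    cur <- nxt
    if (nxt == "End Task") break
  }
  path
}

random_safe_nonoptimal <- function(task) {
  safe <- task$rpm |>
    filter(.data$rpm < task$safety_limit) |>
    dplyr::anti_join(task$optimum, by = c("gate", "diameter"))
  safe[sample.int(nrow(safe), 1L), ]
}

simulate_student <- function(profile, task, student_id) {
  path <- simulate_micro_path(profile)
  n <- length(path)
  dwell <- c(0, stats::rlnorm(n - 1L,
                              meanlog = profile$dwell_meanlog[path[-1L]],
                              sdlog = profile$dwell_sdlog[path[-1L]]))
  if (!is.null(profile$time_mean)) {
    repeat {
      total <- stats::rnorm(1, profile$time_mean, profile$time_sd)
      if (total > 0) break
    }
    dwell <- dwell * total / sum(dwell)
  }
  t <- cumsum(dwell)

  final <- if (stats::runif(1) < profile$answer_policy) {
    task$optimum
  } else {
    random_safe_nonoptimal(task)
  }

  ans_idx <- which(path %in% c("Initial Answer", "Revise Answer"))
  last_ans <- max(ans_idx)

  gate <- gate_levels()[1]
  diameter <- diameter_levels()[1]
  ans <- c(gate = NA_character_, diameter = NA_character_, speed = NA_character_)
  live_records <- integer(0)
  trial_no <- 0L
  rows <- vector("list", n)

  ev_row <- function(t, event, gate = NA, diameter = NA, element = NA,
                     value = NA, rpm = NA, record = NA) {
    tibble(student_id = student_id, t = t, event = event,
           gate = as.character(gate), diameter = as.character(diameter),
           element = as.character(element), value = as.character(value),
           rpm = as.numeric(rpm), record = as.integer(record))
  }

  emit_episode <- function(i) {
    target <- if (i == last_ans) {
      c(gate = final$gate[1], diameter = final$diameter[1],
        speed = as.character(final$rpm[1]))
    } else if (path[i] == "Initial Answer") {
      w <- task$rpm[sample.int(9L, 1L), ]
      c(gate = w$gate[1], diameter = w$diameter[1], speed = as.character(w$rpm[1]))
    } else {
      w <- task$rpm[sample.int(9L, 1L), ]
      pick <- sample(c("gate", "diameter", "speed"), sample.int(3L, 1L))
      out <- ans
      out[pick] <- c(gate = w$gate[1], diameter = w$diameter[1],
                     speed = as.character(w$rpm[1]))[pick]
      out
    }
    edit <- if (path[i] == "Initial Answer") {
      c("gate", "diameter", "speed")
    } else {
      changed <- names(target)[!is.na(target) & (is.na(ans) | target != ans)]
      if (length(changed) == 0L) "speed" else changed
    }
    ans[edit] <<- target[edit]
    bind_rows(lapply(edit, function(el) {
      ev_row(t[i], "edit_answer", element = el, value = ans[[el]])
    }))
  }

  for (i in seq_len(n)) {
    code <- path[i]
    rows[[i]] <- switch(
      code,
      "Start Task" = ev_row(t[i], "start_task"),
      "End Task" = ev_row(t[i], "end_task"),
      "Adjust Gate" = {
        gate <- sample(other_levels(gate, gate_levels()), 1L)
        ev_row(t[i], "adjust_gate", gate = gate)
      },
      "Adjust Diameter" = {
        diameter <- sample(other_levels(diameter, diameter_levels()), 1L)
        ev_row(t[i], "adjust_diameter", diameter = diameter)
      },
      "Run Trial" = {
        trial_no <- trial_no + 1L
        live_records <- c(live_records, trial_no)
        ev_row(t[i], "run_trial", gate = gate, diameter = diameter,
               rpm = rotation_speed(task, gate, diameter))
      },
      "Remove Record" = {
        del <- live_records[sample.int(length(live_records), 1L)]
        live_records <- setdiff(live_records, del)
        ev_row(t[i], "delete_record", record = del)
      },
      emit_episode(i)
    )
  }
  list(
    events = bind_rows(rows),
    truth = tibble(
      student_id = student_id,
      profile = profile$name,
      answer_gate = ans[["gate"]],
      answer_diameter = ans[["diameter"]],
      answer_speed = as.numeric(ans[["speed"]])
    )
  )
}

#' Generate a synthetic cohort of interface event logs
#'
#' Agent-based simulation of raw event logs. Each agent samples its
#' behavior order from its profile's first-order chain; the task grammar is
#' honoured by construction (the first answer episode is Initial Answer and
#' later ones Revise Answer irrespective of the sampled label, record
#' deletion targets an existing data row, and an attempted End Task before
#' any answer forces a completing answer episode first). Trial outcomes in
#' `run_trial` payloads come from [rotation_speed()] at the agent's current
#' settings, and the final submitted triple is the optimum with the
#' profile's `answer_policy` probability.
#'
#' @param profiles A [behavior_profile()], or list of them (e.g.
#'   [builtin_profiles()]).
#' @param n Integer count per profile (recycled or matched by position).
#' @param task An [hpp_task()].
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return Object of class `hpp_cohort`: list with `events` (one row per
#'   raw event: `student_id`, `t`, `event` and flattened payload columns)
#'   and `truth` (per-student ground-truth profile label and submitted
#'   answer). Profiles (with their true transition matrices) are attached
#'   as attribute `profiles`.
#' @examples
#' cohort <- generate_cohort(builtin_profiles()[["effective_efficient"]],
#'                           n = 5, seed = 1)
#' code_events(cohort$events)
#' @export
generate_cohort <- function(profiles, n, task = hpp_task(), seed) {
  if (inherits(profiles, "behavior_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, TRUE, "behavior_profile")))
  n <- as.integer(rep(n, length.out = length(profiles)))
  if (any(n < 1L)) abort("Each profile count must be >= 1.")
  if (sum(n) < 2L) abort("A cohort needs at least 2 students.")
  if (missing(seed) || is.null(seed)) abort("`seed` is required for reproducibility.")

  withr::local_seed(seed)
  width <- nchar(as.character(sum(n)))
  sid <- sprintf(paste0("S%0", width, "d"), seq_len(sum(n)))
  k <- 0L
  out <- vector("list", sum(n))
  for (p in seq_along(profiles)) {
    for (j in seq_len(n[p])) {
      k <- k + 1L
      out[[k]] <- simulate_student(profiles[[p]], task, sid[k])
    }
  }
  res <- list(
    events = bind_rows(lapply(out, `[[`, "events")),
    truth = bind_rows(lapply(out, `[[`, "truth"))
  )
  attr(res, "profiles") <- profiles
  class(res) <- "hpp_cohort"
  res
}

#' @export
print.hpp_cohort <- function(x, ...) {
  cat("<hpp_cohort>", dplyr::n_distinct(x$truth$student_id), "students,",
      nrow(x$events), "events\n")
  print(count(x$truth, .data$profile))
  invisible(x)
}

#' Read and write raw event logs
#'
#' Event logs are exchanged as JSONL (one event object per line, with a
#' nested `payload`) or as CSV with flattened payload columns.
#'
#' @param events Events tibble (as in `generate_cohort()$events`).
#' @param path Output/input file path; format chosen by extension
#'   (`.jsonl` or `.csv`).
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns an events tibble.
#' @export
write_event_log <- function(events, path) {
  if (grepl("\\.jsonl$", path)) {
    payload_cols <- setdiff(names(events), c("student_id", "t", "event"))
    lines <- vapply(seq_len(nrow(events)), function(i) {
      row <- events[i, ]
      payload <- as.list(row[payload_cols])
      payload <- payload[!vapply(payload, function(v) is.na(v), TRUE)]
      jsonlite::toJSON(
        c(list(student_id = row$student_id, t = row$t, event = row$event),
          list(payload = payload)),
        auto_unbox = TRUE, digits = NA, null = "null"
      )
    }, character(1))
    writeLines(lines, path)
  } else {
    utils::write.csv(events, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    bind_rows(lapply(recs, function(r) {
      p <- r$payload
      tibble(
        student_id = r$student_id, t = as.numeric(r$t), event = r$event,
        gate = as.character(p$gate %||% NA), diameter = as.character(p$diameter %||% NA),
        element = as.character(p$element %||% NA), value = as.character(p$value %||% NA),
        rpm = as.numeric(p$rpm %||% NA), record = as.integer(p$record %||% NA)
      )
    }))
  } else {
    out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           colClasses = c(student_id = "character"))
    as_tibble(out) |>
      mutate(across(c("gate", "diameter", "element", "value"), as.character),
             rpm = as.numeric(.data$rpm), record = as.integer(.data$record),
             t = as.numeric(.data$t))
  }
}
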