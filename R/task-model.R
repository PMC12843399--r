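#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n across all_of count slice pull rename
#'   distinct
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap keep
NULL

#' Factor levels of the two manipulable task variables
#'
#' The Hydroelectric Power Plant task exposes two independent variables:
#' the gate position with three ordered levels (Low, Medium, High) and the
#' inlet diameter with three ordered levels (40, 80, 120 cm).
#'
#' @return Character vector of levels in increasing order.
#' @export
gate_levels <- function() c("Low", "Medium", "High")

#' @rdname gate_levels
#' @export
diameter_levels <- function() c("40", "80", "120")

# Default rpm outcome table. Three cells are fixed by the task narrative
# (Medium/120 = 309 optimal, High/120 = 438 over the limit, High/80 = 292
# next-best safe); the remainder are chosen strictly monotone in both factors
# with every non-optimal safe cell below 309.
default_rpm <- function() {
  tibble(
    gate     = rep(gate_levels(), each = 3L),
    diameter = rep(diameter_levels(), times = 3L),
    rpm      = c(76, 124, 208, 118, 196, 309, 163, 292, 438)
  )
}

#' Construct a Hydroelectric Power Plant task definition
#'
#' Defines the task environment: a nine-cell outcome table mapping each
#' gate position x inlet diameter combination to a water-wheel rotation
#' speed (rpm), and a safety limit. The correct answer is the unique cell
#' with the maximal rotation speed strictly below the safety limit.
#'
#' @param rpm Optional tibble/data frame with columns `gate`, `diameter`,
#'   `rpm` covering all nine combinations. Defaults to the built-in table.
#' @param safety_limit Safety threshold in rpm (default 400).
#' @param check Validate the table on construction (default `TRUE`).
#'
#' @return An object of class `hpp_task`: a list with elements `rpm`
#'   (nine-row tibble), `safety_limit`, and `optimum` (one-row tibble with
#'   the correct gate, diameter and speed).
#' @examples
#' task <- hpp_task()
#' rotation_speed(task, "Medium", "120")
#' @export
hpp_task <- function(rpm = NULL, safety_limit = 400, check = TRUE) {
  rpm <- if (is.null(rpm)) default_rpm() else as_tibble(rpm)
  if (!all(c("gate", "diameter", "rpm") %in% names(rpm))) {
    abort("`rpm` must have columns gate, diameter, rpm.")
  }
  rpm <- rpm |>
    mutate(gate = as.character(.data$gate), diameter = as.character(.data$diameter)) |>
    arrange(match(.data$gate, gate_levels()), match(.data$diameter, diameter_levels()))
  grid <- tidyr::expand_grid(gate = gate_levels(), diameter = diameter_levels())
  missing <- dplyr::anti_join(grid, rpm, by = c("gate", "diameter"))
  if (nrow(missing) > 0L) {
    abort(paste0(
      "Outcome table is missing cells: ",
      paste(missing$gate, missing$diameter, sep = "/", collapse = ", ")
    ))
  }
  if (nrow(rpm) != 9L) abort("Outcome table must have exactly nine cells.")
  if (!is.numeric(rpm$rpm) || any(!is.finite(rpm$rpm)) || any(rpm$rpm <= 0)) {
    abort("All rpm values must be finite and positive.")
  }
  if (!is.numeric(safety_limit) || length(safety_limit) != 1L || safety_limit <= 0) {
    abort("`safety_limit` must be a single positive number.")
  }
  safe <- rpm |> filter(.data$rpm < safety_limit)
  if (nrow(safe) == 0L) abort("No cell lies below the safety limit.")
  opt <- safe |> filter(.data$rpm == max(.data$rpm))
  task <- structure(
    list(rpm = rpm, safety_limit = safety_limit, optimum = opt),
    class = "hpp_task"
  )
  if (check) {
    rep <- validate_table(task)
    if (!all(rep$ok)) {
      abort(paste0(
        "Invalid outcome table: ",
        paste(rep$detail[!rep$ok], collapse = "; ")
      ))
    }
  }
  task
}

#' @export
print.hpp_task <- function(x, ...) {
  cat("<hpp_task> safety limit", x$safety_limit, "rpm\n")
  cat("optimum:", x$optimum$gate[1], "/", x$optimum$diameter[1],
      "cm =", x$optimum$rpm[1], "rpm\n")
  print(tidyr::pivot_wider(x$rpm, names_from = "diameter", values_from = "rpm"))
  invisible(x)
}

check_level <- function(value, levels, what) {
  value <- as.character(value)
  bad <- !value %in% levels
  if (any(bad)) {
    abort(paste0("Unknown ", what, " level: ", paste(unique(value[bad]), collapse = ", ")))
  }
  value
}

#' Rotation speed for a variable setting
#'
#' Pure lookup of the outcome table: the rotation speed the simulation
#' returns for a trial at the given gate position and inlet diameter.
#'
#' @param task An [hpp_task()].
#' @param gate Gate position, one of `"Low"`, `"Medium"`, `"High"` (vectorised).
#' @param diameter Inlet diameter in cm, one of `"40"`, `"80"`, `"120"`.
#' @return Numeric rpm value(s).
#' @examples
#' rotation_speed(hpp_task(), "High", "80")
#' @export
rotation_speed <- function(task, gate, diameter) {
  stopifnot(inherits(task, "hpp_task"))
  gate <- check_level(gate, gate_levels(), "gate")
  diameter <- check_level(diameter, diameter_levels(), "diameter")
  key <- paste(task$rpm$gate, task$rpm$diameter)
  task$rpm$rpm[match(paste(gate, diameter), key)]
}

#' Score a submitted answer triple
#'
#' Task correctness is dichotomous: the answer scores 1 only if the submitted
#' gate position and diameter identify the unique optimal condition (maximal
#' rpm below the safety limit) and the submitted speed equals that cell's
#' rpm exactly; otherwise 0. Incomplete answers (any element missing) are
#' rejected, mirroring the task interface which prompts students to complete
#' all three elements before submitting.
#'
#' @param task An [hpp_task()].
#' @param gate,diameter,speed The submitted answer elements (vectorised;
#'   `NA` marks a blank element).
#' @return Integer vector of 0/1 scores.
#' @examples
#' score_answer(hpp_task(), "Medium", "120", 309)
#' @export
score_answer <- function(task, gate, diameter, speed) {
  stopifnot(inherits(task, "hpp_task"))
  incomplete <- is.na(gate) | is.na(diameter) | is.na(speed)
  if (any(incomplete)) {
    abort("Incomplete answer: all three elements (gate, diameter, speed) must be provided.")
  }
  gate <- check_level(gate, gate_levels(), "gate")
  diameter <- check_level(diameter, diameter_levels(), "diameter")
  opt <- task$optimum
  as.integer(gate == opt$gate[1] & diameter == opt$diameter[1] & speed == opt$rpm[1])
}

#' Validate an outcome table
#'
#' Checks the structural requirements of a task outcome table: (a) a unique
#' constrained optimum (exactly one safe cell attains the maximal safe rpm)
#' and (b) strictly monotone increase of rpm along both the gate and the
#' diameter orderings (the task's qualitative priors: a higher gate and a
#' larger diameter each speed up the wheel).
#'
#' @param task An [hpp_task()] (possibly built with `check = FALSE`).
#' @return A tibble with columns `check`, `ok`, `detail`; attribute
#'   `valid` is `TRUE` iff all checks pass.
#' @export
validate_table <- function(task) {
  stopifnot(inherits(task, "hpp_task"))
  rpm <- task$rpm
  safe <- rpm |> filter(.data$rpm < task$safety_limit)
  top <- safe |> filter(.data$rpm == max(.data$rpm))
  unique_ok <- nrow(top) == 1L
  unique_detail <- if (unique_ok) {
    paste0("unique optimum at ", top$gate, "/", top$diameter)
  } else {
    paste0("non-unique optimum: ", paste(top$gate, top$diameter, sep = "/", collapse = ", "))
  }

  wide <- matrix(rpm$rpm[order(match(rpm$gate, gate_levels()),
                               match(rpm$diameter, diameter_levels()))],
                 nrow = 3L, byrow = TRUE,
                 dimnames = list(gate_levels(), diameter_levels()))
  gate_bad <- which(apply(wide, 2, function(col) any(diff(col) <= 0)))
  diam_bad <- which(apply(wide, 1, function(row) any(diff(row) <= 0)))
  mono_ok <- length(gate_bad) == 0L && length(diam_bad) == 0L
  mono_detail <- if (mono_ok) {
    "rpm strictly increasing in gate and diameter"
  } else {
    paste0(
      "monotonicity violated",
      if (length(gate_bad)) paste0(" along gate at diameter ", paste(colnames(wide)[gate_bad], collapse = ", ")),
      if (length(diam_bad)) paste0(" along diameter at gate ", paste(rownames(wide)[diam_bad], collapse = ", "))
    )
  }

  out <- tibble(
    check = c("unique_optimum", "monotone_rpm"),
    ok = c(unique_ok, mono_ok),
    detail = c(unique_detail, mono_detail)
  )
  attr(out, "valid") <- all(out$ok)
  out
}

#' Read or write a task configuration
#'
#' Round-trips a task definition through YAML: ordered variable levels, the
#' nine-cell rpm table and the safety limit.
#'
#' @param path File path of the YAML configuration.
#' @param task An [hpp_task()] to serialise.
#' @return `read_task_config()` returns an [hpp_task()];
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rpm <- as_tibble(cfg$rpm) |> mutate(rpm = as.numeric(.data$rpm))
  hpp_task(rpm = rpm, safety_limit = cfg$safety_limit %||% 400)
}

#' @rdname read_task_config
#' @export
write_task_config <- function(task, path) {
  stopifnot(inherits(task, "hpp_task"))
  yaml::write_yaml(
    list(
      gate_levels = gate_levels(),
      diameter_levels = diameter_levels(),
      rpm = lapply(as.list(task$rpm), function(x) if (is.numeric(x)) x else as.character(x)),
      safety_limit = task$safety_limit
    ),
    path
  )
  invisible(path)
}
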