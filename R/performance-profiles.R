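#' Extract final submitted answers from an event log
#'
#' For each student, the final value of each answer element (last
#' `edit_answer` event per element before End Task).
#'
#' @param events Raw events tibble (see [generate_cohort()]).
#' @return Tibble with columns `student_id`, `gate`, `diameter`, `speed`.
#' @export
final_answers <- function(events) {
  events |>
    filter(.data$event == "edit_answer") |>
    group_by(.data$student_id, .data$element) |>
    dplyr::slice_tail(n = 1) |>
    ungroup() |>
    select("student_id", "element", "value") |>
    tidyr::pivot_wider(names_from = "element", values_from = "value") |>
    mutate(speed = as.numeric(.data$speed))
}

#' Classify students by task effectiveness
#'
#' Effectiveness is dichotomous task correctness: a student is Effective iff
#' the final submitted triple scores 1 under [score_answer()] (the unique
#' optimal condition with its exact rotation speed).
#'
#' @param answers Tibble with `student_id`, `gate`, `diameter`, `speed`
#'   (e.g. from [final_answers()]).
#' @param task An [hpp_task()].
#' @return The input with added columns `correct` (0/1) and
#'   `effectiveness` (`"Effective"`/`"Ineffective"`).
#' @export
classify_effectiveness <- function(answers, task = hpp_task()) {
  if (any(is.na(answers$gate) | is.na(answers$diameter) | is.na(answers$speed))) {
    abort("Every student needs a complete final answer (gate, diameter, speed).")
  }
  answers |>
    mutate(
      correct = score_answer(task, .data$gate, .data$diameter, .data$speed),
      effectiveness = ifelse(.data$correct == 1L, "Effective", "Ineffective")
    )
}

# ---- univariate Gaussian mixture by EM ------------------------------------

gmm_loglik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

gmm_em_once <- function(x, w, mu, sd, max_iter = 500, tol = 1e-8, sd_floor) {
  n <- length(x)
  K <- length(w)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                   numeric(n))
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    if (any(rowsum_d == 0) || any(!is.finite(rowsum_d))) return(NULL)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    if (any(sd < sd_floor)) return(NULL)
    ll <- gmm_loglik(x, w, mu, sd)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  resp <- vapply(seq_len(K), function(k) w[k] * stats::dnorm(x, mu[k], sd[k]),
                 numeric(n))
  if (is.null(dim(resp))) resp <- matrix(resp, nrow = n)
  resp <- resp / rowSums(resp)
  list(w = w, mu = mu, sd = sd, loglik = gmm_loglik(x, w, mu, sd), resp = resp)
}

fit_gmm_K <- function(x, K, seed, prev = NULL, retries = 5) {
  n <- length(x)
  sd_floor <- max(stats::sd(x) * 1e-4, 1e-10)
  inits <- list(
    quantile = list(
      w = rep(1 / K, K),
      mu = as.numeric(stats::quantile(x, probs = (seq_len(K) - 0.5) / K)),
      sd = rep(stats::sd(x), K)
    )
  )
  if (!is.null(prev)) {
    # nested initialization: split the heaviest component of the K-1 solution
    j <- which.max(prev$w)
    eps <- 1e-3
    inits$nested <- list(
      w = c(prev$w[-j], prev$w[j] * (1 - eps), prev$w[j] * eps),
      mu = c(prev$mu[-j], prev$mu[j], prev$mu[j] + prev$sd[j]),
      sd = c(prev$sd[-j], prev$sd[j], prev$sd[j])
    )
  }
  withr::local_seed(seed)
  best <- NULL
  for (init in inits) {
    fit <- gmm_em_once(x, init$w, init$mu, init$sd, sd_floor = sd_floor)
    attempt <- 0
    while (is.null(fit) && attempt < retries) {
      attempt <- attempt + 1
      mu_j <- init$mu + stats::rnorm(K, 0, stats::sd(x) / 4)
      fit <- gmm_em_once(x, rep(1 / K, K), mu_j, rep(stats::sd(x), K),
                         sd_floor = sd_floor)
    }
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) {
    abort(paste0("EM degenerate for K = ", K, " after ", retries, " jittered restarts."))
  }
  ord <- order(best$mu)
  best$w <- best$w[ord]; best$mu <- best$mu[ord]; best$sd <- best$sd[ord]
  best$resp <- best$resp[, ord, drop = FALSE]
  p <- 3 * K - 1
  best$K <- K
  best$bic <- -2 * best$loglik + p * log(n)
  best$aic <- -2 * best$loglik + 2 * p
  best$mean_max_posterior <- mean(apply(best$resp, 1, max))
  best
}

#' Fit latent efficiency profiles to completion times
#'
#' Fits univariate Gaussian mixture models with K = 1..`K_max` components to
#' task completion times (seconds) by EM, selects K by minimum BIC
#' (parameter count 3K - 1), and labels each student by the maximum
#' posterior responsibility. Components are ordered by mean so that the
#' faster component is always first; with the selected two-component
#' solution the smaller-mean component is the Efficient profile and the
#' larger-mean one Inefficient.
#'
#' @param times Positive numeric vector of per-student completion times, or
#'   a data frame with columns `student_id` and `completion_time`.
#' @param K_max Largest component count to try (default 4).
#' @param seed Seed for EM initialisation jitter (default 0).
#' @return An object of class `hpp_gmm`: list with `fits` (per K),
#'   `selection` (tibble of K, logLik, AIC, BIC), `K` (selected),
#'   `assignments` (tibble: `student_id`, `component`, `efficiency`,
#'   `posterior`), and `mean_max_posterior`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' set.seed(1)
#' x <- c(rnorm(80, 80, 25), rnorm(20, 190, 50))
#' fit <- fit_efficiency_profiles(x)
#' glance(fit)
#' @export
fit_efficiency_profiles <- function(times, K_max = 4, seed = 0) {
  ids <- NULL
  if (is.data.frame(times)) {
    ids <- times$student_id
    times <- times$completion_time
  }
  x <- as.numeric(times)
  if (any(!is.finite(x)) || any(x <= 0)) abort("Completion times must be positive and finite.")
  if (stats::sd(x) == 0) abort("Degenerate input: all completion times identical.")
  if (length(x) <= K_max) abort("Need more students than K_max.")
  if (is.null(ids)) ids <- paste0("S", seq_along(x))

  fits <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    fits[[K]] <- fit_gmm_K(x, K, seed = seed + K,
                           prev = if (K > 1) fits[[K - 1]] else NULL)
  }
  selection <- purrr::map_dfr(fits, function(f) {
    tibble(K = f$K, logLik = f$loglik, AIC = f$aic, BIC = f$bic,
           mean_max_posterior = f$mean_max_posterior)
  })
  Ksel <- selection$K[which.min(selection$BIC)]
  sel <- fits[[Ksel]]
  comp <- apply(sel$resp, 1, which.max)
  eff_labels <- if (Ksel == 1) {
    rep("Efficient", length(x))
  } else if (Ksel == 2) {
    c("Efficient", "Inefficient")[comp]
  } else {
    paste0("Profile", comp)  # faster profiles get smaller indices
  }
  assignments <- tibble(
    student_id = ids,
    completion_time = x,
    component = comp,
    efficiency = eff_labels,
    posterior = apply(sel$resp, 1, max)
  )
  structure(
    list(fits = fits, selection = selection, K = Ksel, model = sel,
         assignments = assignments, mean_max_posterior = sel$mean_max_posterior),
    class = "hpp_gmm"
  )
}

#' @export
print.hpp_gmm <- function(x, ...) {
  cat("<hpp_gmm> selected K =", x$K,
      "| mean max posterior =", round(x$mean_max_posterior, 3), "\n")
  print(x$selection)
  invisible(x)
}

#' @rdname fit_efficiency_profiles
#' @param x An `hpp_gmm` object.
#' @param ... Unused.
#' @export
tidy.hpp_gmm <- function(x, ...) {
  m <- x$model
  tibble(component = seq_len(x$K), weight = m$w, mean = m$mu, sd = m$sd)
}

#' @rdname fit_efficiency_profiles
#' @export
glance.hpp_gmm <- function(x, ...) {
  m <- x$model
  tibble(K = x$K, logLik = m$loglik, AIC = m$aic, BIC = m$bic,
         mean_max_posterior = x$mean_max_posterior,
         n = nrow(x$assignments))
}

#' Proportion of diameter-to-run transitions (PDR)
#'
#' The fraction of a student's consecutive micro behavior pairs that are
#' Adjust Diameter followed by Run Trial, a behavioral proxy for
#' inefficient diameter-cycling experimentation. The denominator is all
#' consecutive pairs of the sequence.
#'
#' @param micro Character vector of micro codes (length >= 2).
#' @return Proportion in \[0, 1\].
#' @examples
#' compute_pdr(c("Start Task", "Adjust Diameter", "Run Trial", "End Task"))
#' @export
compute_pdr <- function(micro) {
  if (length(micro) < 2L) abort("PDR is undefined for sequences shorter than 2.")
  src <- micro[-length(micro)]
  tgt <- micro[-1]
  mean(src == "Adjust Diameter" & tgt == "Run Trial")
}

#' Per-student PDR for a coded cohort
#'
#' @param coded Output of [code_events()].
#' @return Tibble with `student_id` and `pdr`.
#' @export
pdr_by_student <- function(coded) {
  seqs <- sequences_of(coded, "micro")
  tibble(student_id = names(seqs), pdr = map_dbl(seqs, compute_pdr))
}

#' Regress PDR on log completion time and correctness
#'
#' Ordinary least squares of the PDR proxy on standardised log completion
#' time and a task-correctness indicator, used to validate that slower
#' students show more diameter-cycling.
#'
#' @param data Tibble with columns `pdr`, `completion_time`, `correct`.
#' @return List with `coefficients` (tibble: term, estimate, std.error,
#'   statistic, p.value), `r.squared`, and the underlying `lm` fit.
#' @export
pdr_regression <- function(data) {
  if (nrow(data) < 10L) abort("Need at least 10 students for the PDR regression.")
  z_logt <- as.numeric(scale(log(data$completion_time)))
  if (!is.finite(stats::sd(z_logt)) || stats::sd(data$completion_time) == 0) {
    abort("Completion time is constant; regression undefined.")
  }
  df <- tibble(pdr = data$pdr, z_log_time = z_logt, correct = data$correct)
  fit <- stats::lm(pdr ~ z_log_time + correct, data = df)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  list(
    coefficients = tibble(
      term = rownames(co), estimate = co[[1]], std.error = co[[2]],
      statistic = co[[3]], p.value = co[[4]]
    ),
    r.squared = sm$r.squared,
    fit = fit
  )
}

#' Quantile-based sensitivity splits of completion time
#'
#' Alternative efficiency groupings for robustness checks: a median split
#' (Efficient = at or below the median) or tertiles. Ties spanning a cut
#' are deterministically assigned to the faster side.
#'
#' @param times Numeric completion times.
#' @param method `"median"` or `"tertile"`.
#' @return Character vector of labels (`Efficient`/`Inefficient`, or
#'   `Efficient`/`Moderate`/`Inefficient` for tertiles).
#' @export
sensitivity_split <- function(times, method = c("median", "tertile")) {
  method <- match.arg(method)
  if (length(times) < 3L) abort("Need at least 3 students per group to split.")
  if (method == "median") {
    ifelse(times <= stats::median(times), "Efficient", "Inefficient")
  } else {
    q <- stats::quantile(times, c(1 / 3, 2 / 3))
    ifelse(times <= q[1], "Efficient", ifelse(times <= q[2], "Moderate", "Inefficient"))
  }
}

#' Mean PDR by profile label
#'
#' @param data Tibble with columns `pdr` and a label column.
#' @param label Name of the label column (string).
#' @return Tibble of per-profile n and mean PDR.
#' @export
pdr_by_profile <- function(data, label) {
  data |>
    group_by(profile = .data[[label]]) |>
    summarise(n = dplyr::n(), mean_pdr = mean(.data$pdr), .groups = "drop")
}

#' Form the 2 x 2 performance subgroups
#'
#' Combines effectiveness classification (task correctness) with
#' GMM-based efficiency profiling of completion time fitted separately
#' within each effectiveness group.
#'
#' @param coded Output of [code_events()].
#' @param answers Final answers tibble (see [final_answers()]).
#' @param task An [hpp_task()].
#' @param K_max Maximum GMM components (default 4).
#' @param seed Seed for EM initialisation (default 0).
#' @return A list of class `hpp_subgroups`: `assignments` (tibble:
#'   `student_id`, `effectiveness`, `efficiency`, `posterior`, `pdr`,
#'   `completion_time`, `sequence_length`, `subgroup`), `gmm` (per
#'   effectiveness group [fit_efficiency_profiles()] results), and
#'   `selection` (model-selection table across groups).
#' @export
performance_subgroups <- function(coded, answers, task = hpp_task(),
                                  K_max = 4, seed = 0) {
  eff <- classify_effectiveness(answers, task)
  meta <- sequence_summary(coded) |>
    left_join(select(eff, "student_id", "correct", "effectiveness"), by = "student_id") |>
    left_join(pdr_by_student(coded), by = "student_id")
  if (any(is.na(meta$effectiveness))) abort("Some students lack a final answer.")
  gmms <- list()
  parts <- list()
  for (g in c("Effective", "Ineffective")) {
    sub <- filter(meta, .data$effectiveness == g)
    if (nrow(sub) == 0L) next
    fit <- fit_efficiency_profiles(
      select(sub, "student_id", "completion_time"),
      K_max = K_max, seed = seed
    )
    gmms[[g]] <- fit
    parts[[g]] <- left_join(
      sub,
      select(fit$assignments, "student_id", "efficiency", "posterior"),
      by = "student_id"
    )
  }
  assignments <- bind_rows(parts) |>
    mutate(subgroup = paste(.data$effectiveness, .data$efficiency, sep = "-")) |>
    arrange(.data$student_id)
  selection <- purrr::imap_dfr(gmms, function(f, g) mutate(f$selection, group = g, .before = 1))
  structure(list(assignments = assignments, gmm = gmms, selection = selection),
            class = "hpp_subgroups")
}

#' @export
print.hpp_subgroups <- function(x, ...) {
  cat("<hpp_subgroups>\n")
  print(count(x$assignments, .data$effectiveness, .data$efficiency))
  invisible(x)
}
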