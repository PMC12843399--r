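#' Compare macro behavior rates between two groups
#'
#' For each macro behavior, fits a Poisson generalized linear model with log
#' link of the per-student behavior count on a group indicator, with the log
#' of total macro behaviors (sequence length) as an exposure offset, so the
#' comparison is of rates per step. Inference uses HC3
#' heteroskedasticity-robust (sandwich) standard errors; the group
#' coefficient and its Wald limits are exponentiated to an Incidence Rate
#' Ratio (IRR) with 95% CI, and p-values are Benjamini-Hochberg adjusted
#' across the modeled behaviors. Behaviors with zero count variance across
#' all students (structurally constant, e.g. START and END) are skipped, as
#' are behaviors absent from both groups; a behavior absent from exactly one
#' group is reported with a boundary IRR and a warning.
#'
#' @param coded Output of [code_events()].
#' @param groups Tibble with `student_id` and a `group` column (two levels);
#'   the IRR is reference-vs-other, where `reference` names the level whose
#'   rate forms the numerator.
#' @param reference Group level treated as the numerator (default the
#'   first level alphabetically... explicitly supply to fix direction).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble of class `hpp_rates`: `behavior`, `irr`, `conf.low`,
#'   `conf.high`, `p_raw`, `p_fdr`, `note`.
#' @export
rate_comparison <- function(coded, groups, reference = NULL, conf_level = 0.95) {
  grp <- as_tibble(groups)
  stopifnot(all(c("student_id", "group") %in% names(grp)))
  lev <- sort(unique(as.character(grp$group)))
  if (length(lev) != 2L) abort("`groups` must contain exactly two group levels.")
  if (is.null(reference)) reference <- lev[1]
  if (!reference %in% lev) abort("`reference` must be one of the group levels.")
  other <- setdiff(lev, reference)
  if (min(table(grp$group)) < 2L) abort("Each group needs at least 2 students.")

  counts <- coded |>
    count(.data$student_id, .data$macro) |>
    tidyr::pivot_wider(names_from = "macro", values_from = "n", values_fill = 0L) |>
    left_join(count(coded, .data$student_id, name = "sequence_length"),
              by = "student_id") |>
    left_join(grp, by = "student_id")
  if (any(is.na(counts$group))) abort("Every student needs a group label.")
  counts$group <- factor(counts$group, levels = c(other, reference))

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map_dfr(macro_codes(), function(b) {
    if (!b %in% names(counts)) {
      return(tibble(behavior = b, irr = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, p_raw = NA_real_, p_fdr = NA_real_,
                    note = "skipped: absent in both groups"))
    }
    y <- counts[[b]]
    if (stats::sd(y) == 0) {
      return(tibble(behavior = b, irr = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, p_raw = NA_real_, p_fdr = NA_real_,
                    note = "skipped: zero count variance"))
    }
    note <- NA_character_
    by_grp <- tapply(y, counts$group, sum)
    if (any(by_grp == 0)) {
      warn(paste0("Behavior ", b, " absent in one group; IRR is a boundary estimate."))
      note <- "boundary: behavior absent in one group"
    }
    fit <- stats::glm(y ~ group + offset(log(sequence_length)),
                      family = stats::poisson(), data = counts)
    vc <- sandwich::vcovHC(fit, type = "HC3")
    est <- unname(stats::coef(fit)[2])
    se <- sqrt(vc[2, 2])
    tibble(
      behavior = b,
      irr = exp(est),
      conf.low = exp(est - z * se),
      conf.high = exp(est + z * se),
      p_raw = 2 * stats::pnorm(-abs(est / se)),
      p_fdr = NA_real_,
      note = note
    )
  })
  modeled <- !is.na(out$p_raw)
  out$p_fdr[modeled] <- stats::p.adjust(out$p_raw[modeled], method = "BH")
  class(out) <- c("hpp_rates", class(out))
  attr(out, "reference") <- reference
  out
}

#' Cross-sectional state distribution of macro sequences
#'
#' Right-pads all macro sequences with a BLANK filler state to the maximum
#' length and tabulates the proportion of each state at every sequence
#' position, the basis of sequence distribution plots.
#'
#' @param coded Output of [code_events()] (optionally pre-filtered to one
#'   group).
#' @return Object of class `hpp_state_dist`: tibble with `position`,
#'   `state`, `prop`; proportions sum to 1 within each position.
#' @export
state_distribution <- function(coded) {
  seqs <- sequences_of(coded, "macro")
  if (length(seqs) == 0L) abort("No sequences supplied.")
  L <- max(lengths(seqs))
  states <- c(macro_codes(), "BLANK")
  mat <- vapply(seqs, function(s) c(s, rep("BLANK", L - length(s))), character(L))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = L)
  out <- purrr::map_dfr(seq_len(L), function(pos) {
    tab <- table(factor(mat[pos, ], levels = states))
    tibble(position = pos, state = states, prop = as.numeric(tab) / length(seqs))
  })
  out <- out |> mutate(state = factor(.data$state, levels = states))
  class(out) <- c("hpp_state_dist", class(out))
  out
}

# is `pattern` an order-preserving, gap-tolerant subsequence of `s`?
contains_pattern <- function(s, pattern) {
  i <- 1L
  np <- length(pattern)
  for (el in s) {
    if (el == pattern[i]) {
      i <- i + 1L
      if (i > np) return(TRUE)
    }
  }
  FALSE
}

pattern_support <- function(seqs, pattern) {
  sum(vapply(seqs, contains_pattern, logical(1), pattern = pattern))
}

#' Wilson score interval for a binomial proportion
#'
#' @param count Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `estimate`, `conf.low`, `conf.high`.
#' @export
wilson_ci <- function(count, n, conf_level = 0.95) {
  if (any(n < 1)) abort("Wilson interval requires n >= 1.")
  if (any(count < 0 | count > n)) abort("`count` must be between 0 and n.")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- count / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  tibble(estimate = p, conf.low = pmax(0, centre - half),
         conf.high = pmin(1, centre + half))
}

#' Compare a pattern's support between two groups
#'
#' Treats each student as a Bernoulli trial (pattern present vs absent):
#' group supports with Wilson 95% score intervals, plus the pooled
#' two-proportion z test (no continuity correction) with a two-sided p.
#'
#' @param count_a,n_a Successes and group size for group A.
#' @param count_b,n_b Successes and group size for group B.
#' @param conf_level Confidence level for the Wilson intervals.
#' @return One-row tibble: supports, Wilson bounds, `z`, `p`.
#' @export
compare_pattern_support <- function(count_a, n_a, count_b, n_b, conf_level = 0.95) {
  if (n_a < 1 || n_b < 1) abort("Group sizes must be >= 1.")
  wa <- wilson_ci(count_a, n_a, conf_level)
  wb <- wilson_ci(count_b, n_b, conf_level)
  p_pool <- (count_a + count_b) / (n_a + n_b)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n_a + 1 / n_b))
  z <- if (se == 0) 0 else (wa$estimate - wb$estimate) / se
  tibble(
    support_a = wa$estimate, conf.low_a = wa$conf.low, conf.high_a = wa$conf.high,
    support_b = wb$estimate, conf.low_b = wb$conf.low, conf.high_b = wb$conf.high,
    z = z, p = 2 * stats::pnorm(-abs(z))
  )
}

#' Mine frequent macro subsequences and compare groups
#'
#' Levelwise enumeration (with anti-monotone support pruning) of
#' order-preserving subsequences with unlimited gaps over the macro
#' alphabet, in the manner of sequential pattern mining with a support
#' threshold. The candidate set is the union over the two groups of
#' subsequences of length 2..`max_len` with support >= `min_support` in at
#' least one group (support counts each student at most once). Each
#' candidate gets per-group Wilson 95% intervals, a pooled two-proportion z
#' test, and Benjamini-Hochberg adjustment across the candidate set;
#' `retained` flags patterns meeting both the support rule and
#' `p_fdr < alpha`.
#'
#' @param coded Output of [code_events()].
#' @param groups Tibble with `student_id` and `group` (two levels).
#' @param min_support Support threshold in (0, 1\] (default 0.30).
#' @param max_len Maximum pattern length (default 4).
#' @param alpha FDR threshold for retention (default 0.05).
#' @return Tibble of class `hpp_patterns`: `pattern` (states joined by
#'   `" -> "`), `length`, per-group support/count/Wilson CI, `z`, `p_raw`,
#'   `p_fdr`, `retained`.
#' @export
mine_patterns <- function(coded, groups, min_support = 0.30, max_len = 4,
                          alpha = 0.05) {
  if (min_support <= 0 || min_support > 1) {
    abort("`min_support` must be in (0, 1]; 0 is refused (combinatorial blowup).")
  }
  if (max_len < 2) abort("`max_len` must be >= 2.")
  grp <- as_tibble(groups)
  lev <- sort(unique(as.character(grp$group)))
  if (length(lev) != 2L) abort("`groups` must contain exactly two levels.")
  seqs <- sequences_of(coded, "macro")
  ga <- grp$student_id[grp$group == lev[1]]
  gb <- grp$student_id[grp$group == lev[2]]
  seqs_a <- seqs[names(seqs) %in% ga]
  seqs_b <- seqs[names(seqs) %in% gb]
  n_a <- length(seqs_a); n_b <- length(seqs_b)
  if (n_a == 0L || n_b == 0L) abort("Both groups must contain coded students.")

  alphabet <- macro_codes()
  # levelwise growth: extend patterns frequent (in at least one group) by one state
  frontier <- lapply(alphabet, function(s) s)
  records <- list()
  for (len in seq_len(max_len)) {
    keep <- list()
    for (pat in frontier) {
      ca <- pattern_support(seqs_a, pat)
      cb <- pattern_support(seqs_b, pat)
      if (ca / n_a >= min_support || cb / n_b >= min_support) {
        keep[[length(keep) + 1L]] <- pat
        if (len >= 2L) {
          records[[length(records) + 1L]] <- list(pat = pat, ca = ca, cb = cb)
        }
      }
    }
    if (len == max_len || length(keep) == 0L) break
    frontier <- purrr::flatten(lapply(keep, function(p) lapply(alphabet, function(s) c(p, s))))
  }

  if (length(records) == 0L) {
    out <- tibble(pattern = character(), length = integer())
    class(out) <- c("hpp_patterns", class(out))
    return(out)
  }
  out <- purrr::map_dfr(records, function(r) {
    cmp <- compare_pattern_support(r$ca, n_a, r$cb, n_b)
    tibble(
      pattern = paste(r$pat, collapse = " -> "),
      length = length(r$pat),
      count_a = r$ca, count_b = r$cb,
      support_a = cmp$support_a, conf.low_a = cmp$conf.low_a, conf.high_a = cmp$conf.high_a,
      support_b = cmp$support_b, conf.low_b = cmp$conf.low_b, conf.high_b = cmp$conf.high_b,
      z = cmp$z, p_raw = cmp$p
    )
  })
  out$p_fdr <- stats::p.adjust(out$p_raw, method = "BH")
  out$retained <- (out$support_a >= min_support | out$support_b >= min_support) &
    out$p_fdr < alpha
  out <- arrange(out, dplyr::desc(pmax(.data$support_a, .data$support_b)))
  class(out) <- c("hpp_patterns", class(out))
  attr(out, "groups") <- stats::setNames(c(n_a, n_b), lev)
  out
}
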