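#' Normalized Shannon entropy of a behavior sequence
#'
#' Treats the relative frequencies of the distinct micro behaviors in a
#' student's sequence as probabilities p_i and computes Shannon entropy
#' H = -sum(p_i log2 p_i) in bits (0 log 0 = 0), normalized by the maximum
#' possible entropy log2(K) over the K = 8 micro codes, giving an index in
#' \[0, 1\]. Higher values indicate a more diverse behavioral repertoire.
#'
#' @param micro Character vector of micro codes (length >= 1).
#' @return List with `H` (bits) and `normalized`.
#' @examples
#' normalized_entropy(rep(micro_codes(), 3))$normalized  # 1
#' @export
normalized_entropy <- function(micro) {
  if (length(micro) == 0L) abort("Entropy is undefined for an empty sequence.")
  bad <- !micro %in% micro_codes()
  if (any(bad)) abort(paste0("Unknown micro code: ", paste(unique(micro[bad]), collapse = ", ")))
  p <- as.numeric(table(micro)) / length(micro)
  H <- -sum(p * log2(p))
  list(H = H, normalized = H / log2(length(micro_codes())))
}

#' Per-student normalized entropy for a coded cohort
#'
#' @param coded Output of [code_events()].
#' @return Tibble with `student_id`, `H`, `normalized`.
#' @export
entropy_by_student <- function(coded) {
  seqs <- sequences_of(coded, "micro")
  tibble(
    student_id = names(seqs),
    H = map_dbl(seqs, function(s) normalized_entropy(s)$H),
    normalized = map_dbl(seqs, function(s) normalized_entropy(s)$normalized)
  )
}

#' Compare normalized entropy across the 2 x 2 performance subgroups
#'
#' Subgroup means of normalized entropy with percentile bootstrap 95%
#' confidence intervals (resampling students within subgroup), and a
#' two-way ANOVA with effectiveness, efficiency and their interaction as
#' between-subject factors (Type II sums of squares for the unbalanced
#' design), reporting partial eta squared per term.
#'
#' @param data Tibble with columns `normalized`, `effectiveness`,
#'   `efficiency`.
#' @param B Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `hpp_entropy`: list with `means` (per-subgroup
#'   n, mean, CI) and `anova` (term, df, sumsq, F, p, partial eta squared;
#'   `NULL` with a warning if any cell has fewer than 2 students).
#' @export
entropy_group_comparison <- function(data, B = 2000, seed = 0, conf_level = 0.95) {
  stopifnot(all(c("normalized", "effectiveness", "efficiency") %in% names(data)))
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  withr::local_seed(seed)
  means <- data |>
    group_by(.data$effectiveness, .data$efficiency) |>
    summarise(n = dplyr::n(), mean = mean(.data$normalized), .groups = "drop")
  ci <- purrr::pmap_dfr(means, function(effectiveness, efficiency, n, mean) {
    x <- data$normalized[data$effectiveness == effectiveness &
                           data$efficiency == efficiency]
    bs <- vapply(seq_len(B), function(b) mean(sample(x, length(x), replace = TRUE)),
                 numeric(1))
    q <- stats::quantile(bs, probs, names = FALSE)
    tibble(conf.low = q[1], conf.high = q[2])
  })
  means <- bind_cols(means, ci)

  anova_tbl <- NULL
  cells <- count(data, .data$effectiveness, .data$efficiency)
  if (nrow(cells) < 4L || any(cells$n < 2L)) {
    warn("ANOVA refused: need at least 2 students in each of the four cells.")
  } else {
    df <- mutate(data,
                 effectiveness = factor(.data$effectiveness),
                 efficiency = factor(.data$efficiency))
    fit <- stats::lm(normalized ~ effectiveness * efficiency, data = df)
    a2 <- car::Anova(fit, type = 2)
    tab <- as.data.frame(a2)
    ss_err <- tab["Residuals", "Sum Sq"]
    terms <- setdiff(rownames(tab), "Residuals")
    anova_tbl <- tibble(
      term = terms,
      df = tab[terms, "Df"],
      sumsq = tab[terms, "Sum Sq"],
      df_error = tab["Residuals", "Df"],
      statistic = tab[terms, "F value"],
      p.value = tab[terms, "Pr(>F)"],
      partial_eta_sq = tab[terms, "Sum Sq"] / (tab[terms, "Sum Sq"] + ss_err)
    )
  }
  structure(list(means = means, anova = anova_tbl), class = "hpp_entropy")
}

#' @export
print.hpp_entropy <- function(x, ...) {
  cat("<hpp_entropy> subgroup means:\n")
  print(x$means)
  if (!is.null(x$anova)) {
    cat("two-way ANOVA (Type II):\n")
    print(x$anova)
  }
  invisible(x)
}

transition_dims <- function() {
  list(
    sources = setdiff(micro_codes(), "End Task"),
    targets = setdiff(micro_codes(), "Start Task")
  )
}

#' Count first-order transitions in micro sequences
#'
#' Tabulates consecutive behavior pairs over all sequences: sources exclude
#' End Task (absorbing) and targets exclude Start Task (structural zeros of
#' the task grammar). Each sequence of length L contributes L - 1 pairs.
#'
#' @param seqs List of micro code character vectors (e.g.
#'   `sequences_of(coded, "micro")`).
#' @return 7 x 7 integer matrix of counts (sources x targets).
#' @export
transition_counts <- function(seqs) {
  d <- transition_dims()
  cnt <- matrix(0L, length(d$sources), length(d$targets),
                dimnames = list(d$sources, d$targets))
  for (s in seqs) {
    if (length(s) < 2L) next
    src <- factor(s[-length(s)], levels = d$sources)
    tgt <- factor(s[-1], levels = d$targets)
    cnt <- cnt + table(src, tgt)
  }
  cnt
}

#' Estimate a first-order transition matrix, optionally smoothed
#'
#' The unsmoothed estimate is the conditional relative frequency
#' P(t | s) = count(s, t) / sum_t' count(s, t'). With a prior (typically the
#' pooled matrix from the full sample) the rows are shrunk by a hierarchical
#' Dirichlet-multinomial scheme: each row receives total prior mass `alpha`
#' split proportionally to the prior row, and the smoothed row is the
#' posterior mean (count(s, t) + alpha * prior(t | s)) / (n_s + alpha).
#' Rows with zero counts equal the prior row; rows with zero counts and no
#' prior are undefined and flagged.
#'
#' @param seqs List of micro code vectors, or an `hpp_coded` tibble.
#' @param prior Optional `hpp_transitions` object (or row-stochastic matrix
#'   over the same dimensions) used as the smoothing prior.
#' @param alpha Concentration parameter, total prior mass per row
#'   (default 0.5); `alpha = 0` reproduces the unsmoothed estimate.
#' @return Object of class `hpp_transitions`: list with `counts`, `probs`
#'   (row-stochastic over defined rows), `row_total`, `defined` (logical per
#'   row), `smoothed`, `alpha`.
#' @export
estimate_transitions <- function(seqs, prior = NULL, alpha = 0.5) {
  if (inherits(seqs, "hpp_coded")) seqs <- sequences_of(seqs, "micro")
  if (length(seqs) < 1L) abort("Need at least one sequence.")
  if (alpha < 0) abort("`alpha` must be non-negative.")
  cnt <- transition_counts(seqs)
  n_s <- rowSums(cnt)
  pm <- NULL
  if (!is.null(prior)) {
    pm <- if (inherits(prior, "hpp_transitions")) prior$probs else as.matrix(prior)
    if (!identical(dim(pm), dim(cnt))) abort("Prior dimensions do not match.")
  }
  if (is.null(pm) || alpha == 0) {
    probs <- cnt / n_s
    defined <- n_s > 0
    probs[!defined, ] <- NA_real_
    smoothed <- FALSE
  } else {
    probs <- (cnt + alpha * pm) / (n_s + alpha)
    defined <- n_s > 0 | rowSums(pm, na.rm = TRUE) > 0
    probs[!defined, ] <- NA_real_
    smoothed <- TRUE
  }
  structure(
    list(counts = cnt, probs = probs, row_total = n_s, defined = defined,
         smoothed = smoothed, alpha = if (smoothed) alpha else 0),
    class = "hpp_transitions"
  )
}

#' @export
print.hpp_transitions <- function(x, ...) {
  cat("<hpp_transitions>", if (x$smoothed) paste0("smoothed (alpha = ", x$alpha, ")") else "unsmoothed", "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @rdname estimate_transitions
#' @param x An `hpp_transitions` object.
#' @param ... Unused.
#' @export
tidy.hpp_transitions <- function(x, ...) {
  as_tibble(as.data.frame.table(x$probs, responseName = "prob")) |>
    rename(from = "Var1", to = "Var2") |>
    mutate(from = as.character(.data$from), to = as.character(.data$to),
           count = as.vector(x$counts))
}

#' Bootstrap delta probability maps between two subgroups
#'
#' Resamples students with replacement independently within each subgroup,
#' recomputes the Dirichlet-smoothed transition matrices (global prior held
#' fixed) and their difference (A minus B) per resample, and summarises
#' percentile 95% intervals per cell, both for each subgroup's transition
#' probabilities and for the delta. A cell is flagged significant when its
#' delta interval excludes zero.
#'
#' @param seqs_a,seqs_b Lists of micro sequences for subgroups A and B
#'   (each n >= 2).
#' @param prior Global prior ([estimate_transitions()] on the full sample).
#' @param alpha Concentration parameter (default 0.5).
#' @param B Bootstrap resamples (default 1000).
#' @param seed Seed.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `hpp_delta_map`: list with `delta` (matrix
#'   A - B), `ci_low`/`ci_high` (delta), `significant` (logical matrix),
#'   `matrix_a`/`matrix_b` (`hpp_transitions`) and per-cell CI matrices
#'   `ci_a_low`, `ci_a_high`, `ci_b_low`, `ci_b_high`.
#' @export
bootstrap_deltas <- function(seqs_a, seqs_b, prior, alpha = 0.5, B = 1000,
                             seed = 0, conf_level = 0.95) {
  if (inherits(seqs_a, "hpp_coded")) seqs_a <- sequences_of(seqs_a, "micro")
  if (inherits(seqs_b, "hpp_coded")) seqs_b <- sequences_of(seqs_b, "micro")
  if (length(seqs_a) < 2L || length(seqs_b) < 2L) {
    abort("Each subgroup needs at least 2 students for the bootstrap.")
  }
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ma <- estimate_transitions(seqs_a, prior = prior, alpha = alpha)
  mb <- estimate_transitions(seqs_b, prior = prior, alpha = alpha)
  delta <- ma$probs - mb$probs

  # per-student count matrices so each resample is a cheap sum
  stack <- function(seqs) t(vapply(seqs, function(s) as.vector(transition_counts(list(s))),
                                   numeric(49)))
  Sa <- stack(seqs_a); Sb <- stack(seqs_b)
  pm <- if (inherits(prior, "hpp_transitions")) prior$probs else as.matrix(prior)
  smooth_vec <- function(v) {
    cnt <- matrix(v, 7, 7)
    (cnt + alpha * pm) / (rowSums(cnt) + alpha)
  }
  withr::local_seed(seed)
  reps_a <- array(NA_real_, c(7, 7, B))
  reps_b <- array(NA_real_, c(7, 7, B))
  for (b in seq_len(B)) {
    ia <- sample.int(nrow(Sa), replace = TRUE)
    ib <- sample.int(nrow(Sb), replace = TRUE)
    reps_a[, , b] <- smooth_vec(colSums(Sa[ia, , drop = FALSE]))
    reps_b[, , b] <- smooth_vec(colSums(Sb[ib, , drop = FALSE]))
  }
  reps_d <- reps_a - reps_b
  qmat <- function(a, p) apply(a, c(1, 2), stats::quantile, probs = p, na.rm = TRUE)
  dims <- dimnames(ma$probs)
  named <- function(m) { dimnames(m) <- dims; m }
  ci_low <- named(qmat(reps_d, probs[1])); ci_high <- named(qmat(reps_d, probs[2]))
  significant <- named(ci_low > 0 | ci_high < 0)
  significant[is.na(delta)] <- NA
  structure(
    list(delta = delta, ci_low = ci_low, ci_high = ci_high,
         significant = significant,
         matrix_a = ma, matrix_b = mb,
         ci_a_low = named(qmat(reps_a, probs[1])), ci_a_high = named(qmat(reps_a, probs[2])),
         ci_b_low = named(qmat(reps_b, probs[1])), ci_b_high = named(qmat(reps_b, probs[2])),
         B = B, alpha = alpha),
    class = "hpp_delta_map"
  )
}

#' @export
print.hpp_delta_map <- function(x, ...) {
  cat("<hpp_delta_map> B =", x$B, "\n")
  sig <- which(x$significant, arr.ind = TRUE)
  if (nrow(sig) == 0L) {
    cat("no significant cells\n")
  } else {
    for (i in seq_len(nrow(sig))) {
      r <- rownames(x$significant)[sig[i, 1]]
      cl <- colnames(x$significant)[sig[i, 2]]
      cat(sprintf("  %s -> %s: delta = %+.3f [%.3f, %.3f]\n", r, cl,
                  x$delta[r, cl], x$ci_low[r, cl], x$ci_high[r, cl]))
    }
  }
  invisible(x)
}

#' @rdname bootstrap_deltas
#' @param x An `hpp_delta_map` object.
#' @param ... Unused.
#' @export
tidy.hpp_delta_map <- function(x, ...) {
  as_tibble(as.data.frame.table(x$delta, responseName = "delta")) |>
    rename(from = "Var1", to = "Var2") |>
    mutate(
      from = as.character(.data$from), to = as.character(.data$to),
      conf.low = as.vector(x$ci_low), conf.high = as.vector(x$ci_high),
      significant = as.vector(x$significant)
    )
}

#' Build a thresholded process graph from a transition matrix
#'
#' Nodes are behavior codes; directed edges are the transition cells with
#' probability at or above `threshold`, weighted by probability. With a
#' delta-map comparison, edges significantly more prominent in subgroup A
#' are coloured green and those more prominent in subgroup B red.
#'
#' @param tm An `hpp_transitions` object.
#' @param threshold Minimum displayed probability in (0, 1\] (default 0.30).
#' @param comparison Optional `hpp_delta_map` for edge colouring.
#' @return Object of class `hpp_process_graph`: list with `nodes` (tibble)
#'   and `edges` (tibble: from, to, prob, colour).
#' @seealso [write_process_dot()], [process_graph_json()]
#' @export
build_process_graph <- function(tm, threshold = 0.30, comparison = NULL) {
  stopifnot(inherits(tm, "hpp_transitions"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  pr <- tm$probs
  idx <- which(!is.na(pr) & pr >= threshold, arr.ind = TRUE)
  edges <- tibble(
    from = rownames(pr)[idx[, 1]],
    to = colnames(pr)[idx[, 2]],
    prob = pr[idx],
    colour = "grey30"
  )
  if (!is.null(comparison)) {
    stopifnot(inherits(comparison, "hpp_delta_map"))
    for (i in seq_len(nrow(edges))) {
      s <- comparison$significant[edges$from[i], edges$to[i]]
      if (isTRUE(s)) {
        edges$colour[i] <- if (comparison$delta[edges$from[i], edges$to[i]] > 0)
          "forestgreen" else "firebrick"
      }
    }
  }
  structure(
    list(nodes = tibble(name = micro_codes()), edges = arrange(edges, dplyr::desc(.data$prob))),
    class = "hpp_process_graph"
  )
}

#' Serialise a process graph
#'
#' `write_process_dot()` writes Graphviz DOT; `process_graph_json()` returns
#' (or writes) a JSON form with the same node and edge set, so the two
#' serialisations round-trip.
#'
#' @param graph An `hpp_process_graph`.
#' @param path Output file path (optional for JSON).
#' @return `write_process_dot()`: `path`, invisibly. `process_graph_json()`:
#'   the JSON string, invisibly if written to a file.
#' @export
write_process_dot <- function(graph, path) {
  stopifnot(inherits(graph, "hpp_process_graph"))
  q <- function(x) paste0('"', x, '"')
  lines <- c(
    "digraph process {",
    "  rankdir=LR;",
    paste0("  ", q(graph$nodes$name), ";"),
    sprintf('  %s -> %s [label="%.2f", color=%s];',
            q(graph$edges$from), q(graph$edges$to), graph$edges$prob,
            q(graph$edges$colour)),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_process_dot
#' @export
process_graph_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "hpp_process_graph"))
  js <- jsonlite::toJSON(
    list(nodes = graph$nodes, edges = graph$edges),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse a DOT file written by [write_process_dot()] back to an edge set
#'
#' @param path DOT file path.
#' @return Tibble with `from`, `to`, `prob`.
#' @export
read_process_dot <- function(path) {
  lines <- grep("->", readLines(path), value = TRUE)
  m <- regmatches(lines, regexec('^\\s*"([^"]+)" -> "([^"]+)" \\[label="([0-9.]+)"', lines))
  purrr::map_dfr(m, function(g) tibble(from = g[2], to = g[3], prob = as.numeric(g[4])))
}
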