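# shared fixtures built in code

# quick event stream for one student from a compact spec like
# c("start", "edit:gate", "run", "end"); times are 0, 1, 2, ...
make_events <- function(..., id = "S1") {
  spec <- c(...)
  rows <- lapply(seq_along(spec), function(i) {
    parts <- strsplit(spec[i], ":", fixed = TRUE)[[1]]
    ev <- switch(parts[1],
                 start = "start_task", end = "end_task", run = "run_trial",
                 gate = "adjust_gate", diam = "adjust_diameter",
                 edit = "edit_answer", del = "delete_record",
                 stop("bad spec: ", spec[i]))
    tibble::tibble(
      student_id = id, t = i - 1, event = ev,
      gate = NA_character_, diameter = NA_character_,
      element = if (ev == "edit_answer") parts[2] else NA_character_,
      value = NA_character_, rpm = NA_real_, record = NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

# sample n sequences from a known transition matrix over the micro codes
# (Start Task -> ... -> End Task); the matrix must make End Task reachable
sample_chain_paths <- function(tm, n, max_steps = 500) {
  codes <- rownames(tm)
  lapply(seq_len(n), function(i) {
    path <- "Start Task"
    cur <- "Start Task"
    repeat {
      nxt <- sample(codes, 1, prob = tm[cur, ])
      path <- c(path, nxt)
      cur <- nxt
      if (nxt == "End Task" || length(path) > max_steps) break
    }
    path
  })
}

# simple consistent chain for transition tests: no answer/record bookkeeping
# issues (Remove Record never used, Initial Answer only from Start Task)
test_chain_matrix <- function() {
  codes <- inquiryflow::micro_codes()
  tm <- matrix(0, 8, 8, dimnames = list(codes, codes))
  tm["Start Task", c("Initial Answer", "Adjust Gate")] <- c(0.6, 0.4)
  tm["Initial Answer", c("Run Trial", "Adjust Gate")] <- c(0.7, 0.3)
  tm["Adjust Gate", c("Run Trial", "Adjust Diameter")] <- c(0.6, 0.4)
  tm["Adjust Diameter", "Run Trial"] <- 1
  tm["Run Trial", c("Adjust Gate", "Revise Answer", "End Task")] <- c(0.4, 0.35, 0.25)
  tm["Revise Answer", c("Run Trial", "End Task")] <- c(0.5, 0.5)
  tm["Remove Record", "End Task"] <- 1
  tm
}

# brute-force transition-frequency estimate used as an oracle against the
# package's estimator and the generator's ground truth
empirical_micro_matrix <- function(seqs) {
  codes <- inquiryflow::micro_codes()
  cnt <- matrix(0, 8, 8, dimnames = list(codes, codes))
  for (s in seqs) {
    for (i in seq_len(length(s) - 1)) cnt[s[i], s[i + 1]] <- cnt[s[i], s[i + 1]] + 1
  }
  pr <- cnt / rowSums(cnt)
  pr["End Task", ] <- 0
  pr[is.nan(pr)] <- 0
  pr
}

# random grammar-free macro sequences for miner oracles
random_macro_seqs <- function(n, max_len = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    sample(inquiryflow::macro_codes(), sample(2:max_len, 1), replace = TRUE)
  })
}

# coded tibble straight from macro sequences (micro column mirrors macro;
# only fields the macro analytics touch are meaningful)
coded_from_macro <- function(seqs) {
  out <- purrr::imap_dfr(seqs, function(s, i) {
    tibble::tibble(
      student_id = sprintf("S%03d", as.integer(i)),
      position = seq_along(s),
      micro = s, macro = s, t = seq_along(s) - 1
    )
  })
  class(out) <- c("hpp_coded", class(out))
  out
}

# exhaustive subsequence-support oracle: every candidate pattern of
# length 2..max_len over the macro alphabet, support by direct scanning
oracle_pattern_supports <- function(seqs, max_len = 4) {
  alphabet <- inquiryflow::macro_codes()
  is_sub <- function(s, p) {
    i <- 1
    for (el in s) {
      if (el == p[i]) {
        i <- i + 1
        if (i > length(p)) return(TRUE)
      }
    }
    FALSE
  }
  res <- list()
  for (len in 2:max_len) {
    grid <- do.call(expand.grid, c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      pat <- as.character(grid[r, ])
      cnt <- sum(vapply(seqs, is_sub, logical(1), p = pat))
      res[[length(res) + 1]] <- tibble::tibble(
        pattern = paste(pat, collapse = " -> "), count = cnt
      )
    }
  }
  dplyr::bind_rows(res)
}
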