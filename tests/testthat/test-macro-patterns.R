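test_that("the two-group Poisson IRR equals the pooled-rate ratio", {
  # group A: rates 3/6; group B: rates 4/4 -> IRR(B vs A) = 2, by hand
  seqs <- list(
    c("DESIGN", "CONDUCT"),                      # A: 1 CONDUCT in 2
    c("CONDUCT", "CONDUCT", "DESIGN", "DESIGN"), # A: 2 in 4
    c("CONDUCT", "CONDUCT"),                     # B: 2 in 2
    c("CONDUCT", "CONDUCT")                      # B: 2 in 2
  )
  coded <- coded_from_macro(seqs)
  groups <- tibble::tibble(student_id = sprintf("S%03d", 1:4),
                           group = c("A", "A", "B", "B"))
  out <- rate_comparison(coded, groups, reference = "B")
  expect_equal(out$irr[out$behavior == "CONDUCT"], 2, tolerance = 1e-8)

  # random small datasets: glm equals the closed-form saturated MLE
  set.seed(1)
  for (i in 1:20) {
    lens <- sample(2:8, 6, replace = TRUE)
    counts <- vapply(lens, function(l) sample.int(l, 1), integer(1))
    seqs <- lapply(seq_along(lens), function(j) {
      s <- rep("DESIGN", lens[j]); s[seq_len(counts[j])] <- "CONDUCT"; s
    })
    grp <- rep(c("A", "B"), each = 3)
    coded <- coded_from_macro(seqs)
    groups <- tibble::tibble(student_id = sprintf("S%03d", 1:6), group = grp)
    out <- suppressWarnings(rate_comparison(coded, groups, reference = "B"))
    irr_oracle <- (sum(counts[4:6]) / sum(lens[4:6])) /
      (sum(counts[1:3]) / sum(lens[1:3]))
    expect_equal(out$irr[out$behavior == "CONDUCT"], irr_oracle, tolerance = 1e-6)
  }
})

test_that("identical groups give IRR 1 and structural behaviors are skipped", {
  cohort <- generate_cohort(builtin_profiles()[["effective_efficient"]],
                            n = 20, seed = 4)
  coded <- code_events(cohort$events)
  ids <- unique(coded$student_id)
  # duplicate every student into both groups
  coded2 <- dplyr::bind_rows(
    coded,
    dplyr::mutate(coded, student_id = paste0(student_id, "_copy"))
  )
  class(coded2) <- class(coded)
  groups <- tibble::tibble(
    student_id = c(ids, paste0(ids, "_copy")),
    group = rep(c("A", "B"), each = length(ids))
  )
  out <- rate_comparison(coded2, groups, reference = "B")
  modeled <- !is.na(out$irr)
  expect_true(all(abs(out$irr[modeled] - 1) < 1e-8))
  expect_true(all(out$p_raw[modeled] > 0.99))
  # START and END have zero count variance (exactly one each) and are skipped
  expect_match(out$note[out$behavior == "START"], "zero count variance")
  expect_match(out$note[out$behavior == "END"], "zero count variance")
  expect_true(all(out$p_fdr[modeled] >= out$p_raw[modeled]))
})

test_that("a behavior absent from one group is flagged as a boundary estimate", {
  seqs <- c(
    replicate(3, c("DESIGN", "MANAGE", "CONDUCT"), simplify = FALSE),
    replicate(3, c("DESIGN", "CONDUCT", "CONDUCT"), simplify = FALSE)
  )
  coded <- coded_from_macro(seqs)
  groups <- tibble::tibble(student_id = sprintf("S%03d", 1:6),
                           group = rep(c("A", "B"), each = 3))
  expect_warning(out <- rate_comparison(coded, groups, reference = "A"),
                 "boundary")
  expect_match(out$note[out$behavior == "MANAGE"], "boundary")
})

test_that("state distributions tally positions with BLANK padding", {
  sd1 <- state_distribution(coded_from_macro(list(c("START", "END"),
                                                  c("START", "DESIGN", "END"))))
  pos3 <- dplyr::filter(sd1, position == 3)
  expect_equal(pos3$prop[pos3$state == "END"], 0.5)
  expect_equal(pos3$prop[pos3$state == "BLANK"], 0.5)

  # every position sums to one, and a naive tally oracle agrees
  set.seed(2)
  for (i in 1:20) {
    seqs <- random_macro_seqs(sample(2:12, 1))
    sd <- state_distribution(coded_from_macro(seqs))
    sums <- dplyr::summarise(dplyr::group_by(sd, position), s = sum(prop))$s
    expect_equal(sums, rep(1, max(lengths(seqs))), tolerance = 1e-9)
    L <- max(lengths(seqs))
    for (pos in seq_len(L)) {
      at <- vapply(seqs, function(s) if (pos <= length(s)) s[pos] else "BLANK", "")
      for (st in unique(at)) {
        expect_equal(sd$prop[sd$position == pos & sd$state == st],
                     mean(at == st))
      }
    }
  }
})

test_that("subsequence containment allows gaps but preserves order", {
  s <- c("START", "DESIGN", "CONDUCT", "ANSWER", "DESIGN", "CONDUCT", "END")
  expect_true(inquiryflow:::contains_pattern(s, c("START", "DESIGN", "CONDUCT", "DESIGN")))
  expect_true(inquiryflow:::contains_pattern(s, c("DESIGN", "CONDUCT")))
  expect_false(inquiryflow:::contains_pattern(s, c("END", "START")))
  expect_false(inquiryflow:::contains_pattern(c("DESIGN"), c("DESIGN", "DESIGN")))
})

test_that("mined supports equal the exhaustive enumeration oracle", {
  set.seed(3)
  seqs <- random_macro_seqs(20, max_len = 8)
  coded <- coded_from_macro(seqs)
  groups <- tibble::tibble(student_id = sprintf("S%03d", 1:20),
                           group = rep(c("A", "B"), each = 10))
  mined <- mine_patterns(coded, groups, min_support = 0.3, max_len = 4)

  oracle_a <- oracle_pattern_supports(seqs[1:10])
  oracle_b <- oracle_pattern_supports(seqs[11:20])
  oracle <- dplyr::full_join(oracle_a, oracle_b, by = "pattern",
                             suffix = c("_a", "_b"))
  oracle_keep <- dplyr::filter(oracle, count_a / 10 >= 0.3 | count_b / 10 >= 0.3)
  expect_setequal(mined$pattern, oracle_keep$pattern)
  joined <- dplyr::left_join(mined, oracle_keep, by = "pattern",
                             suffix = c("", ".o"))
  expect_equal(joined$count_a, joined$count_a.o)
  expect_equal(joined$count_b, joined$count_b.o)
  expect_equal(joined$support_a, joined$count_a.o / 10)
})

test_that("support is anti-monotone and counts each student once", {
  set.seed(4)
  seqs <- random_macro_seqs(16, max_len = 8)
  coded <- coded_from_macro(seqs)
  groups <- tibble::tibble(student_id = sprintf("S%03d", 1:16),
                           group = rep(c("A", "B"), each = 8))
  mined <- mine_patterns(coded, groups, min_support = 0.2, max_len = 4)
  sup <- function(p, col) {
    row <- mined[mined$pattern == p, ]
    if (nrow(row) == 0) Inf else row[[col]]  # unseen prefixes can only have more support
  }
  for (i in seq_len(nrow(mined))) {
    if (mined$length[i] < 3) next
    states <- strsplit(mined$pattern[i], " -> ", fixed = TRUE)[[1]]
    prefix <- paste(states[-length(states)], collapse = " -> ")
    expect_gte(sup(prefix, "support_a"), mined$support_a[i])
    expect_gte(sup(prefix, "support_b"), mined$support_b[i])
  }

  # a student containing the pattern twice still counts once; adding a
  # containing student increases support
  base <- list(c("DESIGN", "CONDUCT", "DESIGN", "CONDUCT"), c("ANSWER", "END"))
  n_with_dup <- inquiryflow:::pattern_support(base, c("DESIGN", "CONDUCT"))
  expect_equal(n_with_dup, 1)
  more <- c(base, list(c("DESIGN", "DESIGN", "CONDUCT")))
  expect_equal(inquiryflow:::pattern_support(more, c("DESIGN", "CONDUCT")), 2)

  expect_error(mine_patterns(coded, groups, min_support = 0), "refused|blowup")
})

test_that("Wilson intervals match the printed pattern-table row and prop.test", {
  w <- wilson_ci(81, 86)
  expect_equal(round(w$estimate, 2), 0.94)
  expect_equal(round(w$conf.low, 2), 0.87)
  expect_equal(round(w$conf.high, 2), 0.97)

  z <- wilson_ci(0, 50)
  expect_equal(z$estimate, 0)
  expect_equal(z$conf.low, 0)

  # prop.test's (uncorrected) interval is the Wilson interval
  for (case in list(c(81, 86), c(135, 173), c(3, 10), c(0, 7))) {
    ours <- wilson_ci(case[1], case[2])
    ref <- suppressWarnings(prop.test(case[1], case[2], correct = FALSE))$conf.int
    expect_equal(c(ours$conf.low, ours$conf.high), as.numeric(ref), tolerance = 1e-10)
  }
  expect_error(wilson_ci(5, 0), "n >= 1")
})

test_that("the pooled two-proportion z test matches hand computation", {
  cmp <- compare_pattern_support(81, 86, 135, 173)
  expect_equal(cmp$z, 3.289, tolerance = 1e-3)
  expect_equal(cmp$p, 0.001, tolerance = 0.01)
  # z^2 equals the uncorrected chi-squared statistic
  chi <- prop.test(c(81, 135), c(86, 173), correct = FALSE)$statistic
  expect_equal(cmp$z^2, unname(chi), tolerance = 1e-10)
  # symmetric case
  same <- compare_pattern_support(10, 20, 10, 20)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
})

test_that("BH adjustment in the pattern table is monotone and conservative", {
  set.seed(5)
  seqs <- random_macro_seqs(24, max_len = 8)
  coded <- coded_from_macro(seqs)
  groups <- tibble::tibble(student_id = sprintf("S%03d", 1:24),
                           group = rep(c("A", "B"), each = 12))
  mined <- mine_patterns(coded, groups, min_support = 0.25)
  expect_true(all(mined$p_fdr >= mined$p_raw - 1e-12))
  ord <- order(mined$p_raw)
  expect_true(all(diff(mined$p_fdr[ord]) >= -1e-12))
  expect_equal(mined$p_fdr, p.adjust(mined$p_raw, "BH"))
})
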