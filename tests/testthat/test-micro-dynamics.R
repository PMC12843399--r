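test_that("normalized entropy hits its analytic anchors", {
  expect_equal(normalized_entropy(rep(micro_codes(), 5))$normalized, 1)
  expect_equal(normalized_entropy(rep("Run Trial", 9))$normalized, 0)
  two <- c(rep("Adjust Gate", 6), rep("Run Trial", 6))
  e <- normalized_entropy(two)
  expect_equal(e$H, 1)
  expect_equal(e$normalized, 1 / 3)
  expect_error(normalized_entropy(character(0)), "empty")
})

test_that("entropy depends only on the frequency profile", {
  set.seed(1)
  s <- sample(micro_codes(), 40, replace = TRUE)
  base <- normalized_entropy(s)$normalized
  expect_equal(normalized_entropy(sample(s))$normalized, base)
  # relabeling via a permutation of the alphabet
  perm <- setNames(sample(micro_codes()), micro_codes())
  expect_equal(normalized_entropy(unname(perm[s]))$normalized, base)
})

test_that("entropy group comparison is calibrated under the null", {
  set.seed(0)
  df <- tibble::tibble(
    normalized = rnorm(200, 0.8, 0.05),
    effectiveness = rep(c("Effective", "Ineffective"), each = 100),
    efficiency = rep(rep(c("Efficient", "Inefficient"), each = 50), 2)
  )
  ec <- entropy_group_comparison(df, B = 500, seed = 0)
  expect_true(all(ec$anova$partial_eta_sq < 0.05))
  expect_gt(ec$anova$p.value[ec$anova$term == "effectiveness:efficiency"], 0.01)
  # bootstrap CIs bracket the observed means
  expect_true(all(ec$means$conf.low <= ec$means$mean + 1e-9))
  expect_true(all(ec$means$conf.high >= ec$means$mean - 1e-9))

  # a strongly shifted cell is detected
  df2 <- df
  shift <- df2$effectiveness == "Effective" & df2$efficiency == "Efficient"
  df2$normalized[shift] <- df2$normalized[shift] + 0.25
  ec2 <- entropy_group_comparison(df2, B = 200, seed = 0)
  expect_lt(ec2$anova$p.value[ec2$anova$term == "effectiveness"], 0.001)

  # balanced design: partial eta^2 agrees with directly computed sums of squares
  fit <- lm(normalized ~ effectiveness * efficiency, data = df)
  ss <- anova(fit)  # sequential = Type II here because the design is balanced
  ss_err <- ss["Residuals", "Sum Sq"]
  for (term in c("effectiveness", "efficiency", "effectiveness:efficiency")) {
    expect_equal(ec$anova$partial_eta_sq[ec$anova$term == term],
                 ss[term, "Sum Sq"] / (ss[term, "Sum Sq"] + ss_err),
                 tolerance = 1e-10)
  }

  # seeded bootstrap is reproducible
  ec3 <- entropy_group_comparison(df, B = 500, seed = 0)
  expect_identical(ec$means, ec3$means)
})

test_that("ANOVA is refused when a cell is too small, means still reported", {
  df <- tibble::tibble(
    normalized = runif(7, 0.5, 0.9),
    effectiveness = c(rep("Effective", 4), rep("Ineffective", 3)),
    efficiency = c("Efficient", "Efficient", "Inefficient", "Inefficient",
                   "Efficient", "Efficient", "Inefficient")
  )
  expect_warning(ec <- entropy_group_comparison(df, B = 50, seed = 1), "refused")
  expect_null(ec$anova)
  expect_equal(nrow(ec$means), 4)
})

test_that("transition estimation follows the conditional-frequency rule", {
  seqs <- list(
    c("Start Task", "Adjust Gate", "Run Trial", "End Task"),
    c("Start Task", "Adjust Gate", "Run Trial", "End Task"),
    c("Start Task", "Adjust Gate", "Adjust Diameter", "Run Trial", "End Task"),
    c("Start Task", "Adjust Gate", "Adjust Diameter", "Run Trial", "End Task")
  )
  est <- estimate_transitions(seqs, alpha = 0)
  # Adjust Gate row has counts (2, 2) over Run Trial and Adjust Diameter
  expect_equal(est$probs["Adjust Gate", "Run Trial"], 0.5)
  expect_equal(est$probs["Adjust Gate", "Adjust Diameter"], 0.5)
  # a row never visited is flagged undefined
  expect_false(est$defined["Remove Record"])
  expect_true(all(is.na(est$probs["Remove Record", ])))
  # each sequence of length L contributes L - 1 pairs
  expect_equal(sum(est$counts), sum(lengths(seqs) - 1))
})

test_that("Dirichlet smoothing is the posterior mean it claims to be", {
  d <- inquiryflow:::transition_dims()
  prior <- matrix(0, 7, 7, dimnames = list(d$sources, d$targets))
  prior["Adjust Gate", c("Run Trial", "Adjust Diameter")] <- c(0.8, 0.2)
  prior["Start Task", "Adjust Gate"] <- 1
  prior["Run Trial", "End Task"] <- 1

  # row with counts (1, 0): (1 + 0.5*0.8)/(1 + 0.5), (0 + 0.5*0.2)/(1 + 0.5)
  seqs <- list(c("Start Task", "Adjust Gate", "Run Trial", "End Task"))
  sm <- estimate_transitions(seqs, prior = prior, alpha = 0.5)
  expect_equal(sm$probs["Adjust Gate", "Run Trial"], 1.4 / 1.5)
  expect_equal(sm$probs["Adjust Gate", "Adjust Diameter"], 0.1 / 1.5)

  # row with zero counts and a prior: the prior row itself
  expect_true(sm$defined["Adjust Diameter"] == FALSE)  # no prior, no data
  seqs2 <- list(c("Start Task", "Run Trial", "End Task"))
  sm2 <- estimate_transitions(seqs2, prior = prior, alpha = 0.5)
  expect_equal(sm2$probs["Adjust Gate", "Run Trial"], 0.8)
  expect_equal(sm2$probs["Adjust Gate", "Adjust Diameter"], 0.2)

  # alpha limits: raw at 1e-9, prior at 1e9
  tiny <- estimate_transitions(seqs, prior = prior, alpha = 1e-9)
  raw <- estimate_transitions(seqs, alpha = 0)
  expect_equal(tiny$probs["Adjust Gate", "Run Trial"],
               raw$probs["Adjust Gate", "Run Trial"], tolerance = 1e-8)
  huge <- estimate_transitions(seqs, prior = prior, alpha = 1e9)
  expect_equal(huge$probs["Adjust Gate", "Run Trial"], 0.8, tolerance = 1e-6)

  # defined smoothed rows stay row-stochastic
  rs <- rowSums(sm$probs[sm$defined & rowSums(prior) > 0, , drop = FALSE])
  expect_true(all(abs(rs - 1) < 1e-9))

  expect_error(estimate_transitions(seqs, prior = prior, alpha = -1), "non-negative")
})

test_that("smoothing helps exactly when the prior is the truth", {
  tm <- test_chain_matrix()
  d <- inquiryflow:::transition_dims()
  truth <- tm[d$sources, d$targets]
  err <- function(est) {
    pr <- est$probs
    ok <- !is.na(pr)
    max(abs(pr[ok] - truth[ok]))
  }
  set.seed(8)
  err_raw_small <- err_sm_small <- numeric(20)
  for (r in 1:20) {
    small <- sample_chain_paths(tm, 10)
    err_raw_small[r] <- err(estimate_transitions(small, alpha = 0))
    err_sm_small[r] <- err(estimate_transitions(small, prior = truth, alpha = 0.5))
  }
  expect_lt(mean(err_sm_small), mean(err_raw_small))
  # both estimators converge as n grows
  big <- sample_chain_paths(tm, 500)
  expect_lt(err(estimate_transitions(big, alpha = 0)), mean(err_raw_small))
  expect_lt(err(estimate_transitions(big, alpha = 0)), 0.06)
})

test_that("delta maps are silent for identical subgroups", {
  set.seed(9)
  seqs <- sample_chain_paths(test_chain_matrix(), 30)
  prior <- estimate_transitions(seqs, alpha = 0)
  dm <- bootstrap_deltas(seqs, seqs, prior = prior, B = 200, seed = 1)
  expect_true(all(dm$delta[!is.na(dm$delta)] == 0))
  expect_false(any(dm$significant, na.rm = TRUE))
})

test_that("a planted transition difference is flagged with the right sign", {
  tm_a <- test_chain_matrix()
  tm_b <- tm_a
  # move 0.3 of mass: subgroup B runs fewer, revises more, after a trial
  tm_b["Run Trial", "Revise Answer"] <- tm_a["Run Trial", "Revise Answer"] - 0.3
  tm_b["Run Trial", "Adjust Gate"] <- tm_a["Run Trial", "Adjust Gate"] + 0.3
  set.seed(10)
  seqs_a <- sample_chain_paths(tm_a, 150)
  seqs_b <- sample_chain_paths(tm_b, 150)
  prior <- estimate_transitions(c(seqs_a, seqs_b), alpha = 0)
  dm <- bootstrap_deltas(seqs_a, seqs_b, prior = prior, B = 400, seed = 0)
  expect_true(dm$significant["Run Trial", "Revise Answer"])
  expect_gt(dm$delta["Run Trial", "Revise Answer"], 0.2)
  expect_true(dm$significant["Run Trial", "Adjust Gate"])
  expect_lt(dm$delta["Run Trial", "Adjust Gate"], -0.2)
  # the significance flag is consistent with its interval
  sig <- dm$significant & !is.na(dm$significant)
  expect_true(all((dm$ci_low > 0 | dm$ci_high < 0)[sig]))

  # seeded bootstrap reproducibility
  dm2 <- bootstrap_deltas(seqs_a, seqs_b, prior = prior, B = 400, seed = 0)
  expect_identical(dm$ci_low, dm2$ci_low)
  expect_identical(dm$ci_high, dm2$ci_high)

  expect_error(bootstrap_deltas(seqs_a[1], seqs_b, prior = prior), "at least 2")
})

test_that("process graphs apply the display threshold and round-trip", {
  seqs <- list(
    c("Start Task", "Adjust Gate", "Run Trial", "End Task"),
    c("Start Task", "Adjust Gate", "Adjust Diameter", "Run Trial", "End Task"),
    c("Start Task", "Adjust Gate", "Run Trial", "Run Trial", "End Task")
  )
  est <- estimate_transitions(seqs, alpha = 0)
  # Adjust Gate row: Run Trial 2/3, Adjust Diameter 1/3 -> one edge at 0.5
  g <- build_process_graph(est, threshold = 0.5)
  ag <- g$edges[g$edges$from == "Adjust Gate", ]
  expect_equal(ag$to, "Run Trial")
  g_all <- build_process_graph(est, threshold = 1)
  expect_true(all(g_all$edges$prob == 1))
  expect_error(build_process_graph(est, threshold = 0), "threshold")
  expect_error(build_process_graph(est, threshold = 1.5), "threshold")

  # a crafted row (0.35, 0.29, 0.36) keeps exactly the two edges >= 0.30
  seqs2 <- list(c(rep(c("Run Trial", "Adjust Gate"), 35),
                  rep(c("Run Trial", "Adjust Diameter"), 29),
                  rep(c("Run Trial", "Revise Answer"), 36), "End Task"))
  est2 <- estimate_transitions(seqs2, alpha = 0)
  g2 <- build_process_graph(est2, threshold = 0.30)
  rt <- g2$edges[g2$edges$from == "Run Trial", ]
  expect_setequal(rt$to, c("Adjust Gate", "Revise Answer"))

  # DOT and JSON carry the same edge set
  dot <- withr::local_tempfile(fileext = ".dot")
  write_process_dot(g2, dot)
  parsed <- read_process_dot(dot)
  js <- jsonlite::fromJSON(process_graph_json(g2))
  expect_setequal(paste(parsed$from, parsed$to), paste(js$edges$from, js$edges$to))
  expect_equal(parsed$prob, round(js$edges$prob, 2))
})

test_that("tidy methods expose transitions and deltas as tibbles", {
  set.seed(11)
  seqs <- sample_chain_paths(test_chain_matrix(), 25)
  est <- estimate_transitions(seqs, alpha = 0)
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 49)
  expect_equal(sum(td$count), sum(est$counts))
  dm <- bootstrap_deltas(seqs, seqs, prior = est, B = 50, seed = 2)
  tdm <- tidy(dm)
  expect_true(all(c("delta", "conf.low", "conf.high", "significant") %in% names(tdm)))
})
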