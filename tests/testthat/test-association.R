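test_that("Fisher exact test reproduces hand-enumerable cases", {
  # strategy x sex table reconstructed from the published percentages
  expect_equal(fisher_exact(ref_strategy_by_sex)$p, 0.545, tolerance = 0.005)
  # 2x2 perfect separation: only the two extreme tables are as unlikely
  expect_equal(fisher_exact(cbind(c(5, 0), c(0, 5)))$p, 2 / 252)
  # identical rows carry no association signal
  expect_equal(fisher_exact(rbind(c(7, 3), c(7, 3)))$p, 1)
  expect_error(fisher_exact(rbind(c(0, 0), c(3, 4))), "degenerate")
})

test_that("Fisher p is invariant to row and column permutations", {
  set.seed(5)
  tab <- matrix(rpois(12, 8), nrow = 4)
  p0 <- fisher_exact(tab)$p
  expect_equal(fisher_exact(tab[sample(4), ])$p, p0)
  expect_equal(fisher_exact(tab[, sample(3)])$p, p0)
})

test_that("Bonferroni ledger reproduces the printed per-test thresholds", {
  expect_equal(bonferroni_family("fisher", 6)$alpha_printed, 0.008)
  expect_equal(bonferroni_family("ame", 40)$alpha_printed, 0.00125)
  expect_equal(bonferroni_family("kw", 18)$alpha_printed, 0.003)
  expect_equal(bonferroni_family("fisher", 6)$alpha_exact, 0.05 / 6)
  # flags are non-increasing in the family size at fixed raw p
  p_raw <- c(0.0009, 0.004, 0.02)
  n_sig <- vapply(c(6, 18, 40), function(m)
    sum(p_raw < bonferroni_family("f", m)$alpha_exact), numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("saturated multinomial AMEs equal differences of sample proportions", {
  set.seed(11)
  n <- 240
  geno <- sample(c("AA", "GA", "GG"), n, replace = TRUE, prob = c(0.2, 0.4, 0.4))
  labels <- sample(c("CC", "HS", "FR", "OT"), n, replace = TRUE,
                   prob = c(0.5, 0.1, 0.1, 0.3))
  am <- multinomial_ame(labels, geno, baseline = "AA", bootstrap_reps = 200,
                        seed = 3)
  # oracle: empirical proportion differences
  for (r in seq_len(nrow(am))) {
    p_g <- mean(labels[geno == am$level[r]] == am$strategy[r])
    p_b <- mean(labels[geno == "AA"] == am$strategy[r])
    expect_equal(am$ame[r], p_g - p_b, tolerance = 1e-12)
  }
  # probability differences over a simplex sum to zero per level
  for (lev in unique(am$level)) {
    expect_equal(sum(am$ame[am$level == lev]), 0, tolerance = 1e-12)
  }
})

test_that("fitted probabilities agree with an independent multinomial fit", {
  library(nnet)
  set.seed(19)
  n <- 150
  geno <- sample(c("L", "H"), n, replace = TRUE)
  labels <- sample(c("CC", "HS", "FR", "OT"), n, replace = TRUE)
  am <- multinomial_ame(labels, geno, baseline = "L", bootstrap_reps = 200,
                        seed = 3)
  fit <- nnet::multinom(factor(labels, levels = c("CC", "HS", "FR", "OT")) ~
                          factor(geno, levels = c("L", "H")),
                        trace = FALSE, maxit = 500)
  pred <- predict(fit, newdata = data.frame(geno = c("L", "H")), type = "probs")
  probs <- attr(am, "probs")
  expect_equal(unname(probs["L", ]), unname(pred[1, ]), tolerance = 1e-4)
  expect_equal(unname(probs["H", ]), unname(pred[2, ]), tolerance = 1e-4)
})

test_that("identical strategy distributions give zero AMEs; separation is flagged", {
  labels <- rep(c("CC", "HS", "FR", "OT"), times = 10)
  geno <- rep(c("GG", "AA"), each = 20)
  am <- multinomial_ame(labels, geno, baseline = "AA", bootstrap_reps = 200,
                        seed = 5)
  expect_equal(am$ame, rep(0, 4))

  labels2 <- c(rep("CC", 30), rep(c("CC", "HS", "FR", "OT"), 10))
  geno2 <- c(rep("GG", 30), rep("AA", 40))
  am2 <- multinomial_ame(labels2, geno2, baseline = "AA", bootstrap_reps = 200,
                         seed = 5)
  expect_true(all(am2$separation))
  expect_true(all(is.na(am2$p)))
  expect_error(multinomial_ame(labels2, rep("GG", 70), baseline = "GG",
                               bootstrap_reps = 200), "two genotype levels")
})

test_that("scenario means partition the schedule into three windows of seven", {
  expect_equal(scenario_means(0:20), c(low = 3, mid = 10, high = 17))
  expect_equal(scenario_means(rep(7L, 21)), c(low = 7, mid = 7, high = 7))
  expect_equal(scenario_means(rep(0L, 21)), c(low = 0, mid = 0, high = 0))
  # the three windows average back to the full-schedule mean
  set.seed(3)
  for (i in 1:10) {
    s <- sample(0:20, 21, replace = TRUE)
    expect_equal(mean(scenario_means(s)), mean(s))
  }
  sm <- scenario_means(rbind(0:20, rep(2L, 21)))
  expect_equal(sm$low, c(3, 2))
})

test_that("Kruskal-Wallis agrees with by-hand rank arithmetic", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # ranks 1..6, group rank sums 6 and 15: H = 12/(6*7) * (12 + 75) - 21
  expect_equal(res$H, 27 / 7)
  expect_equal(res$df, 1)
  expect_equal(kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))$H, 0)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two groups")
})

test_that("Kruskal-Wallis holds its level under label permutation", {
  set.seed(29)
  vals <- rnorm(60)
  groups <- rep(c("AA", "GA", "GG"), each = 20)
  pvals <- replicate(2000, kruskal_wallis(vals, sample(groups))$p)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("the battery stratifies by sex and files every test in one family", {
  co <- generate_cohort(cohort_spec(n = 160, seed = 21))
  frame <- cohort_analysis_frame(co)
  rep <- run_battery(frame, battery_config(bootstrap_reps = 200, seed = 21))
  tests <- rep$tests
  expect_setequal(unique(tests$family),
                  c("fisher", "ame", "kw_scenario", "kw_uninformed"))
  expect_setequal(unique(tests$sex), c("female", "male"))
  # family ledger: per-test thresholds as printed in the field
  expect_equal(unique(tests$alpha_printed[tests$family == "fisher"]), 0.008)
  expect_equal(unique(tests$alpha_printed[tests$family == "ame"]), 0.00125)
  expect_equal(unique(tests$alpha_printed[tests$family == "kw_scenario"]), 0.003)
  # flag definition: raw p below the exact threshold
  expect_equal(tests$significant,
               !is.na(tests$p) & tests$p < tests$alpha_exact)
  # 6 fisher + 6 uninformed KW + 18 scenario KW when all cells testable
  expect_equal(sum(tests$family == "fisher"), 6)
  expect_equal(sum(tests$family == "kw_uninformed"), 6)
  expect_equal(sum(tests$family == "kw_scenario"), 18)
})

test_that("a stratum-variant cell with one genotype level is skipped, m unchanged", {
  co <- generate_cohort(cohort_spec(n = 120, seed = 33,
                                    oxtr_a_freq = 0))   # all GG
  frame <- cohort_analysis_frame(co)
  rep <- run_battery(frame, battery_config(bootstrap_reps = 200, seed = 33))
  expect_true(any(grepl("oxtr", rep$skipped)))
  expect_false(any(rep$tests$variant == "oxtr"))
  expect_equal(unique(rep$tests$m[rep$tests$family == "fisher"]), 6L)
})
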