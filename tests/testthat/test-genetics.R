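test_that("MAOA coding follows the X-linked exclusion rules", {
  expect_equal(code_maoa("male", 4.5), "H")
  expect_equal(code_maoa("male", 3.5), "L")
  expect_equal(code_maoa("female", c(4.5, 4.5)), "H")
  expect_equal(code_maoa("female", c(3.5, 3.5)), "L")
  expect_equal(code_maoa("female", c(3.5, 4.5)), "excluded")  # X-inactivation
  expect_equal(code_maoa("female", c(5.5, 4.5)), "excluded")  # rare allele
  expect_equal(code_maoa("male", 6.5), "excluded")
  expect_equal(code_maoa("male", NA), "excluded")
  expect_error(code_maoa("male", 7.5), "outside")
  expect_error(code_maoa("male", c(3.5, 4.5)), "exactly 1")
  expect_error(code_maoa("female", 3.5), "exactly 2")
})

test_that("OXTR coding is order-independent", {
  expect_equal(code_oxtr(c("A", "G")), "GA")
  expect_equal(code_oxtr(c("G", "A")), "GA")
  expect_equal(code_oxtr(c("G", "G")), "GG")
  expect_equal(code_oxtr(c("A", "A")), "AA")
  expect_equal(code_oxtr(c("A", NA)), "excluded")
  expect_error(code_oxtr(c("A", "T")), "alleles")
})

test_that("RS3 length binning respects the inclusive boundaries", {
  expect_equal(bin_rs3(c(324, 341, 342, 356)),
               c("Short", "Short", "Long", "Long"))
  expect_error(bin_rs3(323), "outside")
  expect_error(bin_rs3(357), "outside")
  expect_equal(code_rs3(c(335, 345)), "Short/Long")
  expect_equal(code_rs3(c(345, 335)), "Short/Long")
  expect_equal(code_rs3(c(350, 345)), "Long/Long")
  expect_warning(g <- code_rs3(c(323, 345)), "outside")
  expect_equal(g, "excluded")
  expect_equal(code_rs3(c(NA, 345)), "excluded")
})

test_that("HWE chi-square reproduces the published genotype statistics", {
  rs3 <- hwe_test(ref_rs3_women + ref_rs3_men)   # pooled (42, 80, 63)
  expect_lt(abs(rs3$chi2 - 2.84), 0.02)
  expect_equal(round(rs3$p, 2), 0.09)              # printed precision
  expect_equal(rs3$df, 1L)

  oxtr <- hwe_test(ref_oxtr_women + ref_oxtr_men) # pooled (27, 67, 88)
  expect_lt(abs(oxtr$chi2 - 5.29), 0.02)
  expect_equal(round(oxtr$p, 2), 0.02)

  expect_equal(hwe_test(c(25, 50, 25))$chi2, 0)     # exact HWE proportions
  expect_equal(sum(oxtr$expected), sum(oxtr$observed))
})

test_that("HWE chi-square is invariant to allele relabeling and flags degeneracy", {
  cnt <- c(11, 52, 37)
  expect_equal(hwe_test(cnt)$chi2, hwe_test(rev(cnt))$chi2)
  degen <- hwe_test(c(40, 0, 0))
  expect_true(degen$degenerate)
  expect_equal(degen$chi2, 0)
  expect_error(hwe_test(c(0, 0, 0)), "zero")
  expect_error(hwe_test(c(-1, 5, 5)), "nonnegative")
})

test_that("HWE test rejects at the nominal rate under the null", {
  set.seed(77)
  p_allele <- 0.3
  n <- 120
  probs <- c(p_allele^2, 2 * p_allele * (1 - p_allele), (1 - p_allele)^2)
  draws <- stats::rmultinom(10000, n, probs)
  pvals <- apply(draws, 2, function(cnt) hwe_test(cnt)$p)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.01)
})

test_that("genotype counting drops exclusions and pools across sexes", {
  coded_oxtr <- data.frame(
    sex = c(rep("female", 105), rep("male", 79)),
    oxtr = c(rep(names(ref_oxtr_women), ref_oxtr_women), "excluded",
             rep(names(ref_oxtr_men), ref_oxtr_men), "excluded"),
    stringsAsFactors = FALSE
  )
  expect_equal(genotype_count_table(coded_oxtr, "oxtr", stratify_by_sex = TRUE)$female,
               setNames(c(18L, 38L, 48L), c("AA", "GA", "GG")))

  coded_rs3 <- data.frame(
    sex = c(rep("female", 106), rep("male", 80)),
    avpr1a = c(rep(names(ref_rs3_women), ref_rs3_women),
               rep(names(ref_rs3_men), ref_rs3_men), "excluded"),
    stringsAsFactors = FALSE
  )
  pooled <- genotype_count_table(coded_rs3, "avpr1a")
  expect_equal(unname(pooled), c(42L, 80L, 63L))
  strat <- genotype_count_table(coded_rs3, "avpr1a", stratify_by_sex = TRUE)
  expect_equal(strat$female + strat$male, pooled)
  expect_error(genotype_count_table(data.frame(oxtr = "excluded"), "oxtr"),
               "after exclusions")
})

test_that("female MAOA HWE uses the pre-exclusion table and refuses males", {
  subjects <- data.frame(
    sex = c(rep("female", 100), rep("male", 4)),
    maoa_a1 = c(rep(3.5, 30), rep(3.5, 50), rep(4.5, 20), rep(3.5, 4)),
    maoa_a2 = c(rep(3.5, 30), rep(4.5, 50), rep(4.5, 20), rep(NA, 4))
  )
  res <- maoa_female_hwe(subjects)
  expect_equal(unname(res$observed), c(30L, 50L, 20L))
  # oracle: p_hat = 110/200, chi-square computed by hand
  p_hat <- (2 * 30 + 50) / 200
  expected <- 100 * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
  expect_equal(res$chi2, sum((c(30, 50, 20) - expected)^2 / expected))

  bad <- subjects
  bad$maoa_a2[102] <- 4.5
  expect_error(maoa_female_hwe(bad), "hemizygous")
})
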