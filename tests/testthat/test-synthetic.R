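test_that("genotype draws respect allele frequencies and hemizygosity", {
  spec <- cohort_spec(n = 200, seed = 2,
                      maoa_freqs = c("3.5" = 1, "4.5" = 0, "5.5" = 0, "6.5" = 0))
  set.seed(2)
  geno <- draw_genotypes(spec)
  coded <- code_genotypes(geno)
  expect_true(all(coded$maoa == "L"))                 # fixed MAOA allele
  expect_true(all(is.na(geno$maoa_a2[geno$sex == "male"])))
  expect_true(all(!is.na(geno$maoa_a2[geno$sex == "female"])))
})

test_that("same seed reproduces the identical cohort", {
  a <- generate_cohort(cohort_spec(n = 60, seed = 14))
  b <- generate_cohort(cohort_spec(n = 60, seed = 14))
  expect_identical(a, b)
  expect_identical(attr(a, "archetype"), attr(b, "archetype"))
})

test_that("genotype marginals converge to Hardy-Weinberg proportions", {
  spec <- cohort_spec(n = 50000, seed = 8, oxtr_a_freq = 0.33)
  set.seed(8)
  geno <- draw_genotypes(spec)
  coded <- code_genotypes(geno)
  props <- prop.table(table(coded$oxtr))
  expect_lt(abs(props[["AA"]] - 0.33^2), 0.01)
  expect_lt(abs(props[["GA"]] - 2 * 0.33 * 0.67), 0.01)
  expect_lt(abs(props[["GG"]] - 0.67^2), 0.01)
})

test_that("frequency vectors must sum to one", {
  expect_error(cohort_spec(maoa_freqs = c("3.5" = 0.5, "4.5" = 0.4,
                                          "5.5" = 0, "6.5" = 0)), "sum to 1")
  expect_error(cohort_spec(rs3_length_freqs = c("330" = 0.7, "344" = 0.2)),
               "sum to 1")
  expect_error(cohort_spec(archetype_weights = c(CC = 1)), "named over")
})

test_that("noise-free archetypes map to their intended labels", {
  expect_equal(
    draw_schedule(archetype_spec("CC", list(beta = 1, intercept = 0), noise = 0)),
    0:20
  )
  expect_equal(
    draw_schedule(archetype_spec("FR", list(ceiling = 0), noise = 0)),
    rep(0L, 21)
  )
  tent <- draw_schedule(archetype_spec("HS", list(peak = 10, height = 20),
                                       noise = 0))
  expect_equal(classify_schedule(tent)$label, "HS")

  set.seed(55)
  for (i in 1:20) {
    beta <- runif(1, 0.5, 1)
    s_cc <- draw_schedule(archetype_spec("CC", list(beta = beta), noise = 0))
    expect_equal(classify_schedule(s_cc)$label, "CC")
    s_fr <- draw_schedule(archetype_spec("FR", noise = 0))
    expect_equal(classify_schedule(s_fr)$label, "FR")
    s_hs <- draw_schedule(archetype_spec("HS",
                                         list(peak = sample(6:14, 1),
                                              height = sample(10:20, 1)),
                                         noise = 0))
    expect_equal(classify_schedule(s_hs)$label, "HS")
    s_un <- draw_schedule(archetype_spec("UNCOND", noise = 0))
    expect_equal(classify_schedule(s_un)$label, "OT")
  }
})

test_that("free-rider schedules never exceed their ceiling even with noise", {
  set.seed(66)
  for (i in 1:20) {
    s <- draw_schedule(archetype_spec("FR", list(ceiling = 3), noise = 4))
    expect_true(max(s) <= 3)
  }
})

test_that("the cohort table round-trips through CSV unchanged", {
  co <- generate_cohort(cohort_spec(n = 40, seed = 77))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(co, path, row.names = FALSE, quote = FALSE)
  back <- read_subjects(path)
  attr(co, "archetype") <- NULL
  expect_equal(back, co, ignore_attr = TRUE)
})

test_that("uninformed contributions come from the subject's own schedule", {
  co <- generate_cohort(cohort_spec(n = 100, seed = 88))
  sched <- as.matrix(co[paste0("c", 0:20)])
  # every uninformed value appears somewhere in that subject's schedule
  hits <- vapply(seq_len(nrow(co)), function(i)
    co$uninformed[i] %in% sched[i, ], logical(1))
  expect_true(all(hits))
})

test_that("a planted genotype effect tilts the archetype mix for carriers", {
  spec <- cohort_spec(
    n = 4000, seed = 99, noise = 0,
    archetype_weights = c(CC = 0.4, HS = 0.2, FR = 0.2, UNCOND = 0.2, MISC = 0),
    effect = list(variant = "oxtr", level = "GG", tilt = c(CC = 4))
  )
  co <- generate_cohort(spec)
  coded <- code_genotypes(co)
  kinds <- attr(co, "archetype")
  p_gg <- mean(kinds[coded$oxtr == "GG"] == "CC")
  p_aa <- mean(kinds[coded$oxtr == "AA"] == "CC")
  # tilt 4: P(CC | GG) = 1.6/2.2 = 0.727 vs baseline 0.4
  expect_equal(p_gg, 1.6 / 2.2, tolerance = 0.05)
  expect_equal(p_aa, 0.4, tolerance = 0.07)
})
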