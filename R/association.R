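# Sex-stratified association battery: Fisher exact tests of strategy x
# genotype, multinomial-logit average marginal effects with bootstrap
# uncertainty, and Kruskal-Wallis tests on scenario means and uninformed
# contributions, each under its own Bonferroni family.

STRATEGY_LEVELS <- c("CC", "HS", "FR", "OT")

#' Bonferroni family ledger entry
#'
#' Per-test significance threshold for a family of `m` hypotheses at
#' family-wise level `family_alpha`. Both the exact threshold
#' (`family_alpha / m`) and its conventional printed rounding are reported;
#' significance flags throughout the package use the exact value, since the
#' printed rounding (e.g. 0.008 for 0.05/6 = 0.00833...) would be slightly
#' anti-conservative if used literally.
#'
#' @param name Family name.
#' @param m Number of hypotheses in the family.
#' @param family_alpha Family-wise error level (default 0.05).
#' @return List with `name`, `m`, `family_alpha`, `alpha_exact`,
#'   `alpha_printed`.
#' @examples
#' bonferroni_family("fisher", 6)$alpha_printed  # 0.008
#' @export
bonferroni_family <- function(name, m, family_alpha = 0.05) {
  if (m < 1) stop("`m` must be a positive integer")
  exact <- family_alpha / m
  # print exactly when the threshold terminates within 5 decimals
  # (0.05/40 = 0.00125), otherwise round to 3 decimals (0.008, 0.003)
  printed <- if (abs(exact - round(exact, 5)) < 1e-12) {
    round(exact, 5)
  } else {
    round(exact, 3)
  }
  list(name = name, m = as.integer(m), family_alpha = family_alpha,
       alpha_exact = exact, alpha_printed = printed)
}

#' Two-sided Fisher exact test for an r x c contingency table
#'
#' Exact enumeration over tables with fixed margins when feasible, switching
#' to a seeded fixed-margin Monte-Carlo estimate (at least `mc_draws` draws)
#' for tables too large to enumerate. The Monte-Carlo path is flagged in the
#' result.
#'
#' @param table Matrix of nonnegative counts, at least 2 nonempty rows and
#'   columns. Rows or columns with a zero margin are dropped before testing.
#' @param mc_draws Monte-Carlo draws for the fallback (minimum 1e5).
#' @param seed Seed for the Monte-Carlo fallback.
#' @return List with `p`, `monte_carlo` (logical) and the effective `table`.
#' @examples
#' fisher_exact(cbind(women = c(48, 13, 10, 36), men = c(44, 9, 8, 20)))$p
#' @export
fisher_exact <- function(table, mc_draws = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) stop("counts must be nonnegative")
  table <- table[rowSums(table) > 0, colSums(table) > 0, drop = FALSE]
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("degenerate table: fewer than two nonempty rows or columns")
  }
  mc_draws <- max(mc_draws, 1e5)
  res <- tryCatch(
    stats::fisher.test(table, workspace = 2e7),
    error = function(e) NULL
  )
  if (!is.null(res)) {
    return(list(p = res$p.value, monte_carlo = FALSE, table = table))
  }
  p <- local({
    set.seed(seed)
    stats::fisher.test(table, simulate.p.value = TRUE, B = mc_draws)$p.value
  })
  list(p = p, monte_carlo = TRUE, table = table)
}

#' Average marginal effects of genotype on strategy probabilities
#'
#' Fits the multinomial model `strategy ~ genotype` and reports, for each
#' non-baseline genotype level g and strategy s, the discrete-change average
#' marginal effect `P(s | g) - P(s | baseline)`. With a single categorical
#' predictor the model is saturated, so its maximum-likelihood fitted
#' probabilities are the within-genotype sample proportions, computed here in
#' closed form. Standard errors are the standard deviation of the effect over
#' seeded bootstrap resamples of subjects; p-values use the normal
#' approximation on `effect / SE`. A genotype level in which only one
#' strategy was observed (separation) is flagged, and for its effects the
#' bootstrap-percentile interval replaces the normal p.
#'
#' @param labels Per-subject strategy labels (CC/HS/FR/OT).
#' @param genotype Per-subject genotype category; `"excluded"`/`NA` dropped.
#' @param baseline Baseline genotype level.
#' @param bootstrap_reps Bootstrap resamples (minimum 200, default 1000).
#' @param seed Seed for the bootstrap.
#' @param ci_level Level for the percentile interval (default 0.95).
#' @return Data frame with one row per (level, strategy): `level`,
#'   `strategy`, `ame`, `se`, `p`, `ci_lo`, `ci_hi`, `separation`,
#'   `n_boot`. Attribute `"probs"` holds the fitted probability matrix.
#' @export
multinomial_ame <- function(labels, genotype, baseline,
                            bootstrap_reps = 1000L, seed = 1L,
                            ci_level = 0.95) {
  if (bootstrap_reps < 200L) stop("`bootstrap_reps` must be at least 200")
  keep <- !is.na(genotype) & genotype != "excluded" & !is.na(labels)
  labels <- as.character(labels)[keep]
  genotype <- as.character(genotype)[keep]
  levs <- unique(genotype)
  if (length(levs) < 2L) stop("need at least two genotype levels")
  if (!baseline %in% levs) stop(sprintf("baseline level '%s' not present", baseline))
  levs <- c(baseline, sort(setdiff(levs, baseline)))
  g <- match(genotype, levs)
  s <- match(labels, STRATEGY_LEVELS)
  if (anyNA(s)) stop("labels must be CC/HS/FR/OT")
  n <- length(g)
  G <- length(levs); K <- length(STRATEGY_LEVELS)

  prop_mat <- function(gi, si) {
    cnt <- matrix(tabulate(gi + G * (si - 1L), nbins = G * K), nrow = G)
    tot <- rowSums(cnt)
    cnt / ifelse(tot == 0, NA_real_, tot)
  }
  probs <- prop_mat(g, s)
  dimnames(probs) <- list(levs, STRATEGY_LEVELS)
  ame <- sweep(probs[-1, , drop = FALSE], 2, probs[1, ])

  # separation: a genotype level with a single observed strategy
  sep_level <- vapply(seq_len(G), function(i) {
    length(unique(s[g == i])) == 1L
  }, logical(1))

  boot <- array(NA_real_, dim = c(bootstrap_reps, G - 1L, K))
  local({
    set.seed(seed)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      pm <- prop_mat(g[idx], s[idx])
      if (anyNA(pm[1, ])) next  # baseline absent from resample
      boot[b, , ] <<- sweep(pm[-1, , drop = FALSE], 2, pm[1, ])
    }
  })

  rows <- do.call(rbind, lapply(seq_len(G - 1L), function(i) {
    do.call(rbind, lapply(seq_len(K), function(k) {
      draws <- boot[, i, k]
      draws <- draws[!is.na(draws)]
      se <- if (length(draws) > 1L) sd(draws) else NA_real_
      est <- ame[i, k]
      sep <- sep_level[1L] || sep_level[i + 1L]
      p <- if (sep || is.na(se) || se == 0) {
        NA_real_
      } else {
        2 * pnorm(-abs(est / se))
      }
      ci <- if (length(draws)) {
        quantile(draws, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2),
                 names = FALSE, type = 6)
      } else {
        c(NA_real_, NA_real_)
      }
      data.frame(
        level = levs[i + 1L], strategy = STRATEGY_LEVELS[k],
        ame = est, se = se, p = p, ci_lo = ci[1], ci_hi = ci[2],
        separation = sep, n_boot = length(draws),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(rows) <- NULL
  attr(rows, "probs") <- probs
  attr(rows, "baseline") <- baseline
  rows
}

#' Scenario means of a contingent schedule
#'
#' Per-subject means of the schedule over the three cooperation scenarios:
#' low (others' average 0-6), mid (7-13) and high (14-20), seven entries
#' each.
#'
#' @param schedule A 21-entry schedule, or a matrix/list of schedules.
#' @return Named numeric vector `c(low, mid, high)`, or a data frame with
#'   those columns for multiple schedules.
#' @examples
#' scenario_means(0:20)  # c(low = 3, mid = 10, high = 17)
#' @export
scenario_means <- function(schedule) {
  if (is.matrix(schedule) || is.data.frame(schedule) ||
      (is.list(schedule) && !is.numeric(schedule))) {
    sched <- as_schedule_list(schedule)
    out <- t(vapply(sched, scenario_means, numeric(3)))
    return(as.data.frame(out))
  }
  schedule <- validate_schedule(schedule)
  c(low = mean(schedule[1:7]), mid = mean(schedule[8:14]),
    high = mean(schedule[15:21]))
}

#' Kruskal-Wallis rank test across genotype groups
#'
#' Tie-corrected H statistic with a chi-square reference on `k - 1` degrees
#' of freedom.
#'
#' @param values Per-subject numeric values.
#' @param groups Per-subject group labels; `NA`/`"excluded"` dropped.
#' @return List with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups) & groups != "excluded"
  values <- values[keep]
  groups <- factor(as.character(groups)[keep])
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (length(unique(values)) == 1L) {
    # all observations tied: no rank variation, H = 0 by convention
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1, n = length(values)))
  }
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = length(values))
}

#' Battery configuration
#'
#' @param bootstrap_reps Bootstrap resamples for the marginal effects.
#' @param family_alpha Family-wise level (default 0.05).
#' @param m_fisher,m_ame,m_kw_scenario,m_kw_uninformed Family sizes: 6
#'   Fisher tests (3 variants x 2 sexes), 40 marginal-effect contrasts, 18
#'   Kruskal-Wallis scenario tests (3 variants x 3 scenarios x 2 sexes) and
#'   6 uninformed-contribution tests.
#' @param baselines Named list of baseline genotype levels per variant.
#' @param mc_draws Monte-Carlo budget for large Fisher tables.
#' @param seed Seed for bootstrap and Monte-Carlo steps.
#' @return List of class `"battery_config"`.
#' @export
battery_config <- function(bootstrap_reps = 1000L, family_alpha = 0.05,
                           m_fisher = 6L, m_ame = 40L, m_kw_scenario = 18L,
                           m_kw_uninformed = 6L,
                           baselines = list(maoa = "L", oxtr = "AA",
                                            avpr1a = "Long/Long"),
                           mc_draws = 1e5, seed = 1L) {
  structure(
    list(bootstrap_reps = as.integer(bootstrap_reps),
         family_alpha = family_alpha,
         families = list(
           fisher = bonferroni_family("fisher", m_fisher, family_alpha),
           ame = bonferroni_family("ame", m_ame, family_alpha),
           kw_scenario = bonferroni_family("kw_scenario", m_kw_scenario,
                                           family_alpha),
           kw_uninformed = bonferroni_family("kw_uninformed", m_kw_uninformed,
                                             family_alpha)
         ),
         baselines = baselines, mc_draws = mc_draws, seed = as.integer(seed)),
    class = "battery_config"
  )
}

#' Run the sex-stratified association battery
#'
#' For each sex stratum and each variant: (a) a Fisher exact test of the
#' strategy x genotype table; (b) multinomial average marginal effects of
#' each genotype level on each strategy probability; (c) Kruskal-Wallis
#' tests of the per-subject scenario means (low/mid/high) across genotypes;
#' (d) a Kruskal-Wallis test of the uninformed contributions across
#' genotypes. Each test carries its family's Bonferroni threshold; the
#' significance flag is `p < family_alpha / m` (exact). A stratum-variant
#' cell with fewer than two genotype levels is skipped and logged without
#' shrinking the family size.
#'
#' @param cohort Data frame with columns `sex`, `label` (CC/HS/FR/OT),
#'   `maoa`, `oxtr`, `avpr1a`, `uninformed`, `sm_low`, `sm_mid`, `sm_high`
#'   (see [cohort_analysis_frame()]).
#' @param config A [battery_config()].
#' @return List of class `"association_report"`: `tests` (one row per
#'   hypothesis), `ame` (full marginal-effect tables), `ledger` (the four
#'   Bonferroni families), `skipped` (character log), `n_flags`.
#' @export
run_battery <- function(cohort, config = battery_config()) {
  stopifnot(inherits(config, "battery_config"))
  need <- c("sex", "label", "maoa", "oxtr", "avpr1a", "uninformed",
            "sm_low", "sm_mid", "sm_high")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  variants <- c("maoa", "oxtr", "avpr1a")
  sexes <- intersect(c("female", "male"), unique(cohort$sex))
  tests <- list(); ames <- list(); skipped <- character(0)
  add_test <- function(family, sex, variant, test, statistic, p, note = "") {
    fam <- config$families[[family]]
    tests[[length(tests) + 1L]] <<- data.frame(
      family = family, sex = sex, variant = variant, test = test,
      statistic = statistic, p = p, m = fam$m,
      alpha_exact = fam$alpha_exact, alpha_printed = fam$alpha_printed,
      significant = !is.na(p) & p < fam$alpha_exact,
      note = note, stringsAsFactors = FALSE
    )
  }
  for (sex in sexes) {
    stratum <- cohort[cohort$sex == sex, , drop = FALSE]
    for (v in variants) {
      geno <- stratum[[v]]
      ok <- !is.na(geno) & geno != "excluded"
      sub <- stratum[ok, , drop = FALSE]
      if (length(unique(sub[[v]])) < 2L) {
        skipped <- c(skipped, sprintf("%s/%s: fewer than two genotype levels", sex, v))
        next
      }
      # (a) Fisher exact strategy x genotype
      tab <- table(factor(sub$label, levels = STRATEGY_LEVELS), sub[[v]])
      fe <- fisher_exact(tab, mc_draws = config$mc_draws, seed = config$seed)
      add_test("fisher", sex, v, "strategy x genotype", NA_real_, fe$p,
               if (fe$monte_carlo) "monte-carlo" else "")
      # (b) multinomial AMEs
      am <- tryCatch(
        multinomial_ame(sub$label, sub[[v]], baseline = config$baselines[[v]],
                        bootstrap_reps = config$bootstrap_reps,
                        seed = config$seed,
                        ci_level = 1 - config$families$ame$alpha_exact),
        error = function(e) {
          skipped <<- c(skipped, sprintf("%s/%s AME: %s", sex, v,
                                         conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(am)) {
        am$sex <- sex; am$variant <- v
        ames[[paste(sex, v)]] <- am
        for (r in seq_len(nrow(am))) {
          fam <- config$families$ame
          # flag rule is uniform: raw p below the exact per-test threshold;
          # separation rows carry no p (the percentile interval is reported
          # for inspection instead) and therefore never flag
          tests[[length(tests) + 1L]] <- data.frame(
            family = "ame", sex = sex, variant = v,
            test = sprintf("AME %s on %s", am$level[r], am$strategy[r]),
            statistic = am$ame[r], p = am$p[r], m = fam$m,
            alpha_exact = fam$alpha_exact, alpha_printed = fam$alpha_printed,
            significant = !is.na(am$p[r]) && am$p[r] < fam$alpha_exact,
            note = if (am$separation[r]) "separation" else "",
            stringsAsFactors = FALSE
          )
        }
      }
      # (c) Kruskal-Wallis on scenario means
      for (sc in c("low", "mid", "high")) {
        kw <- kruskal_wallis(sub[[paste0("sm_", sc)]], sub[[v]])
        add_test("kw_scenario", sex, v, paste0(sc, " scenario"), kw$H, kw$p)
      }
      # (d) Kruskal-Wallis on uninformed contributions
      kw <- kruskal_wallis(sub$uninformed, sub[[v]])
      add_test("kw_uninformed", sex, v, "uninformed", kw$H, kw$p)
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(
    list(tests = tests, ame = ames, ledger = config$families,
         skipped = skipped, n_flags = sum(tests$significant)),
    class = "association_report"
  )
}

#' @export
print.association_report <- function(x, ...) {
  cat(sprintf("Association battery: %d tests, %d significant after Bonferroni\n",
              nrow(x$tests), x$n_flags))
  for (fam in x$ledger) {
    cat(sprintf("  family %-13s m = %2d, per-test alpha %.5g (printed %g)\n",
                fam$name, fam$m, fam$alpha_exact, fam$alpha_printed))
  }
  if (length(x$skipped)) cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
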