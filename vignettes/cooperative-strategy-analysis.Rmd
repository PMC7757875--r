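---
title: "Cooperative-strategy phenotyping and candidate-gene association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative-strategy phenotyping and candidate-gene association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopgene)
```

## The measurement problem

In a linear public goods game, four players each hold 20 tokens (worth 250
CLP apiece); tokens contributed to a common pot are doubled and split
equally, so the payoff of player $i$ is

$$\pi_i = \left(20 - g_i + 0.5 \sum_{j=1}^{4} g_j\right) \times 250\ \text{CLP}.$$

The marginal return of a contributed token (0.5) is below that of a kept
token (1), so free riding is individually dominant whatever the others do —
observed contributions alone cannot separate a cooperative disposition from
optimistic expectations about the group. The strategy method resolves this
by eliciting a complete contingent plan: a 21-entry schedule stating the
player's contribution for each possible rounded average contribution
(0–20) of the other three. One group member, chosen at random, is paid by
their schedule evaluated at the others' rounded average uninformed
contribution; the rest are paid by their uninformed choices. Since either
decision may bind, both are incentive compatible. `coopgene` implements
this machinery (`pgg_payoff()`, `resolve_group()`), the schedule
classifier, genotype coding for three candidate variants, and the
sex-stratified association battery, plus a synthetic cohort generator that
makes the whole pipeline testable end to end.

## Classifying schedules

`classify_schedule()` applies four rules in strict order:

1. **Free rider (FR)** — the maximum schedule entry is at or below
   `round_half_up(fr_fraction * 20)` tokens: 4 at the default 20% cutoff,
   2 and 6 at the 10%/30% robustness cutoffs. The screen precedes the
   correlation tests, so a constant-4 schedule is FR even though its rank
   correlation is undefined.
2. **Hump-shaped (HS)** — for some split $k$ (first segment = entries for
   others' average $0..k-1$, $k = 3..18$), the Spearman correlation of the
   first segment with the others' average is significantly positive *and*
   that of the complement significantly negative, both at the 1% level.
3. **Conditional cooperator (CC)** — the full 21-entry Spearman
   coefficient is significantly positive at 1%.
4. **Other (OT)** — everything else, including unconditional cooperators,
   whose constant schedules have no defined rank correlation.

Design choices that the verbal rule leaves open, settled here once:

* *Both-significant reading of the sign change.* "A positive-to-negative
  change … at a 1% significance level" is read as both segment
  coefficients individually significant with the required signs — the
  strictest reading, which stops noise-level sign flips from triggering
  HS.
* *Two-sided tests with a sign requirement* (default), matching the
  default behavior of standard correlation tests; a one-sided variant is
  available via `classifier_config(sided = "one")`.
* *CC is judged on the whole schedule*, as in the precursor
  strategy-method protocol; the rule names no segment.
* *Constant segments* yield an undefined correlation treated as not
  significant — forced by the mathematics, and consistent with
  unconditional cooperators landing in OT.
* *Ties get average (midrank) ranks*, the standard Spearman convention.

### Exact small-sample p-values

Short segments make the $t$ approximation to the Spearman null
unreliable, so for segments of $n \le 8$ the two-sided p-value is computed
by exact enumeration of all $n!$ rank permutations (cached per tie
pattern; the null distribution depends only on the two rank multisets).
One useful consequence: a first segment of length 3 can never fire the
hump flag, because the smallest achievable two-sided exact p is
$2/3! = 1/3$, far above 1% — the sliding-split search effectively begins
contributing at $k = 6$. Above $n = 8$ the usual
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ reference is used, with $p = 0$ at
$|\rho| = 1$.

## Genotype coding and Hardy–Weinberg testing

*MAOA*-uVNTR is X-linked: men carry one allele (4.5 repeats → MAOA-H, 3.5
→ MAOA-L), women two. Heterozygous (3.5/4.5) women are excluded because
random X-inactivation makes the expressed allele unknowable; carriers of
the rare 5.5/6.5 alleles are excluded outright. *OXTR* rs53576 codes to
GG/GA/AA. *AVPR1a* RS3 fragment lengths bin to Short (324–341 bp) and
Long (342–356 bp), both boundaries inclusive; lengths outside that
support are rejected rather than extrapolated, because no behavior is
defined beyond it.

`hwe_test()` is the 1-df Pearson chi-square on the genotype counts with
allele frequencies estimated from the same counts, *without* continuity
correction — the corrected variant does not reproduce the reference
values this implementation is validated against (χ² = 2.84 for the pooled
RS3 counts 42/80/63 and 5.29 for the pooled OXTR counts 27/67/88).
Female MAOA HWE (`maoa_female_hwe()`) runs on the pre-exclusion genotype
table, since a table purged of heterozygotes carries no HWE information;
male (hemizygous) counts are refused.

## The association battery

All analyses run separately by sex. Four Bonferroni families at
family-wise level 0.05:

| family | test | m | per-test α (exact) | printed |
|---|---|---|---|---|
| fisher | strategy × genotype, Fisher exact | 6 | 0.00833… | 0.008 |
| ame | multinomial marginal effects | 40 | 0.00125 | 0.00125 |
| kw_scenario | Kruskal–Wallis, scenario means | 18 | 0.00278… | 0.003 |
| kw_uninformed | Kruskal–Wallis, uninformed | 6 | 0.00833… | 0.008 |

Flags use the exact threshold; the printed rounding would be slightly
anti-conservative if applied literally. Scenario means are per-subject
averages of schedule entries over others' averages 0–6 (low), 7–13 (mid)
and 14–20 (high) — one value per subject, preserving independence of the
observations entering the rank test. A stratum-variant cell with fewer
than two genotype levels is skipped and logged; the family size is not
reduced.

The multinomial model `strategy ~ genotype` has a single categorical
predictor, so it is saturated and its maximum-likelihood fitted
probabilities are the within-genotype sample proportions; the average
marginal effect of level $g$ on strategy $s$ is
$\hat P(s\,|\,g) - \hat P(s\,|\,\text{baseline})$, computed in closed
form (the test suite cross-checks the fitted probabilities against an
iterative multinomial fit). Uncertainty comes from a seeded nonparametric
bootstrap over subjects (default 1000 resamples), with a normal
approximation on effect/SE for the p-value. Two caveats are flagged
rather than hidden:

* **Separation** — a genotype level in which a single strategy was
  observed gets no p-value (the bootstrap cannot represent its
  uncertainty); the percentile interval is reported and the row never
  counts as significant.
* **Boundary cells** — when a small genotype cell has an observed zero
  count for some strategy, resampling reproduces the zero every time, the
  bootstrap SE shrinks, and the normal-approximation p can be markedly
  anti-conservative. At cohorts of a few dozen subjects per stratum this
  inflates the AME family's realized false-positive rate well above its
  nominal Bonferroni level: in the package's own null simulations at the
  default cohort composition (188 subjects), roughly a third of replicates
  show at least one AME flag, almost all traceable to zero-count cells. A
  delta-method variance from a fitted multinomial would behave oppositely
  (inflated SEs under near-separation). Users should treat isolated AME
  flags in small cohorts with corresponding suspicion; the Fisher,
  Kruskal–Wallis and separation-handling paths hold their levels.

`fisher_exact()` and `kruskal_wallis()` delegate to the standard exact
network algorithm and tie-corrected rank test; Fisher tables too large to
enumerate fall back to a seeded fixed-margin Monte-Carlo estimate with at
least $10^5$ draws, flagged in the result.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws genotypes allele-by-allele under configurable
frequencies (Hardy–Weinberg by construction, one MAOA allele for men) and
schedules from five archetypes: CC (linear with slope β ∈ (0,1] — the
"selfish bias" that makes empirical conditional cooperators average below
the diagonal), HS (a tent with configurable peak and height), FR (capped
at the ceiling), UNCOND (constant) and MISC (arbitrary entries, so the OT
class contains genuinely unclassifiable patterns, not only constants).
Entrywise integer jitter (default half-width 2 tokens, clipped to range)
adds noise. Defaults follow the reference cohort: n = 188 with 107 women,
archetype weights at the observed pooled strategy mix (CC 92, HS 22,
FR 18, UNCOND 3, MISC 53 of 188), MAOA-L allele frequency 0.54 with the
rare alleles at 0.01 each, OXTR A at 0.33, and RS3 length frequencies
giving a Short-bin frequency of 0.56.

Uninformed contributions are generated by evaluating the subject's own
schedule at a binomial(20, 0.45) "belief" about the others' average —
embodying the point that uninformed actions mix strategy with
expectations. An optional planted effect multiplies archetype weights for
carriers of one genotype level, for power and recovery studies.

The generator does **not** simulate linkage disequilibrium, population
admixture, genotyping error, or within-subject inconsistency between the
two decision types. Passing recovery tests therefore show that the
pipeline recovers the structure this model plants — not that real
cohorts satisfy the model.

## Numerical and degenerate-input conventions

* Others'-average rounding is half-up (8.5 → 9), configurable only in
  the sense that it is isolated in `round_half_up()`; it matters only for
  .5 averages.
* Payoffs are computed in integer half-token units (multiples of 125
  CLP), so the accounting identity
  $\sum \pi_i = 250\,(80 + \sum g_i)$ holds exactly.
* A monomorphic HWE sample returns χ² = 0 with a degenerate flag; an
  all-tied Kruskal–Wallis sample returns H = 0.
* Bootstrap resamples that lose the baseline genotype level are dropped
  from the SE computation and counted in `n_boot`.
* Report files serialize percentages and χ² at two decimals and p-values
  at three or more, and identical configuration + seed reproduce
  byte-identical bundles.

## Problem sizes used in the validation suite

The shipped tests exercise: exact-vs-enumerated Spearman p-values up to
n = 7; classifier recovery on a 2,000-subject low-noise cohort (observed
maximum label error ≈ 1.4 percentage points against a ±3-point band);
null-battery behavior over 200 seeded cohorts of 188; planted-effect
recovery on 20 cohorts of 5,000 with 200-resample bootstraps (all
recovered effects positive, interval coverage at the nominal level); and
Hardy–Weinberg calibration over 10,000 simulated genotype tables. These
sizes were chosen so that Monte-Carlo error is small relative to each
assertion's band.

## Known limitations

* The AME bootstrap-normal p-value's boundary-cell anti-conservatism,
  discussed above, is the dominant caveat at candidate-gene sample sizes.
* The exact Spearman path covers segments up to n = 8; intermediate
  segment lengths rely on the t approximation, which is slightly
  approximate in the presence of heavy ties.
* The 40-hypothesis marginal-effect family size is the conventional
  count of genotype-level × strategy contrasts across variants and sexes;
  cohorts with missing levels keep the nominal family size (conservative)
  rather than shrinking it.
* Robustness sweeps over the FR cutoff guarantee label monotonicity (FR
  at 10% implies FR at 20% and 30%), but non-FR labels can change only by
  absorption into FR — there is no analogous guarantee across `alpha`.
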