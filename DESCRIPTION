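Package: coopgene
Title: Cooperative-Strategy Phenotyping and Candidate-Gene Association for
    Public-Goods-Game Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene studies of cooperation measured with the
    strategy method in a four-player public goods game. Implements the game's
    payoff mechanics and incentive-compatible group resolution, a four-way
    classifier of contingent-contribution schedules into conditional
    cooperators, hump-shaped contributors, free riders and others (sliding
    Spearman sign-change segmentation with exact small-sample permutation
    p-values), genotype coding for MAOA-uVNTR (X-linked), OXTR rs53576 and
    AVPR1a RS3 with Hardy-Weinberg equilibrium testing, and a sex-stratified
    association battery (Fisher exact tests, multinomial-logit average
    marginal effects with bootstrapped uncertainty, Kruskal-Wallis tests over
    contribution scenarios) under Bonferroni family-wise control. A synthetic
    cohort generator with archetype-derived schedules and Hardy-Weinberg
    genotypes makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nnet,
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
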