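# Genotype coding for the three candidate variants, and Hardy-Weinberg
# equilibrium testing. MAOA-uVNTR is X-linked: men are hemizygous (one
# allele), women carry two; heterozygous women are excluded because random
# X-inactivation makes the expressed allele unknowable.

MAOA_ALLELES <- c(3.5, 4.5, 5.5, 6.5)
RS3_SHORT <- c(324L, 341L)
RS3_LONG <- c(342L, 356L)

#' Code MAOA-uVNTR raw repeat alleles into expression classes
#'
#' The 4.5-repeat allele is the high-expression (MAOA-H) variant and 3.5 the
#' low-expression (MAOA-L) variant. Carriers of the rare 5.5 or 6.5 repeats
#' are excluded, as are heterozygous (3.5/4.5) women, whose expressed allele
#' cannot be determined under random X-inactivation.
#'
#' @param sex `"female"` or `"male"`.
#' @param alleles Repeat counts: one value for males, two for females, each
#'   in `{3.5, 4.5, 5.5, 6.5}`. `NA` values yield `"excluded"`.
#' @return `"H"`, `"L"` or `"excluded"`.
#' @examples
#' code_maoa("male", 4.5)            # "H"
#' code_maoa("female", c(3.5, 4.5))  # "excluded"
#' @export
code_maoa <- function(sex, alleles) {
  sex <- match.arg(sex, c("female", "male"))
  if (all(is.na(alleles))) return("excluded")
  alleles <- alleles[!is.na(alleles)]
  if (!all(alleles %in% MAOA_ALLELES)) {
    stop(sprintf("MAOA repeat allele outside {%s}",
                 paste(MAOA_ALLELES, collapse = ", ")))
  }
  expected <- if (sex == "male") 1L else 2L
  if (length(alleles) != expected) {
    stop(sprintf("%s must carry exactly %d MAOA allele%s (X-linked)",
                 sex, expected, if (expected > 1L) "s" else ""))
  }
  if (any(alleles %in% c(5.5, 6.5))) return("excluded")
  if (sex == "male") {
    return(if (alleles == 4.5) "H" else "L")
  }
  if (alleles[1] != alleles[2]) return("excluded")  # heterozygous woman
  if (alleles[1] == 4.5) "H" else "L"
}

#' Code OXTR rs53576 alleles
#'
#' Unordered pair of A/G alleles; the heterozygote is reported as `"GA"`.
#'
#' @param alleles Two values in `{"A", "G"}`; `NA` yields `"excluded"`.
#' @return `"AA"`, `"GA"`, `"GG"` or `"excluded"`.
#' @export
code_oxtr <- function(alleles) {
  if (anyNA(alleles)) return("excluded")
  if (length(alleles) != 2L || !all(alleles %in% c("A", "G"))) {
    stop("OXTR alleles must be two values in {A, G}")
  }
  n_g <- sum(alleles == "G")
  c("AA", "GA", "GG")[n_g + 1L]
}

#' Bin an AVPR1a RS3 allele length into Short/Long
#'
#' Microsatellite fragment lengths of 324-341 bp are `"Short"` and
#' 342-356 bp `"Long"` (both ranges inclusive), the conventional two-bin
#' treatment of a repeat with many low-frequency alleles.
#'
#' @param length_bp Integer allele length(s) in base pairs.
#' @return Character vector of `"Short"`/`"Long"`.
#' @examples
#' bin_rs3(c(341, 342))  # "Short" "Long"
#' @export
bin_rs3 <- function(length_bp) {
  if (any(!is.na(length_bp) &
          (length_bp < RS3_SHORT[1] | length_bp > RS3_LONG[2]))) {
    bad <- length_bp[!is.na(length_bp) &
                       (length_bp < RS3_SHORT[1] | length_bp > RS3_LONG[2])][1]
    stop(sprintf("RS3 allele length %s bp outside observed support [%d, %d]",
                 format(bad), RS3_SHORT[1], RS3_LONG[2]))
  }
  ifelse(length_bp <= RS3_SHORT[2], "Short", "Long")
}

#' Code an AVPR1a RS3 genotype from two allele lengths
#'
#' @param lengths_bp Two allele lengths in base pairs; out-of-range or `NA`
#'   alleles make the genotype `"excluded"` (out-of-range with a warning).
#' @return `"Short/Short"`, `"Short/Long"`, `"Long/Long"` or `"excluded"`.
#' @export
code_rs3 <- function(lengths_bp) {
  if (anyNA(lengths_bp)) return("excluded")
  if (length(lengths_bp) != 2L) stop("RS3 genotype needs two allele lengths")
  bins <- tryCatch(bin_rs3(lengths_bp), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NULL
  })
  if (is.null(bins)) return("excluded")
  n_long <- sum(bins == "Long")
  c("Short/Short", "Short/Long", "Long/Long")[n_long + 1L]
}

#' Code all three variants for a subject table
#'
#' @param subjects Data frame with columns `sex`, `maoa_a1`, `maoa_a2`
#'   (NA for males), `oxtr_a1`, `oxtr_a2`, `rs3_a1_bp`, `rs3_a2_bp`.
#' @return Data frame with columns `maoa`, `oxtr`, `avpr1a` (analysis-ready
#'   labels, `"excluded"` where the coding rules drop the subject).
#' @export
code_genotypes <- function(subjects) {
  need <- c("sex", "maoa_a1", "maoa_a2", "oxtr_a1", "oxtr_a2",
            "rs3_a1_bp", "rs3_a2_bp")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(subjects)
  maoa <- character(n); oxtr <- character(n); avpr1a <- character(n)
  for (i in seq_len(n)) {
    sex <- subjects$sex[i]
    m_alleles <- if (identical(sex, "male")) {
      subjects$maoa_a1[i]
    } else {
      c(subjects$maoa_a1[i], subjects$maoa_a2[i])
    }
    maoa[i] <- code_maoa(sex, m_alleles)
    oxtr[i] <- code_oxtr(c(subjects$oxtr_a1[i], subjects$oxtr_a2[i]))
    avpr1a[i] <- code_rs3(c(subjects$rs3_a1_bp[i], subjects$rs3_a2_bp[i]))
  }
  data.frame(maoa = maoa, oxtr = oxtr, avpr1a = avpr1a,
             stringsAsFactors = FALSE)
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' For a biallelic system with genotype counts (hom1, het, hom2): estimates
#' the allele frequency from the counts, forms expected counts
#' `n * (p^2, 2pq, q^2)`, and computes the 1-df Pearson chi-square without
#' continuity correction.
#'
#' @param counts Numeric vector of the three genotype counts, ordered
#'   (hom-reference, heterozygote, hom-alternate). Names are kept.
#' @return A list of class `"hwe_result"`: `chi2`, `df`, `p`,
#'   `allele_freq` (estimated frequency of the first-named allele),
#'   `observed`, `expected`, `degenerate` (TRUE when the sample is
#'   monomorphic, in which case `chi2 = 0` by convention).
#' @examples
#' hwe_test(c(42, 80, 63))  # chi2 = 2.84 on the pooled RS3 counts
#' @export
hwe_test <- function(counts) {
  if (length(counts) != 3L || any(counts < 0) || anyNA(counts)) {
    stop("`counts` must be three nonnegative genotype counts")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count is zero")
  p_hat <- (2 * counts[[1]] + counts[[2]]) / (2 * n)
  if (p_hat == 0 || p_hat == 1) {
    return(structure(
      list(chi2 = 0, df = 1L, p = 1, allele_freq = p_hat,
           observed = counts, expected = counts, degenerate = TRUE),
      class = "hwe_result"
    ))
  }
  q_hat <- 1 - p_hat
  expected <- n * c(p_hat^2, 2 * p_hat * q_hat, q_hat^2)
  chi2 <- sum((counts - expected)^2 / expected)
  structure(
    list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE),
         allele_freq = p_hat, observed = counts, expected = expected,
         degenerate = FALSE),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.2f (df = %d), p = %.3g%s\n",
              x$chi2, x$df, x$p, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Genotype counts per variant, excluding dropped subjects
#'
#' @param coded Data frame from [code_genotypes()] (columns `maoa`, `oxtr`,
#'   `avpr1a`), plus a `sex` column when stratifying.
#' @param variant `"maoa"`, `"oxtr"` or `"avpr1a"`.
#' @param stratify_by_sex Partition counts by sex (requires a `sex` column);
#'   pooled counts are the sum over sexes.
#' @return Named integer vector of counts in genotype-class order, or a list
#'   of such vectors (one per sex) when stratified.
#' @export
genotype_count_table <- function(coded, variant = c("maoa", "oxtr", "avpr1a"),
                                 stratify_by_sex = FALSE) {
  variant <- match.arg(variant)
  classes <- switch(variant,
    maoa = c("H", "L"),
    oxtr = c("AA", "GA", "GG"),
    avpr1a = c("Long/Long", "Short/Long", "Short/Short")
  )
  count_one <- function(values) {
    values <- values[values != "excluded" & !is.na(values)]
    if (length(values) == 0L) stop("no genotypes left after exclusions")
    tab <- table(factor(values, levels = classes))
    setNames(as.integer(tab), classes)
  }
  if (stratify_by_sex) {
    if (is.null(coded$sex)) stop("stratification requires a `sex` column")
    lapply(split(coded[[variant]], coded$sex), count_one)
  } else {
    count_one(coded[[variant]])
  }
}

#' HWE test for female MAOA genotypes before exclusion
#'
#' MAOA-uVNTR is X-linked, so Hardy-Weinberg proportions are only testable in
#' women; male (hemizygous) genotypes are refused. The test runs on the
#' pre-exclusion female genotype table (3.5/3.5, 3.5/4.5, 4.5/4.5 counts,
#' dropping 5.5/6.5 carriers only) because a table purged of heterozygotes
#' cannot carry HWE information.
#'
#' @param subjects Raw subject table with `sex`, `maoa_a1`, `maoa_a2`.
#' @return An [hwe_test()] result on counts (3.5/3.5, 3.5/4.5, 4.5/4.5).
#' @export
maoa_female_hwe <- function(subjects) {
  if (any(subjects$sex == "male" & !is.na(subjects$maoa_a2))) {
    stop("male MAOA genotypes are hemizygous; HWE is testable only in women")
  }
  fem <- subjects[subjects$sex == "female", , drop = FALSE]
  a1 <- fem$maoa_a1; a2 <- fem$maoa_a2
  keep <- !is.na(a1) & !is.na(a2) &
    a1 %in% c(3.5, 4.5) & a2 %in% c(3.5, 4.5)
  a1 <- a1[keep]; a2 <- a2[keep]
  n_low <- (a1 == 3.5) + (a2 == 3.5)
  counts <- setNames(
    as.integer(table(factor(n_low, levels = c(2, 1, 0)))),
    c("3.5/3.5", "3.5/4.5", "4.5/4.5")
  )
  hwe_test(counts)
}
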