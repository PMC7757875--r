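# Spearman rank correlation with exact permutation p-values for short
# segments. The classifier calls this on every sliding-split segment, so the
# exact null distributions (which depend only on the two rank-tie patterns,
# not on the data values) are cached per tie pattern.

.perm_cache <- new.env(parent = emptyenv())

# all permutations of 1..n as an n! x n integer matrix (n <= 8 in practice)
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- all_permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, sub + (sub >= i))
    }))
  }
  storage.mode(p) <- "integer"
  .perm_cache[[key]] <- p
  p
}

.null_cache <- new.env(parent = emptyenv())

# exact null distribution of rho given the two midrank multisets
spearman_null_rhos <- function(rx, ry) {
  n <- length(rx)
  key <- paste(c(n, sort(rx), sort(ry)), collapse = ",")
  cached <- .null_cache[[key]]
  if (!is.null(cached)) return(cached)
  P <- all_permutations(n)
  xc <- rx - mean(rx)
  Y <- matrix(ry[P], nrow = nrow(P), ncol = n)
  Yc <- Y - mean(ry)
  rhos <- as.vector(Yc %*% xc) / sqrt(sum(xc^2) * sum((ry - mean(ry))^2))
  .null_cache[[key]] <- rhos
  rhos
}

# internal fast core: alt is "two.sided", "greater" or "less" (pre-matched)
spearman_core <- function(x, y, alt, exact_max = 8L) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  xc <- rx - mx
  yc <- ry - my
  sxx <- sum(xc * xc)
  syy <- sum(yc * yc)
  if (sxx == 0 || syy == 0) {
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE, n = n,
                method = "undefined"))
  }
  rho <- sum(xc * yc) / sqrt(sxx * syy)
  eps <- 1e-8
  if (n <= exact_max) {
    rhos <- spearman_null_rhos(rx, ry)
    p <- if (alt == "two.sided") {
      mean(abs(rhos) >= abs(rho) - eps)
    } else if (alt == "greater") {
      mean(rhos >= rho - eps)
    } else {
      mean(rhos <= rho + eps)
    }
    method <- "exact"
  } else {
    if (abs(rho) >= 1 - eps) {
      p_two <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_two <- 2 * pt(-abs(tstat), df = n - 2)
    }
    p <- if (alt == "two.sided") {
      p_two
    } else if (alt == "greater") {
      if (rho >= 0) p_two / 2 else 1 - p_two / 2
    } else {
      if (rho <= 0) p_two / 2 else 1 - p_two / 2
    }
    method <- "t-approx"
  }
  list(rho = rho, p = p, defined = TRUE, n = n, method = method)
}

#' Spearman rank correlation with a small-sample exact p-value
#'
#' Computes the Spearman coefficient on average (midrank) ranks, allowing
#' ties. The two-sided p-value is obtained by exact enumeration of all `n!`
#' permutations of one rank vector when `n <= 8`, and from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom otherwise (`|rho| = 1` with `n > 8` yields `p = 0`). If either
#' input is constant the correlation is undefined and the result is flagged.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max Largest `n` for which the exact permutation null is used.
#' @return A list with elements `rho`, `p`, `defined` (FALSE when a vector is
#'   constant, in which case `rho` and `p` are `NA`), `n` and `method`
#'   (`"exact"` or `"t-approx"`).
#' @examples
#' spearman_with_p(0:20, 0:20)          # rho = 1, p = 0
#' spearman_with_p(0:2, c(5, 5, 5))     # undefined: constant segment
#' @export
spearman_with_p <- function(x, y, alternative = c("two.sided", "greater", "less"),
                            exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least two observations")
  spearman_core(x, y, alternative, exact_max = exact_max)
}
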