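#' Configuration for the cooperative-strategy classifier
#'
#' @param fr_fraction Fraction of the endowment defining the free-rider
#'   ceiling; a schedule whose maximum entry is at or below
#'   `round_half_up(fr_fraction * tokens)` tokens is a free rider. Default
#'   0.20 (4 tokens of 20); 0.10 and 0.30 are the conventional robustness
#'   values (2 and 6 tokens).
#' @param alpha Significance level for all segment and full-schedule Spearman
#'   tests (default 0.01).
#' @param min_segment Smallest segment length in the sliding split search
#'   (default 3: the first split compares entries 0..2 against 3..20).
#' @param sided `"two"` (default) or `"one"`: whether significance combines a
#'   two-sided p with the required sign, or uses the one-sided p directly.
#' @param tokens Endowment size (default 20).
#' @return A list of class `"classifier_config"`.
#' @export
classifier_config <- function(fr_fraction = 0.20, alpha = 0.01, min_segment = 3L,
                              sided = c("two", "one"), tokens = 20L) {
  sided <- match.arg(sided)
  if (fr_fraction <= 0 || fr_fraction >= 1) stop("`fr_fraction` must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  min_segment <- as.integer(min_segment)
  if (min_segment < 2L) stop("`min_segment` must be at least 2")
  structure(
    list(fr_fraction = fr_fraction, alpha = alpha, min_segment = min_segment,
         sided = sided, tokens = as.integer(tokens),
         fr_ceiling = round_half_up(fr_fraction * tokens)),
    class = "classifier_config"
  )
}

seg_test <- function(x, y, sided, direction) {
  alt <- if (sided == "two") {
    "two.sided"
  } else if (direction > 0) "greater" else "less"
  spearman_core(x, y, alt)
}

seg_significant <- function(res, alpha, direction) {
  if (!res$defined || is.na(res$p)) return(FALSE)
  res$p < alpha && sign(res$rho) == direction
}

#' Classify one contingent-contribution schedule
#'
#' Applies the four-way rule in strict order. (1) Free rider (FR): the
#' maximum schedule entry is at or below the token ceiling
#' `round_half_up(fr_fraction * tokens)`. (2) Hump-shaped (HS): for some
#' sliding split k (first segment = entries for others' average `0..k-1`,
#' `k` from `min_segment` to `21 - min_segment`), the Spearman correlation of
#' the first segment with the others' average is significantly positive *and*
#' that of the complementary segment significantly negative, both at `alpha`.
#' (3) Conditional cooperator (CC): the full 21-entry Spearman is
#' significantly positive at `alpha`. (4) Other (OT) otherwise; constant
#' schedules (undefined correlation) such as unconditional cooperation land
#' here. The diagnostic trace of every split is always populated.
#'
#' @param schedule Integer vector of 21 entries in `[0, 20]`.
#' @param config A [classifier_config()].
#' @return A list of class `"strategy_call"` with `label` (one of
#'   `"CC"`, `"HS"`, `"FR"`, `"OT"`), `fr_ceiling_tokens`, `full_rho`,
#'   `full_p`, and `splits`, a data frame of 16 rows (one per split k) with
#'   the per-segment coefficients, p-values and `hump_flag`.
#' @examples
#' classify_schedule(rep(0, 21))$label  # "FR"
#' classify_schedule(0:20)$label        # "CC"
#' @export
classify_schedule <- function(schedule, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  schedule <- validate_schedule(schedule, tokens = config$tokens)
  m <- config$tokens + 1L           # 21 entries
  x <- seq_len(m) - 1L              # others' average 0..20
  ks <- seq.int(config$min_segment, m - config$min_segment)

  nk <- length(ks)
  rho_first <- p_first <- rho_second <- p_second <- numeric(nk)
  hump_flag <- logical(nk)
  for (j in seq_len(nk)) {
    k <- ks[j]
    first <- seg_test(x[1:k], schedule[1:k], config$sided, +1)
    second <- seg_test(x[(k + 1):m], schedule[(k + 1):m], config$sided, -1)
    rho_first[j] <- first$rho; p_first[j] <- first$p
    rho_second[j] <- second$rho; p_second[j] <- second$p
    hump_flag[j] <- seg_significant(first, config$alpha, +1) &&
      seg_significant(second, config$alpha, -1)
  }
  splits <- data.frame(
    split_index = ks,
    rho_first = rho_first, p_first = p_first,
    rho_second = rho_second, p_second = p_second,
    hump_flag = hump_flag
  )

  full <- seg_test(x, schedule, config$sided, +1)

  label <- if (max(schedule) <= config$fr_ceiling) {
    "FR"
  } else if (any(splits$hump_flag)) {
    "HS"
  } else if (seg_significant(full, config$alpha, +1)) {
    "CC"
  } else {
    "OT"
  }

  structure(
    list(
      label = label,
      fr_ceiling_tokens = config$fr_ceiling,
      full_rho = full$rho, full_p = full$p, full_defined = full$defined,
      splits = splits
    ),
    class = "strategy_call"
  )
}

#' @export
print.strategy_call <- function(x, ...) {
  cat(sprintf("Strategy: %s (FR ceiling %d tokens; full rho %s, p %s)\n",
              x$label, x$fr_ceiling_tokens,
              formatC(x$full_rho, digits = 3, format = "f"),
              formatC(x$full_p, digits = 4, format = "g")))
  invisible(x)
}

#' Classify a cohort of schedules
#'
#' @param schedules A list of 21-entry schedules, or a matrix/data frame with
#'   one schedule per row (21 columns).
#' @param config A [classifier_config()].
#' @param ids Optional subject identifiers.
#' @return A list with `calls` (data frame: id, label, fr_ceiling, full_rho,
#'   full_p, and the best split's diagnostics), `labels` (factor), and
#'   `distribution` (percentage per label over CC/HS/FR/OT, summing to 100,
#'   reported to 2 decimals).
#' @export
classify_cohort <- function(schedules, config = classifier_config(), ids = NULL) {
  schedules <- as_schedule_list(schedules)
  if (length(schedules) == 0L) stop("empty cohort")
  if (is.null(ids)) ids <- seq_along(schedules)
  # identical schedules receive identical calls: classify unique ones once
  keys <- vapply(schedules, paste, character(1), collapse = ",")
  uniq <- !duplicated(keys)
  uniq_calls <- lapply(schedules[uniq], classify_schedule, config = config)
  calls <- uniq_calls[match(keys, keys[uniq])]
  best_split <- vapply(calls, function(cl) {
    s <- cl$splits
    ok <- !is.na(s$p_first) & !is.na(s$p_second)
    if (!any(ok)) return(NA_integer_)
    cand <- s[ok, ]
    as.integer(cand$split_index[which.min(pmax(cand$p_first, cand$p_second))])
  }, integer(1))
  df <- data.frame(
    id = ids,
    label = vapply(calls, `[[`, character(1), "label"),
    fr_ceiling = config$fr_ceiling,
    full_rho = vapply(calls, `[[`, numeric(1), "full_rho"),
    full_p = vapply(calls, `[[`, numeric(1), "full_p"),
    best_split = best_split,
    stringsAsFactors = FALSE
  )
  labels <- factor(df$label, levels = c("CC", "HS", "FR", "OT"))
  dist <- round(100 * table(labels) / length(labels), 2)
  list(calls = df, labels = labels,
       distribution = setNames(as.numeric(dist), names(dist)),
       details = calls)
}

as_schedule_list <- function(schedules) {
  if (is.data.frame(schedules)) schedules <- as.matrix(schedules)
  if (is.matrix(schedules)) {
    schedules <- lapply(seq_len(nrow(schedules)), function(i) schedules[i, ])
  }
  if (!is.list(schedules)) stop("`schedules` must be a list or matrix of schedules")
  schedules
}

#' Average schedule profile per strategy label
#'
#' Entrywise mean of the schedules within each label, the per-strategy
#' profile plotted against the diagonal of perfect conditional cooperation.
#'
#' @param labels Character or factor of per-subject labels (CC/HS/FR/OT).
#' @param schedules Schedules as accepted by [classify_cohort()].
#' @return A matrix with one row per label present and 21 columns
#'   (others' average 0..20); labels with no subjects are absent (not zero
#'   rows), with the missing labels recorded in attribute `"absent"`.
#' @export
average_profile <- function(labels, schedules) {
  schedules <- as_schedule_list(schedules)
  if (length(labels) != length(schedules)) {
    stop("`labels` and `schedules` lengths differ")
  }
  labels <- as.character(labels)
  all_labels <- c("CC", "HS", "FR", "OT")
  present <- all_labels[all_labels %in% labels]
  mat <- t(vapply(present, function(lb) {
    colMeans(do.call(rbind, schedules[labels == lb]))
  }, numeric(length(schedules[[1]]))))
  colnames(mat) <- paste0("c", seq_len(ncol(mat)) - 1L)
  attr(mat, "absent") <- setdiff(all_labels, present)
  mat
}
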