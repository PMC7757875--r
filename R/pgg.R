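#' Public-goods-game endowment and payoff parameters
#'
#' Bundles the constants of the four-player linear public goods game: each
#' player holds `tokens` tokens worth `token_value` Chilean pesos each, and
#' every token contributed to the common pot returns `multiplier_return` of
#' its value to *each* group member (contributions are doubled and split four
#' ways, so the marginal per-capita return is 0.5).
#'
#' The social-dilemma condition `1/group_size < multiplier_return < 1` is
#' enforced: contributing must benefit the group (total return
#' `group_size * multiplier_return > 1`) while free riding remains the
#' individually dominant action (`multiplier_return < 1`).
#'
#' @param tokens Integer endowment per player (default 20).
#' @param token_value Value of one token in CLP (default 250).
#' @param multiplier_return Fraction of the group pot returned per member
#'   (default 0.5).
#' @param group_size Number of players per group (default 4).
#' @return An object of class `"pgg_endowment"`.
#' @examples
#' pgg_endowment()
#' @export
pgg_endowment <- function(tokens = 20L, token_value = 250, multiplier_return = 0.5,
                          group_size = 4L) {
  tokens <- as.integer(tokens)
  group_size <- as.integer(group_size)
  if (tokens <= 0L) stop("`tokens` must be a positive integer")
  if (token_value <= 0) stop("`token_value` must be positive")
  if (group_size < 2L) stop("`group_size` must be at least 2")
  if (multiplier_return <= 1 / group_size || multiplier_return >= 1) {
    stop(sprintf(
      "`multiplier_return` = %g violates the social-dilemma condition 1/%d < m < 1",
      multiplier_return, group_size
    ))
  }
  structure(
    list(
      tokens = tokens, token_value = token_value,
      multiplier_return = multiplier_return, group_size = group_size
    ),
    class = "pgg_endowment"
  )
}

#' @export
print.pgg_endowment <- function(x, ...) {
  cat(sprintf(
    "Public goods game: %d tokens x %g CLP, %d players, per-capita return %g\n",
    x$tokens, x$token_value, x$group_size, x$multiplier_return
  ))
  invisible(x)
}

#' Payoff of one player in the public goods game
#'
#' Computes `(tokens - own + m * sum(group)) * token_value`: the player keeps
#' the uncontributed tokens and receives the per-capita return `m` on the full
#' group pot, own contribution included. With the default endowment the payoff
#' is always an exact multiple of 125 CLP; the arithmetic is carried out in
#' integer half-token units so the accounting identity
#' `sum(payoffs) = token_value * (group_size * tokens + sum(group))` holds
#' without floating-point drift (every contributed token is doubled and
#' redistributed; every kept token is counted once).
#'
#' @param own One player's contribution, in tokens.
#' @param group Vector of all `group_size` contributions (own included).
#' @param endowment A [pgg_endowment()].
#' @return Payoff in CLP.
#' @examples
#' pgg_payoff(0, c(0, 0, 0, 0))   # keeps the endowment: 5000
#' pgg_payoff(20, c(20, 20, 20, 20))  # full cooperation: 10000
#' @export
pgg_payoff <- function(own, group, endowment = pgg_endowment()) {
  stopifnot(inherits(endowment, "pgg_endowment"))
  if (length(group) != endowment$group_size) {
    stop(sprintf("`group` must have %d contributions", endowment$group_size))
  }
  bad <- which(group < 0 | group > endowment$tokens)
  if (length(bad)) {
    stop(sprintf(
      "contribution of member %d (%g tokens) outside [0, %d]",
      bad[1], group[bad[1]], endowment$tokens
    ))
  }
  if (!any(abs(group - own) < 1e-9)) {
    stop("`own` must be one of the `group` contributions")
  }
  if (endowment$multiplier_return == 0.5) {
    # exact: half-token units, multiples of token_value/2
    halves <- 2L * (endowment$tokens - as.integer(own)) + as.integer(sum(group))
    return(halves * endowment$token_value / 2)
  }
  (endowment$tokens - own + endowment$multiplier_return * sum(group)) *
    endowment$token_value
}

#' Marginal incentives of the public goods game
#'
#' Returns the marginal gain (in tokens) of contributing one token versus
#' keeping it. Under the social-dilemma condition the contribution gain
#' (`multiplier_return`) is strictly below the keeping gain (1), so free
#' riding is the dominant action even though full contribution is socially
#' optimal.
#'
#' @param endowment A [pgg_endowment()].
#' @return Named numeric vector `c(gain_contribute = m, gain_keep = 1)`.
#' @examples
#' marginal_gain_check()  # c(gain_contribute = 0.5, gain_keep = 1)
#' @export
marginal_gain_check <- function(endowment = pgg_endowment()) {
  stopifnot(inherits(endowment, "pgg_endowment"))
  gains <- c(gain_contribute = endowment$multiplier_return, gain_keep = 1)
  stopifnot(gains[["gain_contribute"]] < gains[["gain_keep"]])
  gains
}

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going up (8.5 -> 9), the everyday
#' convention, unlike [base::round()]'s round-half-even. Used when averaging
#' the three uninformed contributions ("rounded to the integer") and when
#' converting the free-rider fraction to a token ceiling.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @return Integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

#' One player's two strategy-method decisions
#'
#' The strategy method elicits an *uninformed* contribution (chosen with no
#' information about the other players) and a *contingent* schedule: the
#' planned contribution for each possible rounded average contribution
#' 0..20 of the other three group members (21 entries).
#'
#' @param uninformed Integer contribution in `[0, tokens]`.
#' @param schedule Integer vector of 21 schedule entries, each in
#'   `[0, tokens]`; `schedule[x + 1]` is the planned contribution when the
#'   others' rounded average is `x`.
#' @param tokens Endowment size the entries are validated against.
#' @return A list of class `"pgg_decision"`.
#' @export
pgg_decision <- function(uninformed, schedule, tokens = 20L) {
  schedule <- validate_schedule(schedule, tokens = tokens)
  uninformed <- as.integer(uninformed)
  if (length(uninformed) != 1L || is.na(uninformed) ||
      uninformed < 0L || uninformed > tokens) {
    stop(sprintf("`uninformed` must be a single integer in [0, %d]", tokens))
  }
  structure(list(uninformed = uninformed, schedule = schedule),
            class = "pgg_decision")
}

validate_schedule <- function(schedule, tokens = 20L) {
  schedule <- suppressWarnings(as.numeric(schedule))
  if (length(schedule) != tokens + 1L) {
    stop(sprintf("a contingent schedule must have %d entries", tokens + 1L))
  }
  if (anyNA(schedule) || any(schedule != floor(schedule))) {
    stop("schedule entries must be integers")
  }
  if (any(schedule < 0 | schedule > tokens)) {
    stop(sprintf("schedule entries must lie in [0, %d]", tokens))
  }
  as.integer(schedule)
}

#' Resolve one four-player group
#'
#' Implements the incentive-compatible group resolution: the uninformed
#' contributions of the three non-responder players are averaged and rounded
#' to the integer (half up); the responder's realized contribution is their
#' contingent schedule evaluated at that average; the other three contribute
#' their uninformed amounts; payoffs follow from [pgg_payoff()].
#'
#' @param decisions List of `group_size` [pgg_decision()] objects.
#' @param responder_index Which member's contingent decision binds (1-based).
#' @param endowment A [pgg_endowment()].
#' @return A list with `contributions`, `responder_index`, `others_average`
#'   and `payoffs_clp`.
#' @export
resolve_group <- function(decisions, responder_index, endowment = pgg_endowment()) {
  stopifnot(inherits(endowment, "pgg_endowment"))
  if (length(decisions) != endowment$group_size ||
      !all(vapply(decisions, inherits, logical(1), "pgg_decision"))) {
    stop(sprintf("`decisions` must be %d pgg_decision objects", endowment$group_size))
  }
  responder_index <- as.integer(responder_index)
  if (responder_index < 1L || responder_index > endowment$group_size) {
    stop("`responder_index` out of range")
  }
  uninformed <- vapply(decisions, `[[`, integer(1), "uninformed")
  others_average <- round_half_up(mean(uninformed[-responder_index]))
  contributions <- uninformed
  contributions[responder_index] <-
    decisions[[responder_index]]$schedule[others_average + 1L]
  payoffs <- vapply(
    seq_along(contributions),
    function(i) pgg_payoff(contributions[i], contributions, endowment),
    numeric(1)
  )
  list(
    contributions = contributions,
    responder_index = responder_index,
    others_average = others_average,
    payoffs_clp = payoffs
  )
}

#' Resolve a session of groups with a random responder per group
#'
#' Seeded wrapper around [resolve_group()] that picks the responder uniformly
#' at random in each group, as the experimental software does.
#'
#' @param decisions List of [pgg_decision()] objects, length a multiple of the
#'   group size; consecutive players form groups.
#' @param endowment A [pgg_endowment()].
#' @param seed Integer seed for responder selection.
#' @return List of [resolve_group()] results, one per group.
#' @export
resolve_session <- function(decisions, endowment = pgg_endowment(), seed = 1L) {
  k <- endowment$group_size
  if (length(decisions) %% k != 0L) {
    stop(sprintf("number of decisions must be a multiple of %d", k))
  }
  n_groups <- length(decisions) %/% k
  responders <- local({
    set.seed(seed)
    sample.int(k, n_groups, replace = TRUE)
  })
  lapply(seq_len(n_groups), function(g) {
    idx <- ((g - 1L) * k + 1L):(g * k)
    resolve_group(decisions[idx], responders[g], endowment)
  })
}
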