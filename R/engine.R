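#' Create a fresh group state
#'
#' Tracks the cumulative balances of one group: each player's individual
#' account and the shared group account. Balances only ever decrease through a
#' wipe event, which resets the affected account(s) to zero.
#'
#' @param spec A [treatment_spec()].
#' @return An object of class `"group_state"`.
#' @export
new_group_state <- function(spec) {
  structure(
    list(
      round_index = 1L,
      individual_balances = rep(0, spec$group_size),
      group_balance = 0
    ),
    class = "group_state"
  )
}

validate_contributions <- function(contributions, spec) {
  if (length(contributions) != spec$group_size) {
    stop(sprintf("expected %d contributions, got %d",
                 spec$group_size, length(contributions)), call. = FALSE)
  }
  if (!is.numeric(contributions) || anyNA(contributions) ||
      any(contributions != round(contributions)) ||
      any(contributions < 0) || any(contributions > spec$endowment)) {
    stop(sprintf("contributions must be integers in [0, %d]", spec$endowment),
         call. = FALSE)
  }
  as.integer(round(contributions))
}

#' Resolve one round of the game
#'
#' Credits the accounts first — each player keeps `endowment - c_i` in the
#' individual account, the pot `m * S` is added to the group account — and then
#' draws the check. A check occurs with probability `check_prob`; when it does,
#' a threshold is drawn by the treatment's rule and compared against the group
#' total `S`. On failure the wipe rule is applied: under `"full"` both accounts
#' are zeroed; under `"impact"` one of individual / group / both is drawn with
#' equal probability (an "individual" wipe zeroes every player's individual
#' account). Because accounts are credited before the check, a failed check
#' destroys the current round's earnings along with all earlier ones.
#'
#' Randomness (check occurrence, threshold draw, impact draw) comes from R's
#' global random stream; call `set.seed()` for reproducible play.
#'
#' @param contributions Integer vector of length `group_size`, each in
#'   `[0, endowment]`.
#' @param state A `"group_state"`.
#' @param spec A [treatment_spec()].
#' @return A list with `result` (the round outcome) and `state` (the updated
#'   group state). The result holds `contributions`, `group_total`,
#'   `check_occurred`, `threshold` (NA when no check), `passed` (NA when no
#'   check) and `wipe_outcome` (`"none"`, `"individual"`, `"group"`, `"both"`).
#' @export
resolve_round <- function(contributions, state, spec) {
  contributions <- validate_contributions(contributions, spec)
  S <- sum(contributions)

  ind <- state$individual_balances + (spec$endowment - contributions)
  grp <- state$group_balance + spec$multiplier * S

  check_occurred <- spec$check_prob > 0 && stats::runif(1) < spec$check_prob
  threshold <- NA_integer_
  passed <- NA
  wipe_outcome <- "none"

  if (check_occurred) {
    threshold <- draw_threshold(spec)
    passed <- S >= threshold
    if (!passed) {
      wipe_outcome <- if (spec$wipe_rule == "full") {
        "both"
      } else {
        sample(c("individual", "group", "both"), 1L)
      }
      if (wipe_outcome %in% c("individual", "both")) ind <- rep(0, spec$group_size)
      if (wipe_outcome %in% c("group", "both")) grp <- 0
    }
  }

  result <- list(
    contributions = contributions,
    group_total = S,
    check_occurred = check_occurred,
    threshold = threshold,
    passed = passed,
    wipe_outcome = wipe_outcome
  )
  state$individual_balances <- ind
  state$group_balance <- grp
  state$round_index <- state$round_index + 1L
  list(result = result, state = state)
}

#' Final earnings of each player
#'
#' At the end of play the group account is divided evenly among the players,
#' so player `i` earns their individual balance plus `group_balance / n`.
#'
#' @param state A `"group_state"` at the end of play.
#' @param spec A [treatment_spec()].
#' @return Numeric vector of per-player earnings.
#' @export
final_payout <- function(state, spec) {
  state$individual_balances + state$group_balance / spec$group_size
}

#' Play a full session with strategy callbacks
#'
#' Drives [resolve_round()] for `n_rounds` rounds. Each player is a callback
#' `function(round, own_prev, others_mean_prev, check_info)` returning an
#' integer contribution in `[0, endowment]`; in round 1 the lagged arguments
#' are `NA`. `check_info` is a list with `check_occurred`, `passed` and
#' `wipe_outcome` from the previous round (all `NA`/`"none"` in round 1),
#' mirroring the feedback screen participants saw. The horizon is not exposed
#' to the callbacks.
#'
#' @param strategies List of `group_size` callback functions.
#' @param spec A [treatment_spec()].
#' @param session_id,group_id Labels stamped on every record.
#' @return A tibble in long format, one row per player-round, with columns
#'   `session_id`, `treatment`, `group_id`, `participant_id`, `round`,
#'   `contribution`, `others_mean_prev` (NA in round 1), `check_occurred`,
#'   `threshold`, `passed`, `wipe_outcome`, `individual_balance`,
#'   `group_balance` (balances after the round, post-wipe).
#' @export
play_session <- function(strategies, spec, session_id = "S1", group_id = "G1") {
  n <- spec$group_size
  if (length(strategies) != n) {
    stop(sprintf("need %d strategy callbacks, got %d", n, length(strategies)),
         call. = FALSE)
  }
  state <- new_group_state(spec)
  prev_contrib <- rep(NA_real_, n)
  prev_check <- list(check_occurred = NA, passed = NA, wipe_outcome = "none")
  rows <- vector("list", spec$n_rounds)

  for (r in seq_len(spec$n_rounds)) {
    others_mean <- if (r == 1L) {
      rep(NA_real_, n)
    } else {
      (sum(prev_contrib) - prev_contrib) / (n - 1)
    }
    contributions <- vapply(seq_len(n), function(i) {
      c_i <- strategies[[i]](r, prev_contrib[i], others_mean[i], prev_check)
      if (!is.numeric(c_i) || length(c_i) != 1L || is.na(c_i) ||
          c_i != round(c_i) || c_i < 0 || c_i > spec$endowment) {
        stop(sprintf("strategy %d returned an invalid contribution in round %d",
                     i, r), call. = FALSE)
      }
      as.numeric(c_i)
    }, numeric(1))

    step <- resolve_round(contributions, state, spec)
    state <- step$state
    res <- step$result

    rows[[r]] <- tibble::tibble(
      session_id = session_id,
      treatment = spec$name,
      group_id = group_id,
      participant_id = paste0(group_id, "_p", seq_len(n)),
      round = r,
      contribution = as.integer(contributions),
      others_mean_prev = others_mean,
      check_occurred = res$check_occurred,
      threshold = as.integer(res$threshold),
      passed = res$passed,
      wipe_outcome = res$wipe_outcome,
      individual_balance = state$individual_balances,
      group_balance = state$group_balance
    )

    prev_contrib <- contributions
    prev_check <- list(
      check_occurred = res$check_occurred,
      passed = res$passed,
      wipe_outcome = res$wipe_outcome
    )
  }
  dplyr::bind_rows(rows)
}

#' A constant-contribution strategy callback
#'
#' @param level Contribution played in every round.
#' @return A strategy function usable with [play_session()].
#' @export
constant_strategy <- function(level) {
  force(level)
  function(round, own_prev, others_mean_prev, check_info) level
}
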