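#' One-shot expected-payoff model with a stake at risk
#'
#' Specifies the single-interaction game evaluated by the equilibrium routines.
#' A player who contributes `c_i` when the group total is `S` holds a stake of
#' `B + e - c_i + (m/n) * S`: the balance-at-risk `B` already accumulated, the
#' kept endowment, and the player's share of the pot. With probability
#' `p * P(T > S)` a check occurs and fails, and the wipe destroys the stake.
#' Under a `"full"` wipe the whole stake is lost; under an `"impact"` wipe the
#' individual component (`B_ind + e - c_i`) and the group-share component
#' (`B_grp + (m/n) * S`) are each lost with probability 2/3 conditional on
#' failure (the wipe target individual / group / both is drawn with equal
#' probability 1/3 each). `B` is split between the components by
#' `stake_group_frac` (default 0: all of `B` sits in the individual account).
#'
#' Setting `B = 0` gives the pure one-shot round; a positive `B` carries
#' accumulated earnings into the evaluation, which is what makes threshold
#' profiles sustainable as equilibria in treatments where a single round's
#' earnings alone would not deter deviation.
#'
#' @param spec A [treatment_spec()].
#' @param balance_at_risk Per-player stake `B >= 0` destroyed by a wipe.
#' @param stake_group_frac Fraction of `B` attributed to the group-share
#'   component under an impact wipe, in `[0, 1]`.
#' @return An object of class `"payoff_model"`.
#' @export
payoff_model <- function(spec, balance_at_risk = 0, stake_group_frac = 0) {
  stopifnot(
    inherits(spec, "treatment_spec"),
    balance_at_risk >= 0,
    stake_group_frac >= 0, stake_group_frac <= 1
  )
  structure(
    list(spec = spec, balance_at_risk = balance_at_risk,
         stake_group_frac = stake_group_frac),
    class = "payoff_model"
  )
}

# Vectorised expected payoff for own contribution c at group total S.
payoff_cS <- function(c, S, model) {
  spec <- model$spec
  B <- model$balance_at_risk
  share <- (spec$multiplier / spec$group_size) * S
  q <- spec$check_prob * threshold_fail_prob(S, spec)
  if (spec$wipe_rule == "full") {
    (B + spec$endowment - c + share) * (1 - q)
  } else {
    ind <- B * (1 - model$stake_group_frac) + spec$endowment - c
    grp <- B * model$stake_group_frac + share
    (ind + grp) * (1 - (2 / 3) * q)
  }
}

#' Expected payoff of a player at a strategy profile
#'
#' @param profile Integer contribution vector of length `group_size`, each in
#'   `[0, endowment]`.
#' @param player_index Which player's payoff to evaluate.
#' @param model A [payoff_model()].
#' @return Expected units kept by the player.
#' @examples
#' m <- payoff_model(treatment_spec("40P", 0.4))
#' expected_payoff(c(15, 15, 15, 15), 1, m)  # 29: S = 60 passes every check
#' @export
expected_payoff <- function(profile, player_index, model) {
  spec <- model$spec
  profile <- validate_contributions(profile, spec)
  if (player_index < 1 || player_index > spec$group_size) {
    stop("player_index out of range", call. = FALSE)
  }
  payoff_cS(profile[player_index], sum(profile), model)
}

#' Is a profile a pure-strategy Nash equilibrium?
#'
#' Checks every unilateral integer deviation in `[0, endowment]` for every
#' player; the profile is an equilibrium iff no deviation strictly increases
#' that player's expected payoff (strictness tolerance `eps`).
#'
#' @inheritParams expected_payoff
#' @param eps Strict-improvement tolerance for floating-point comparison.
#' @return `TRUE` or `FALSE`.
#' @export
is_nash <- function(profile, model, eps = 1e-9) {
  spec <- model$spec
  profile <- validate_contributions(profile, spec)
  S <- sum(profile)
  devs <- 0:spec$endowment
  for (i in seq_len(spec$group_size)) {
    here <- payoff_cS(profile[i], S, model)
    alt <- payoff_cS(devs, S - profile[i] + devs, model)
    if (any(alt > here + eps)) return(FALSE)
  }
  TRUE
}

#' Enumerate all pure-strategy Nash equilibria by brute force
#'
#' Evaluates every profile in the `(e + 1)^n` integer strategy space (194,481
#' profiles at the default `e = 20`, `n = 4`) against every unilateral integer
#' deviation, using a precomputed best-response value table: since the payoff
#' depends only on (own contribution, group total), the best attainable payoff
#' against a given opponents' total is shared across profiles.
#'
#' @param model A [payoff_model()].
#' @param eps Strict-improvement tolerance.
#' @return An object of class `"equilibrium_set"`: a list with `profiles` (one
#'   equilibrium per row), `group_totals` (sorted unique totals attained),
#'   `n_equilibria`, and the `model`.
#' @examples
#' eq <- enumerate_equilibria(payoff_model(treatment_spec("Control", 0)))
#' eq$group_totals  # 0: the dominant zero-contribution equilibrium
#' @export
enumerate_equilibria <- function(model, eps = 1e-9) {
  spec <- model$spec
  e <- spec$endowment
  n <- spec$group_size
  strat <- 0:e

  profiles <- as.matrix(do.call(expand.grid, rep(list(strat), n)))
  dimnames(profiles) <- NULL
  S <- rowSums(profiles)

  # best attainable payoff against each possible opponents' total
  opp_totals <- 0:((n - 1) * e)
  br_value <- vapply(opp_totals, function(o) {
    max(payoff_cS(strat, o + strat, model))
  }, numeric(1))

  keep <- rep(TRUE, nrow(profiles))
  for (i in seq_len(n)) {
    own <- profiles[, i]
    keep <- keep & (payoff_cS(own, S, model) >= br_value[S - own + 1L] - eps)
  }

  eq_profiles <- profiles[keep, , drop = FALSE]
  structure(
    list(
      profiles = eq_profiles,
      group_totals = sort(unique(rowSums(eq_profiles))),
      n_equilibria = nrow(eq_profiles),
      model = model
    ),
    class = "equilibrium_set"
  )
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_set> %s (B = %g): %d equilibria, group totals {%s}\n",
    x$model$spec$name, x$model$balance_at_risk, x$n_equilibria,
    paste(x$group_totals, collapse = ", ")
  ))
  invisible(x)
}

#' Manhattan distance of a contribution profile from a symmetric level
#'
#' The four-dimensional Manhattan metric used to measure how far a group's
#' contribution combination sits from the symmetric profile in which every
#' player contributes `symmetric_level`.
#'
#' @param contributions Numeric contribution vector.
#' @param symmetric_level Per-player contribution of the symmetric reference
#'   profile, in `[0, endowment]`.
#' @return Nonnegative distance in units: `sum(|c_i - symmetric_level|)`.
#' @examples
#' distance_to_symmetric(c(20, 20, 20, 0), 15)  # 30
#' @export
distance_to_symmetric <- function(contributions, symmetric_level) {
  stopifnot(is.numeric(contributions), length(symmetric_level) == 1L)
  sum(abs(contributions - symmetric_level))
}

#' Smallest stake at which a treatment's claimed equilibrium structure holds
#'
#' The equilibrium structure of the treatments is the zero profile plus all
#' profiles whose total equals the threshold target (60, or 70 where the
#' threshold is uniform on 50--70). Whether that structure holds in the
#' one-shot game depends on the balance-at-risk `B`: losses grow with the
#' accumulated stake, so threshold profiles that are not equilibria at `B = 0`
#' become equilibria once enough earnings are at stake. This scans an integer
#' grid of `B` values and returns the smallest at which the equilibrium set is
#' exactly `{zero profile} + {profiles with total = target}`, or `NA` if none
#' on the grid qualifies.
#'
#' @param spec A [treatment_spec()].
#' @param target The positive group total the structure claims.
#' @param b_grid Stake values to scan, in increasing order.
#' @param ... Passed to [payoff_model()].
#' @return A list with `min_B` and the per-grid-point logical `holds`.
#' @export
minimal_stake_for_structure <- function(spec, target, b_grid = 0:200, ...) {
  holds <- vapply(b_grid, function(B) {
    eq <- enumerate_equilibria(payoff_model(spec, balance_at_risk = B, ...))
    identical(eq$group_totals, sort(unique(c(0, target)))) &&
      all(rowSums(eq$profiles) %in% c(0, target))
  }, logical(1))
  min_B <- if (any(holds)) b_grid[which(holds)[1]] else NA
  list(min_B = min_B, b_grid = b_grid, holds = holds)
}
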