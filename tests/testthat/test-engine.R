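test_that("round resolution credits accounts and applies threshold checks", {
  trs <- default_treatments()

  # deterministic keep-everything case: no checks in Control
  st <- new_group_state(trs$Control)
  out <- resolve_round(c(0, 0, 0, 0), st, trs$Control)
  expect_equal(out$state$individual_balances, rep(20, 4))
  expect_equal(out$state$group_balance, 0)
  expect_false(out$result$check_occurred)

  # force a check with p = 1 and the 40P threshold: S = 60 passes, pot = 1.6 * 60
  p1 <- treatment_spec("40P", check_prob = 1)
  st <- new_group_state(p1)
  out <- resolve_round(c(15, 15, 15, 15), st, p1)
  expect_true(out$result$check_occurred)
  expect_true(out$result$passed)
  expect_equal(out$result$wipe_outcome, "none")
  expect_equal(out$state$group_balance, 96)
  expect_equal(out$state$individual_balances, rep(5, 4))

  # S = 40 < 60 fails and the full wipe zeroes both accounts exactly
  st <- new_group_state(p1)
  st$individual_balances <- rep(50, 4)
  st$group_balance <- 200
  out <- resolve_round(c(10, 10, 10, 10), st, p1)
  expect_false(out$result$passed)
  expect_equal(out$result$wipe_outcome, "both")
  expect_identical(out$state$individual_balances, rep(0, 4))
  expect_identical(out$state$group_balance, 0)
})

test_that("impact wipes hit the drawn account class and only that class", {
  spec <- treatment_spec("Impact", check_prob = 1, wipe_rule = "impact")
  set.seed(101)
  seen <- character()
  for (i in 1:60) {
    st <- new_group_state(spec)
    st$individual_balances <- rep(30, 4)
    st$group_balance <- 120
    out <- resolve_round(c(0, 0, 0, 0), st, spec)  # S = 0 always fails
    w <- out$result$wipe_outcome
    seen <- c(seen, w)
    # accounts credited first, then wiped: surviving accounts keep the round's earnings
    if (w %in% c("individual", "both")) {
      expect_identical(out$state$individual_balances, rep(0, 4))
    } else {
      expect_equal(out$state$individual_balances, rep(50, 4))
    }
    if (w %in% c("group", "both")) {
      expect_identical(out$state$group_balance, 0)
    } else {
      expect_equal(out$state$group_balance, 120)
    }
  }
  expect_setequal(unique(seen), c("individual", "group", "both"))
})

test_that("invalid contributions are rejected", {
  spec <- default_treatments()$Control
  st <- new_group_state(spec)
  expect_error(resolve_round(c(21, 0, 0, 0), st, spec), "integers in \\[0, 20\\]")
  expect_error(resolve_round(c(5.5, 0, 0, 0), st, spec), "integers")
  expect_error(resolve_round(c(0, 0, 0), st, spec), "expected 4 contributions")
})

test_that("final payout splits the group account evenly", {
  spec <- default_treatments()$Control
  st <- new_group_state(spec)
  st$individual_balances <- c(10, 20, 30, 40)
  st$group_balance <- 100
  expect_equal(final_payout(st, spec), c(35, 45, 55, 65))

  st$individual_balances <- rep(0, 4)
  st$group_balance <- 0
  expect_equal(final_payout(st, spec), rep(0, 4))

  # closed form: 20 rounds of (15,15,15,15) in Control earns 20*5 + 20*96/4 each
  st <- new_group_state(spec)
  for (r in 1:20) st <- resolve_round(rep(15, 4), st, spec)$state
  expect_equal(final_payout(st, spec), rep(580, 4))
})

test_that("sessions run callbacks, attach lagged means, and replay under a seed", {
  spec3 <- treatment_spec("Control", check_prob = 0, n_rounds = 3)
  rec <- constant_session(rep(15, 4), spec3)
  expect_equal(nrow(rec), 12)
  expect_true(all(rec$contribution == 15))
  expect_true(all(is.na(rec$others_mean_prev[rec$round == 1])))
  expect_true(all(rec$others_mean_prev[rec$round > 1] == 15))

  p1 <- treatment_spec("100P", check_prob = 1, n_rounds = 5)
  rec <- constant_session(c(20, 20, 20, 20), p1)
  expect_true(all(rec$check_occurred))
  expect_true(all(rec$passed))

  noisy <- function(round, own_prev, om, chk) sample(0:20, 1)
  spec <- default_treatments()$`40P`
  set.seed(99)
  a <- play_session(rep(list(noisy), 4), spec)
  set.seed(99)
  b <- play_session(rep(list(noisy), 4), spec)
  expect_identical(a, b)

  bad <- function(round, own_prev, om, chk) 42
  expect_error(play_session(rep(list(bad), 4), spec), "invalid contribution")
})

test_that("earnings are conserved on traces without wipes", {
  # total payout must equal sum over rounds of n*e + (m - 1)*S_t
  spec <- treatment_spec("40P", check_prob = 0.4, n_rounds = 20)
  set.seed(5)
  passing <- function(round, own_prev, om, chk) sample(15:20, 1)  # S >= 60 always
  rec <- play_session(rep(list(passing), 4), spec)
  expect_true(all(rec$wipe_outcome == "none"))
  totals <- rec |>
    dplyr::group_by(round) |>
    dplyr::summarise(S = sum(contribution))
  last <- rec[rec$round == max(rec$round), ]
  payout <- sum(last$individual_balance) + last$group_balance[1]
  expect_equal(payout, sum(4 * 20 + 0.6 * totals$S))
})

test_that("with p = 0 the engine is a standard public goods game with MPCR 0.4", {
  spec <- default_treatments()$Control
  set.seed(31)
  cvec <- replicate(10, sample(0:20, 4, replace = TRUE))
  st <- new_group_state(spec)
  for (r in 1:10) {
    out <- resolve_round(cvec[, r], st, spec)
    expect_false(out$result$check_occurred)
    st <- out$state
  }
  # payoff of player i: sum over rounds of e - c_i + 0.4 * S_t
  expected <- vapply(1:4, function(i) {
    sum(20 - cvec[i, ] + 0.4 * colSums(cvec))
  }, numeric(1))
  expect_equal(final_payout(st, spec), expected)
})
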