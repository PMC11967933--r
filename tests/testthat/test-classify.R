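test_that("LCP fitting matches hand OLS and handles degenerate regressors", {
  lcp <- fit_lcp(rep(15, 5), c(3, 7, 11, 2, 9))
  expect_equal(lcp$intercept, 15)
  expect_equal(lcp$slope, 0)

  lcp <- fit_lcp(c(4, 9, 13), c(4, 9, 13))
  expect_equal(lcp$intercept, 0)
  expect_equal(lcp$slope, 1)

  # hand-computed: Sxy = 40, Sxx = 50
  lcp <- fit_lcp(c(6, 10, 14), c(5, 10, 15))
  expect_equal(lcp$slope, 0.8, tolerance = 1e-12)
  expect_equal(lcp$intercept, 2, tolerance = 1e-12)
  expect_equal(lcp$y_min, 2)
  expect_equal(lcp$y_max, 18)

  # zero-variance regressor: slope 0, intercept = mean response
  lcp <- fit_lcp(c(4, 6, 8), c(10, 10, 10))
  expect_equal(lcp$slope, 0)
  expect_equal(lcp$intercept, 6)

  expect_error(fit_lcp(1:3, 1:4), "equal length")
  expect_error(fit_lcp(1, 1), "at least 2")
})

test_that("LCP fits agree with a generic least-squares solver", {
  set.seed(21)
  for (k in 1:20) {
    x <- runif(19, 0, 20)
    y <- pmin(pmax(2 + 0.6 * x + rnorm(19, 0, 2), 0), 20)
    lcp <- fit_lcp(y, x)
    ref <- unname(coef(lm(y ~ x)))
    expect_equal(lcp$intercept, ref[1], tolerance = 1e-10)
    expect_equal(lcp$slope, ref[2], tolerance = 1e-10)
  }
})

test_that("the archetype lines classify to their player types", {
  line <- function(a, b) list(intercept = a, slope = b,
                              y_min = min(a, a + 20 * b),
                              y_max = max(a, a + 20 * b))
  expect_equal(classify_lcp(line(15, 0)), "UC")
  expect_equal(classify_lcp(line(2, 0.2)), "FR")
  expect_equal(classify_lcp(line(2, 0.8)), "CC")
  expect_equal(classify_lcp(line(18, -0.5)), "Uncategorized")
  # constant line exactly on the boundary is neither above nor below
  expect_equal(classify_lcp(line(10, 0)), "Uncategorized")
})

test_that("dataset classification recovers trivial cohorts and planted types", {
  spec <- treatment_spec("Control", check_prob = 0, n_rounds = 6)
  all15 <- dplyr::bind_rows(lapply(1:5, function(g) {
    constant_session(rep(15, 4), spec, group_id = paste0("g", g))
  }))
  out <- classify_dataset(all15)
  expect_true(all(out$participants$type == "UC"))

  all0 <- dplyr::bind_rows(lapply(1:5, function(g) {
    constant_session(rep(0, 4), spec, group_id = paste0("g", g))
  }))
  expect_true(all(classify_dataset(all0)$participants$type == "FR"))

  # shares sum to one within every condition
  shares <- out$shares
  sums <- tapply(shares$share, shares$condition, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
})

test_that("classification is invariant to participant relabeling and row order", {
  cohort <- recovery_cohort(seed = 3, n_groups = 4,
                            treatments = default_treatments()["40P"])
  base <- classify_dataset(cohort$records)$participants

  shuffled <- cohort$records[sample(nrow(cohort$records)), ]
  resorted <- classify_dataset(shuffled)$participants
  merged <- dplyr::inner_join(base, resorted,
                              by = c("treatment", "group_id", "participant_id"))
  expect_identical(merged$type.x, merged$type.y)
  expect_equal(merged$slope.x, merged$slope.y)
})

test_that("planted types are recovered and recovery improves as noise shrinks", {
  noisy <- recovery_cohort(seed = 7, noise_sd = 1.5)
  quiet <- recovery_cohort(seed = 8, noise_sd = 0.2)
  r_noisy <- recovery_rate(noisy)
  r_quiet <- recovery_rate(quiet)
  expect_gte(r_noisy, 0.95)
  expect_equal(r_quiet, 1)
})

test_that("conformity direction finds matchers, non-movers, and the UC/CC contrast", {
  spec <- treatment_spec("Control", check_prob = 0, n_rounds = 8)
  # a perfect matcher among three constant players at distinct levels
  matcher <- function(round, own_prev, om, chk) {
    if (round == 1) 0 else as.integer(round(om))
  }
  rec <- play_session(list(matcher, constant_strategy(18), constant_strategy(6),
                           constant_strategy(12)), spec)
  moves <- conformity_direction(rec)$moves
  m_moves <- moves[moves$participant_id == "G1_p1" & moves$position != "equal", ]
  expect_true(all(m_moves$conforming))

  const_moves <- moves[moves$participant_id == "G1_p2", ]
  expect_true(all(const_moves$adjustment == "none"))

  # a UC-heavy condition conforms less than a CC-heavy one
  set.seed(14)
  cc_heavy <- generate_cohort(cohort_config(
    n_groups = 12, treatments = default_treatments()["Control"],
    type_mix = c(UC = 0.2, CC = 0.7, FR = 0.1)
  ))
  uc_heavy <- generate_cohort(cohort_config(
    n_groups = 12, treatments = default_treatments()["40P"],
    type_mix = c(UC = 0.7, CC = 0.2, FR = 0.1)
  ))
  rates <- conformity_direction(
    dplyr::bind_rows(cc_heavy$records, uc_heavy$records)
  )$rates
  expect_lt(rates$conformity_rate[rates$treatment == "40P"],
            rates$conformity_rate[rates$treatment == "Control"])
})

test_that("rank conformity reports persistence and degenerates gracefully", {
  spec <- treatment_spec("Control", check_prob = 0, n_rounds = 6)

  tied <- constant_session(rep(15, 4), spec)
  out <- conformity_rank(tied)
  expect_true(is.na(out$rank_autocorrelation))

  persistent <- constant_session(c(20, 14, 8, 2), spec)
  out <- conformity_rank(persistent)
  expect_equal(out$rank_autocorrelation, 1)

  cohort <- recovery_cohort(seed = 9, n_groups = 8,
                            treatments = default_treatments()["40P"])
  out <- conformity_rank(cohort$records)
  expect_gt(out$rank_autocorrelation, 0)
  expect_lt(out$rank_autocorrelation, 1)
})
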