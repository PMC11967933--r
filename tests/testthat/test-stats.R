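test_that("check events carry deficit and surplus fractions", {
  contr <- matrix(rep(c(15, 15, 15, 10), 3), nrow = 3, byrow = TRUE)  # S = 55
  checks <- data.frame(round = 2, threshold = 60, passed = FALSE)
  rec <- scripted_records(contr, checks)
  ev <- check_events(rec)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$deficit, 5)
  expect_equal(ev$deficit_fraction, 5 / 60)

  contr <- matrix(rep(15, 12), nrow = 3)  # S = 60
  checks <- data.frame(round = 2, threshold = 60, passed = TRUE)
  ev <- check_events(scripted_records(contr, checks))
  expect_equal(ev$deficit, 0)
  expect_equal(ev$surplus_fraction, 0)
})

test_that("post-check trajectories average by lag and truncate correctly", {
  # constant contributors: flat profile at every lag
  contr <- matrix(15, nrow = 8, ncol = 4)
  checks <- data.frame(round = c(2, 6), threshold = c(60, 60), passed = TRUE)
  out <- rounds_after_check(scripted_records(contr, checks), max_lag = 4)
  expect_true(all(out$by_lag$mean_group_total == 60))
  # window after the round-2 check stops before the round-6 check
  ev1 <- out$trajectories[out$trajectories$event_id == 1, ]
  expect_equal(max(ev1$round), 5)

  # lag-0 mean equals the mean group total in check rounds
  set.seed(44)
  cohort <- recovery_cohort(seed = 44, n_groups = 6,
                            treatments = default_treatments()["40P"])
  out <- rounds_after_check(cohort$records)
  ev <- check_events(cohort$records)
  lag0 <- out$trajectories[out$trajectories$lag == 0, ]
  expect_equal(mean(lag0$group_total), mean(ev$group_total))

  # single check in the final round: only lag 0 populated
  contr <- matrix(10, nrow = 5, ncol = 4)
  checks <- data.frame(round = 5, threshold = 60, passed = FALSE)
  out <- rounds_after_check(scripted_records(contr, checks), max_lag = 4)
  expect_equal(out$by_lag$lag, 0)

  # no checks at all
  expect_warning(
    out <- rounds_after_check(scripted_records(contr, checks = NULL)),
    "no check events"
  )
  expect_equal(nrow(out$by_lag), 0)
})

test_that("a planted raise-after-failure rule shows up at the right lag", {
  # agents play 10 each; two rounds after a failed check they jump to 18
  contr <- matrix(10, nrow = 7, ncol = 4)
  contr[5, ] <- 18  # check fails in round 3; raise at lag 2
  checks <- data.frame(round = 3, threshold = 60, passed = FALSE)
  out <- rounds_after_check(scripted_records(contr, checks), max_lag = 3)
  by_lag <- out$by_lag
  expect_gt(by_lag$mean_group_total[by_lag$lag == 2],
            by_lag$mean_group_total[by_lag$lag == 1])
})

test_that("near-threshold splits follow the 10% margin rule", {
  mk <- function(S_per_player, passed) {
    contr <- matrix(S_per_player, nrow = 3, ncol = 4)
    checks <- data.frame(round = 2, threshold = 60, passed = passed)
    scripted_records(contr, checks)
  }
  # S = 55, failed: deficit fraction 0.083 <= 0.1 -> almost-made-it
  near <- near_threshold_cases(mk(14, FALSE))
  # 14*4 = 56, deficit 4/60 = 0.067
  expect_equal(nrow(near$almost_made_it$cases), 1)
  expect_equal(nrow(near$near_miss$cases), 0)

  # S = 32, failed: excluded
  far <- near_threshold_cases(mk(8, FALSE))
  expect_equal(nrow(far$almost_made_it$cases), 0)

  # S = 60, passed: surplus 0 -> near-miss
  boundary <- near_threshold_cases(mk(15, TRUE))
  expect_equal(nrow(boundary$near_miss$cases), 1)
  expect_equal(nrow(boundary$almost_made_it$cases), 0)
})

test_that("cluster-robust standard errors match independent matrix algebra", {
  # 8 observations, 2 groups x 2 participants
  fix <- tibble::tibble(
    contribution = c(5, 7, 6, 9, 14, 12, 15, 11),
    treatment = rep(c("Control", "40P"), each = 4),
    group_id = rep(c("g1", "g1", "g2", "g2"), 2),
    participant_id = rep(c("p1", "p2"), 4)
  )

  # independent oracle: CR1 sandwich by explicit matrix algebra
  X <- cbind(1, as.numeric(fix$treatment == "Control"))
  y <- fix$contribution
  bread <- solve(t(X) %*% X)
  beta <- bread %*% t(X) %*% y
  u <- as.numeric(y - X %*% beta)
  meat_for <- function(ids) {
    G <- length(unique(ids))
    n <- nrow(X); k <- ncol(X)
    m <- matrix(0, k, k)
    for (g in unique(ids)) {
      s <- colSums(X[ids == g, , drop = FALSE] * u[ids == g])
      m <- m + s %*% t(s)
    }
    (G / (G - 1)) * ((n - 1) / (n - k)) * m
  }
  inter <- paste(fix$group_id, fix$participant_id)
  meat <- meat_for(fix$group_id) + meat_for(fix$participant_id) - meat_for(inter)
  vc_oracle <- bread %*% meat %*% bread

  fitted <- treatment_contrast(fix, cluster = c("group_id", "participant_id"))
  expect_equal(unname(fitted$vcov), unname(vc_oracle), tolerance = 1e-8)
  expect_equal(fitted$coefficients$std_error, sqrt(diag(vc_oracle)),
               tolerance = 1e-8)

  # one-way clustering agrees with the one-way oracle
  one <- treatment_contrast(fix, cluster = "group_id")
  vc_one <- bread %*% meat_for(fix$group_id) %*% bread
  expect_equal(unname(one$vcov), unname(vc_one), tolerance = 1e-8)

  expect_error(
    treatment_contrast(dplyr::mutate(fix, group_id = "g1"), cluster = "group_id"),
    "at least 2 clusters"
  )
})

test_that("planted treatment effects are recovered within sampling error", {
  set.seed(55)
  base <- generate_cohort(cohort_config(
    n_groups = 12, treatments = default_treatments()[c("Control", "40P")],
    type_mix = c(UC = 0.5, CC = 0.4, FR = 0.1)
  ))
  # null case: relabel half the Control groups as a fake treatment
  ctrl <- base$records[base$records$treatment == "Control", ]
  fake <- ctrl
  fake$treatment[fake$group_id %in% unique(fake$group_id)[1:6]] <- "Fake"
  null_fit <- treatment_contrast(fake)
  co <- null_fit$coefficients
  row <- co[co$term == "treatmentFake", ]
  expect_lt(abs(row$estimate), 3 * row$std_error)

  # planted effect: shift one arm's contributions up by 4 units
  shifted <- ctrl
  up <- shifted$group_id %in% unique(shifted$group_id)[1:6]
  shifted$treatment[up] <- "Up"
  shifted$contribution[up] <- pmin(shifted$contribution[up] + 4L, 20L)
  fit <- treatment_contrast(shifted)
  co <- fit$coefficients
  row <- co[co$term == "treatmentUp", ]
  expect_lt(abs(row$estimate - 4), 3 * row$std_error + 0.2)
})

test_that("pre-first-check subsets keep the rounds decided before any check", {
  # scripted group: first check in round 4
  contr <- matrix(c(12, 13, 11, 12), nrow = 8, ncol = 4, byrow = TRUE)
  checks <- data.frame(round = 4, threshold = 60, passed = FALSE)
  rec <- scripted_records(contr, checks)
  rec2 <- scripted_records(matrix(c(5, 6, 4, 5), nrow = 8, ncol = 4, byrow = TRUE),
                           NULL, treatment = "Control", group_id = "G2")
  out <- pre_first_check_contrast(dplyr::bind_rows(rec, rec2))
  expect_equal(out$n_obs, 4 * 4 + 8 * 4)  # rounds 1-4 of G1, all rounds of G2

  # p = 1: only round 1 was decided before a check
  p1 <- treatment_spec("100P", check_prob = 1, n_rounds = 6)
  rec3 <- constant_session(c(8, 9, 7, 8), p1, group_id = "G3")
  first <- min(rec3$round[rec3$check_occurred])
  expect_equal(first, 1)
  out <- pre_first_check_contrast(dplyr::bind_rows(rec3, rec2))
  expect_equal(out$n_obs, 4 + 8 * 4)
})
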