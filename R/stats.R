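#' Check events in a long-format dataset
#'
#' One row per check (group x round): whether the group passed, the deficit
#' `max(0, T - S)` and its fraction of the threshold, and the surplus
#' `max(0, S - T)` with its fraction.
#'
#' @param records Long-format tibble as written by [play_session()].
#' @return A tibble of check events.
#' @export
check_events <- function(records) {
  records |>
    dplyr::group_by(.data$treatment, .data$session_id, .data$group_id, .data$round) |>
    dplyr::summarise(
      group_total = sum(.data$contribution),
      check_occurred = .data$check_occurred[1],
      threshold = .data$threshold[1],
      passed = .data$passed[1],
      .groups = "drop"
    ) |>
    dplyr::filter(.data$check_occurred) |>
    dplyr::mutate(
      deficit = pmax(0, .data$threshold - .data$group_total),
      deficit_fraction = .data$deficit / .data$threshold,
      surplus = pmax(0, .data$group_total - .data$threshold),
      surplus_fraction = .data$surplus / .data$threshold
    )
}

# Group-round totals with check flags, one row per group-round.
group_rounds <- function(records) {
  records |>
    dplyr::group_by(.data$treatment, .data$session_id, .data$group_id, .data$round) |>
    dplyr::summarise(
      group_total = sum(.data$contribution),
      check_occurred = .data$check_occurred[1],
      passed = .data$passed[1],
      .groups = "drop"
    )
}

# Lag trajectories after each event in `events` (needs group_id and round).
# Windows truncate at the next check in the same group or at the end of the
# session, whichever comes first.
lag_trajectories <- function(records, events, max_lag) {
  gr <- group_rounds(records)
  checks <- gr |>
    dplyr::filter(.data$check_occurred) |>
    dplyr::select("group_id", check_round = "round")

  out <- lapply(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    later_checks <- checks$check_round[checks$group_id == ev$group_id &
                                         checks$check_round > ev$round]
    cutoff <- if (length(later_checks) > 0) min(later_checks) - 1L else Inf
    window <- gr |>
      dplyr::filter(
        .data$group_id == ev$group_id,
        .data$round >= ev$round,
        .data$round <= min(ev$round + max_lag, cutoff)
      ) |>
      dplyr::mutate(lag = .data$round - ev$round, event_id = k)
    window
  })
  dplyr::bind_rows(out)
}

#' Mean group contribution by rounds after a check
#'
#' For every check event, tracks the group's total contribution at lags
#' `0..max_lag` after the check (lag 0 is the check round itself), truncating
#' each window at the group's next check or the end of the session, and
#' averages by lag separately for passed and failed checks. Group identity is
#' kept on the per-window rows so downstream standard errors can cluster on
#' groups.
#'
#' @param records Long-format tibble.
#' @param max_lag Largest lag tracked (default 5).
#' @return A list with `trajectories` (one row per event x lag, with
#'   `group_id`, `lag`, `group_total`, `event_passed`) and `by_lag` (mean group
#'   total per lag, split by pass/fail). Warns and returns empty tibbles when
#'   the records contain no checks.
#' @export
rounds_after_check <- function(records, max_lag = 5L) {
  ev <- check_events(records)
  if (nrow(ev) == 0) {
    warning("no check events in records", call. = FALSE)
    empty <- tibble::tibble()
    return(list(trajectories = empty, by_lag = empty))
  }
  traj <- lag_trajectories(records, ev, max_lag) |>
    dplyr::left_join(
      ev |>
        dplyr::mutate(event_id = dplyr::row_number()) |>
        dplyr::select("event_id", event_passed = "passed"),
      by = "event_id"
    )
  by_lag <- traj |>
    dplyr::group_by(event_passed = .data$event_passed, lag = .data$lag) |>
    dplyr::summarise(
      mean_group_total = mean(.data$group_total),
      n_events = dplyr::n(),
      .groups = "drop"
    )
  list(trajectories = traj, by_lag = by_lag)
}

#' Near-threshold check cases and their post-check trajectories
#'
#' Splits checks into "almost-made-it" cases — failed checks whose deficit is
#' at most `margin` of the threshold — and "near-miss" cases — passed checks
#' whose surplus is at most `margin` of the threshold (the mirror
#' interpretation of narrowly passing) — and returns each subset's post-check
#' lag profile.
#'
#' @param records Long-format tibble.
#' @param margin Relative margin `delta` in `(0, 1)` (default 0.1).
#' @param max_lag Largest lag tracked (default 5).
#' @return A list with `almost_made_it` and `near_miss`, each holding `cases`
#'   (the qualifying check events) and `by_lag` (mean group totals by lag).
#' @export
near_threshold_cases <- function(records, margin = 0.1, max_lag = 5L) {
  stopifnot(margin > 0, margin < 1)
  ev <- check_events(records)
  subset_profile <- function(cases) {
    by_lag <- if (nrow(cases) == 0) {
      tibble::tibble()
    } else {
      lag_trajectories(records, cases, max_lag) |>
        dplyr::group_by(lag = .data$lag) |>
        dplyr::summarise(
          mean_group_total = mean(.data$group_total),
          n_events = dplyr::n(),
          .groups = "drop"
        )
    }
    list(cases = cases, by_lag = by_lag)
  }
  list(
    almost_made_it = subset_profile(
      dplyr::filter(ev, !.data$passed, .data$deficit_fraction <= margin)
    ),
    near_miss = subset_profile(
      dplyr::filter(ev, .data$passed, .data$surplus_fraction <= margin)
    )
  )
}

#' Treatment contrast with cluster-robust standard errors
#'
#' Fits `contribution ~ condition` by OLS and reports coefficients with
#' sandwich standard errors adjusted for clustering. With two cluster keys the
#' adjustment is the standard two-way inclusion-exclusion combination
#' (cluster on A + cluster on B - cluster on their intersection), each
#' component with the CR1/HC1 small-sample factor.
#'
#' @param records Long-format tibble.
#' @param rhs Right-hand side of the model formula (default `~ treatment`).
#' @param cluster Character vector of clustering columns (default
#'   `c("group_id", "participant_id")`).
#' @param outcome Outcome column (default `"contribution"`).
#' @return A list with `model` (the `lm` fit), `vcov` (the cluster-robust
#'   covariance), and `coefficients` (a tibble with estimates, cluster-robust
#'   SEs, t statistics and p-values).
#' @export
treatment_contrast <- function(records,
                               rhs = ~treatment,
                               cluster = c("group_id", "participant_id"),
                               outcome = "contribution") {
  stopifnot(all(cluster %in% names(records)), outcome %in% names(records))
  for (cl in cluster) {
    if (length(unique(records[[cl]])) < 2) {
      stop(sprintf("need at least 2 clusters on '%s' for a cluster-robust contrast", cl),
           call. = FALSE)
    }
  }
  formula <- stats::reformulate(attr(stats::terms(rhs), "term.labels"),
                                response = outcome)
  fit <- stats::lm(formula, data = records)
  cl_df <- as.data.frame(records[cluster])
  vc <- sandwich::vcovCL(fit, cluster = cl_df, type = "HC1", cadjust = TRUE)
  se <- sqrt(diag(vc))
  est <- stats::coef(fit)
  tstat <- est / se
  df_resid <- stats::df.residual(fit)
  list(
    model = fit,
    vcov = vc,
    coefficients = tibble::tibble(
      term = names(est),
      estimate = unname(est),
      std_error = unname(se),
      statistic = unname(tstat),
      p_value = unname(2 * stats::pt(-abs(tstat), df_resid))
    )
  )
}

#' Treatment contrast restricted to rounds before the first check
#'
#' Keeps, for each group, only the rounds up to and including the group's
#' first check (all rounds if the group never experienced one), then runs
#' [treatment_contrast()] on the subset. Contributions in those rounds were
#' decided before any check had been experienced — checks resolve after
#' contributing — so the subset contrasts behaviour under a looming but not
#' yet realised threat.
#'
#' @inheritParams treatment_contrast
#' @return As [treatment_contrast()], plus `n_obs` of the restricted subset.
#' @export
pre_first_check_contrast <- function(records,
                                     rhs = ~treatment,
                                     cluster = c("group_id", "participant_id"),
                                     outcome = "contribution") {
  first_checks <- records |>
    dplyr::filter(.data$check_occurred) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(first_check = min(.data$round), .groups = "drop")
  subset <- records |>
    dplyr::left_join(first_checks, by = "group_id") |>
    dplyr::filter(is.na(.data$first_check) | .data$round <= .data$first_check) |>
    dplyr::select(-"first_check")
  if (nrow(subset) == 0) {
    warning("no rounds before the first check; returning NULL", call. = FALSE)
    return(NULL)
  }
  out <- treatment_contrast(subset, rhs = rhs, cluster = cluster, outcome = outcome)
  out$n_obs <- nrow(subset)
  out
}
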