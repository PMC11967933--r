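# Shared fixture builders. Everything is generated in code; no files.

# A cohort of groups with planted UC/CC/FR agents played through the engine.
recovery_cohort <- function(seed, noise_sd = 1.5, n_groups = 15,
                            treatments = default_treatments()[c("Control", "40P",
                                                                "Level", "Impact")],
                            type_mix = c(UC = 0.4, CC = 0.4, FR = 0.2)) {
  set.seed(seed)
  generate_cohort(cohort_config(
    n_groups = n_groups, treatments = treatments,
    type_mix = type_mix, noise_sd = noise_sd
  ))
}

# Share of participants whose fitted label matches the planted type.
recovery_rate <- function(cohort) {
  fits <- classify_dataset(cohort$records)$participants
  merged <- dplyr::inner_join(
    fits, cohort$truth,
    by = c("treatment", "group_id", "participant_id"),
    suffix = c("_fit", "_true")
  )
  mean(merged$type_fit == merged$type_true)
}

# A session of four constant contributors.
constant_session <- function(levels, spec, ...) {
  play_session(lapply(levels, constant_strategy), spec, ...)
}

# Hand-built long-format records: one group, scripted contributions and checks.
# contributions: matrix rounds x 4; checks: data.frame(round, threshold, passed).
scripted_records <- function(contributions, checks = NULL,
                             treatment = "40P", group_id = "G1",
                             wipe_on_fail = "both") {
  n_rounds <- nrow(contributions)
  n <- ncol(contributions)
  rows <- list()
  ind <- rep(0, n)
  grp <- 0
  for (r in seq_len(n_rounds)) {
    cvec <- contributions[r, ]
    S <- sum(cvec)
    ind <- ind + 20 - cvec
    grp <- grp + 1.6 * S
    chk <- if (!is.null(checks)) checks[checks$round == r, ] else NULL
    has_check <- !is.null(chk) && nrow(chk) == 1
    wipe <- "none"
    if (has_check && !chk$passed) {
      wipe <- wipe_on_fail
      if (wipe %in% c("individual", "both")) ind <- rep(0, n)
      if (wipe %in% c("group", "both")) grp <- 0
    }
    om <- if (r == 1) rep(NA_real_, n) else {
      (sum(contributions[r - 1, ]) - contributions[r - 1, ]) / (n - 1)
    }
    rows[[r]] <- tibble::tibble(
      session_id = "S1", treatment = treatment, group_id = group_id,
      participant_id = paste0(group_id, "_p", seq_len(n)),
      round = r, contribution = as.integer(cvec), others_mean_prev = om,
      check_occurred = has_check,
      threshold = if (has_check) as.integer(chk$threshold) else NA_integer_,
      passed = if (has_check) chk$passed else NA,
      wipe_outcome = wipe,
      individual_balance = ind, group_balance = grp
    )
  }
  dplyr::bind_rows(rows)
}
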