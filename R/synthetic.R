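#' Configuration of a synthetic experiment cohort
#'
#' Describes a cohort of groups playing the game through the engine, with each
#' participant assigned a planted behavioural type. An agent of type `(alpha,
#' beta)` contributes `round(clip(alpha + beta * others_mean_prev +
#' Normal(0, noise_sd), 0, e))` from round 2 on, and draws its round-1
#' contribution from `round(clip(Normal(init, init_sd), 0, e))`. The planted
#' parameters form the hidden ground truth against which classifier recovery
#' is measured.
#'
#' @param n_groups Groups per treatment.
#' @param treatments Named list of [treatment_spec()]s (default
#'   [default_treatments()]).
#' @param type_mix Named shares over `UC`, `CC`, `FR`, `Uncategorized`
#'   summing to 1. Defaults to the pooled treatment anchor (0.56, 0.36, 0.04,
#'   0.04).
#' @param noise_sd Gaussian contribution noise, in units (default 1.5).
#' @param type_params Per-type `alpha`, `beta`, `init`; see
#'   [planted_type_params()].
#' @param init_sd Standard deviation of the round-1 draw (default 4,
#'   reflecting the wide dispersion of first-round contributions in
#'   public-goods experiments).
#' @param sessions Session labels; groups are dealt round-robin over sessions
#'   (a stand-in for the study's two country sites).
#' @param session_init_shift Named per-session additive shift of the round-1
#'   mean (default none).
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_groups,
                          treatments = default_treatments(),
                          type_mix = c(UC = 0.56, CC = 0.36, FR = 0.04,
                                       Uncategorized = 0.04),
                          noise_sd = 1.5,
                          type_params = planted_type_params(),
                          init_sd = 4,
                          sessions = "S1",
                          session_init_shift = NULL) {
  stopifnot(
    n_groups >= 1,
    abs(sum(type_mix) - 1) < 1e-8, all(type_mix >= 0),
    noise_sd >= 0, init_sd >= 0
  )
  if (is.null(names(type_mix)) || !all(names(type_mix) %in%
                                       c("UC", "CC", "FR", "Uncategorized"))) {
    stop("type_mix must be named with UC/CC/FR/Uncategorized", call. = FALSE)
  }
  structure(
    list(
      n_groups = as.integer(n_groups),
      treatments = treatments,
      type_mix = type_mix,
      noise_sd = noise_sd,
      type_params = type_params,
      init_sd = init_sd,
      sessions = sessions,
      session_init_shift = session_init_shift
    ),
    class = "cohort_config"
  )
}

# Strategy closure for one planted agent.
planted_agent_strategy <- function(alpha, beta, init_mean, noise_sd, init_sd,
                                   endowment) {
  force(alpha); force(beta); force(init_mean)
  force(noise_sd); force(init_sd); force(endowment)
  function(round, own_prev, others_mean_prev, check_info) {
    raw <- if (round == 1L) {
      stats::rnorm(1, init_mean, init_sd)
    } else {
      alpha + beta * others_mean_prev + stats::rnorm(1, 0, noise_sd)
    }
    as.integer(round(pmin(pmax(raw, 0), endowment)))
  }
}

#' Generate a synthetic cohort with planted behavioural types
#'
#' Plays `n_groups` groups of planted agents per treatment through
#' [play_session()] — so checks, thresholds and wipes are drawn by the game
#' engine — and returns both the long-format records and the hidden truth
#' table of planted types and parameters. Call `set.seed()` first for a
#' reproducible cohort.
#'
#' @param config A [cohort_config()].
#' @return A list with `records` (long-format tibble, schema of
#'   [play_session()]) and `truth` (one row per participant: ids, planted
#'   `type`, `alpha`, `beta`, `init_mean`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  all_records <- list()
  all_truth <- list()
  idx <- 0L

  for (tr_name in names(config$treatments)) {
    spec <- config$treatments[[tr_name]]
    for (g in seq_len(config$n_groups)) {
      idx <- idx + 1L
      session <- config$sessions[((g - 1L) %% length(config$sessions)) + 1L]
      shift <- if (!is.null(config$session_init_shift) &&
                   session %in% names(config$session_init_shift)) {
        config$session_init_shift[[session]]
      } else {
        0
      }
      group_id <- sprintf("%s_g%03d", tr_name, g)
      types <- sample(names(config$type_mix), spec$group_size,
                      replace = TRUE, prob = config$type_mix)
      params <- config$type_params[types]
      strategies <- lapply(seq_len(spec$group_size), function(i) {
        planted_agent_strategy(
          alpha = params[[i]]$alpha, beta = params[[i]]$beta,
          init_mean = params[[i]]$init + shift,
          noise_sd = config$noise_sd, init_sd = config$init_sd,
          endowment = spec$endowment
        )
      })
      all_records[[idx]] <- play_session(strategies, spec,
                                         session_id = session,
                                         group_id = group_id)
      all_truth[[idx]] <- tibble::tibble(
        session_id = session,
        treatment = tr_name,
        group_id = group_id,
        participant_id = paste0(group_id, "_p", seq_len(spec$group_size)),
        type = types,
        alpha = vapply(params, `[[`, numeric(1), "alpha"),
        beta = vapply(params, `[[`, numeric(1), "beta"),
        init_mean = vapply(params, `[[`, numeric(1), "init") + shift
      )
    }
  }
  list(
    records = dplyr::bind_rows(all_records),
    truth = dplyr::bind_rows(all_truth)
  )
}
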