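#' Fit a linear conditional-contribution profile (LCP)
#'
#' The LCP is the ordinary least-squares line of a participant's contribution
#' on the mean contribution of the other group members that they observed
#' immediately before contributing (the lagged others' mean). The intercept
#' measures willingness to contribute when others give nothing; the slope
#' measures responsiveness to others. Round 1 has no lagged observation and is
#' excluded upstream, so a 20-round session yields 19 paired observations.
#'
#' @param responses The participant's contributions in rounds `2..R`.
#' @param regressors The lagged others' means (rounds `1..R-1`), same length.
#' @return An object of class `"lcp_profile"`: `intercept`, `slope`, `n_obs`,
#'   and the line's extremes `y_min`/`y_max` over the regressor domain
#'   `[0, endowment]`. If the regressors have zero variance the slope is set to
#'   0 and the intercept to the mean response (degenerate rule).
#' @param endowment Upper end of the regressor domain (default 20).
#' @examples
#' fit_lcp(c(6, 10, 14), c(5, 10, 15))  # intercept 2, slope 0.8
#' @export
fit_lcp <- function(responses, regressors, endowment = 20) {
  if (length(responses) != length(regressors)) {
    stop("responses and regressors must have equal length", call. = FALSE)
  }
  if (length(responses) < 2L) {
    stop("need at least 2 observations to fit an LCP", call. = FALSE)
  }
  if (anyNA(responses) || anyNA(regressors)) {
    stop("LCP fit does not accept missing values", call. = FALSE)
  }
  x <- as.numeric(regressors)
  y <- as.numeric(responses)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    slope <- 0
    intercept <- mean(y)
  } else {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    intercept <- mean(y) - slope * mean(x)
  }
  ends <- c(intercept, intercept + endowment * slope)
  structure(
    list(
      intercept = intercept,
      slope = slope,
      n_obs = length(y),
      y_min = min(ends),
      y_max = max(ends),
      endowment = endowment
    ),
    class = "lcp_profile"
  )
}

#' @export
print.lcp_profile <- function(x, ...) {
  cat(sprintf("<lcp_profile> intercept %.3f, slope %.3f (n = %d; line %.2f to %.2f)\n",
              x$intercept, x$slope, x$n_obs, x$y_min, x$y_max))
  invisible(x)
}

#' Classify a participant from their LCP
#'
#' Player types are read off the fitted line over the regressor domain:
#' a Free-Rider's (FR) line lies entirely below half the endowment (10 units),
#' an Unconditional Cooperator's (UC) entirely above it, and a Conditional
#' Cooperator's (CC) has a positive slope and crosses it. Anything else —
#' including negative-slope crossers and constant lines sitting exactly on the
#' boundary — is Uncategorized.
#'
#' @param lcp An [fit_lcp()] result, or any list with `y_min`, `y_max`, `slope`.
#' @param half_endowment The classification boundary (default 10 units).
#' @param eps Comparison tolerance.
#' @param slope_p_max Optional significance screen: if not `NULL`, the CC label
#'   additionally requires the slope's two-sided p-value (supplied as
#'   `lcp$slope_p`) to be at most this value. Off by default.
#' @return One of `"UC"`, `"CC"`, `"FR"`, `"Uncategorized"`.
#' @examples
#' classify_lcp(fit_lcp(c(6, 10, 14), c(5, 10, 15)))  # "CC"
#' @export
classify_lcp <- function(lcp, half_endowment = 10, eps = 1e-9,
                         slope_p_max = NULL) {
  if (lcp$y_max < half_endowment - eps) return("FR")
  if (lcp$y_min > half_endowment + eps) return("UC")
  crosses <- lcp$y_min <= half_endowment + eps && lcp$y_max >= half_endowment - eps
  if (lcp$slope > eps && crosses) {
    if (!is.null(slope_p_max) &&
        (is.null(lcp$slope_p) || lcp$slope_p > slope_p_max)) {
      return("Uncategorized")
    }
    return("CC")
  }
  "Uncategorized"
}

#' Classify every participant in a long-format dataset
#'
#' Fits each participant's LCP on rounds `2..R` (contribution against the
#' lagged others' mean) and labels them UC / CC / FR / Uncategorized.
#' Participants with fewer than 2 usable rounds are labeled Uncategorized with
#' a warning.
#'
#' @param records Long-format tibble as written by [play_session()] (columns
#'   `treatment`, `participant_id`, `round`, `contribution`,
#'   `others_mean_prev` at minimum).
#' @param endowment Endowment defining the regressor domain (default 20).
#' @param half_endowment Classification boundary (default 10).
#' @return A list with `participants` (one row per participant: ids, fitted
#'   intercept/slope, `type`) and `shares` (per-treatment type shares plus a
#'   pooled `Control` vs `Treatments` split).
#' @export
classify_dataset <- function(records, endowment = 20, half_endowment = 10) {
  usable <- dplyr::filter(records, !is.na(.data$others_mean_prev))
  fits <- usable |>
    dplyr::group_by(.data$treatment, .data$group_id, .data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        return(tibble::tibble(intercept = NA_real_, slope = NA_real_,
                              n_obs = nrow(df), type = "Uncategorized"))
      }
      lcp <- fit_lcp(df$contribution, df$others_mean_prev, endowment = endowment)
      tibble::tibble(
        intercept = lcp$intercept, slope = lcp$slope, n_obs = lcp$n_obs,
        type = classify_lcp(lcp, half_endowment = half_endowment)
      )
    }) |>
    dplyr::ungroup()

  short <- sum(fits$n_obs < 2L)
  if (short > 0) {
    warning(sprintf("%d participant(s) had fewer than 2 usable rounds; labeled Uncategorized",
                    short), call. = FALSE)
  }

  levels <- c("UC", "CC", "FR", "Uncategorized")
  share_table <- function(df, label) {
    counts <- table(factor(df$type, levels = levels))
    tibble::tibble(
      condition = label,
      type = levels,
      n = as.integer(counts),
      share = as.numeric(counts) / nrow(df)
    )
  }
  by_treatment <- fits |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_map(~ share_table(.x, .y$treatment)) |>
    dplyr::bind_rows()
  pooled <- dplyr::bind_rows(
    share_table(dplyr::filter(fits, .data$treatment == "Control"), "Control (pooled)"),
    share_table(dplyr::filter(fits, .data$treatment != "Control"), "Treatments (pooled)")
  )

  list(participants = fits, shares = dplyr::bind_rows(by_treatment, pooled))
}

#' Direction-of-adjustment conformity rates
#'
#' For every participant-round from round 2 on, compares the participant's
#' previous contribution with the others' mean they observed (position: above /
#' below / equal) and the change they then made (adjustment: decrease /
#' increase / none). An adjustment conforms when it moves toward the group:
#' decrease when above, increase when below. The conformity rate per condition
#' is the share of conforming moves among rounds where the position is not
#' equal (an equal position prescribes no direction).
#'
#' @param records Long-format tibble (see [classify_dataset()]).
#' @return A list with `moves` (one row per participant-round with position,
#'   adjustment and the conforming flag) and `rates` (per-treatment conformity
#'   rate and counts).
#' @export
conformity_direction <- function(records) {
  moves <- records |>
    dplyr::arrange(.data$treatment, .data$group_id, .data$participant_id, .data$round) |>
    dplyr::group_by(.data$treatment, .data$group_id, .data$participant_id) |>
    dplyr::mutate(prev_contribution = dplyr::lag(.data$contribution)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$others_mean_prev)) |>
    dplyr::mutate(
      position = dplyr::case_when(
        .data$prev_contribution > .data$others_mean_prev ~ "above",
        .data$prev_contribution < .data$others_mean_prev ~ "below",
        TRUE ~ "equal"
      ),
      adjustment = dplyr::case_when(
        .data$contribution < .data$prev_contribution ~ "decrease",
        .data$contribution > .data$prev_contribution ~ "increase",
        TRUE ~ "none"
      ),
      conforming = (.data$position == "above" & .data$adjustment == "decrease") |
        (.data$position == "below" & .data$adjustment == "increase")
    )
  rates <- moves |>
    dplyr::filter(.data$position != "equal") |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n_moves = dplyr::n(),
      conformity_rate = mean(.data$conforming),
      .groups = "drop"
    )
  list(moves = moves, rates = rates)
}

#' Rank-persistence conformity summary
#'
#' Ranks contributions within each group and round (ties averaged) and
#' summarises two aspects of rank behaviour: the lag-1 autocorrelation of a
#' participant's rank (how persistent high/low contributors are) and the rate
#' of rank-directed adjustment (contributions move down when ranked above the
#' group's mean rank and up when below it, mirroring the direction-conformity
#' measure on the rank scale). Rounds in which all group members tie carry no
#' rank information; if every round ties, the autocorrelation is reported as
#' `NA`.
#'
#' @param records Long-format tibble (see [classify_dataset()]).
#' @return A tibble per treatment with `rank_autocorrelation`,
#'   `rank_conformity_rate` and the move counts behind each.
#' @export
conformity_rank <- function(records) {
  ranked <- records |>
    dplyr::group_by(.data$treatment, .data$group_id, .data$round) |>
    dplyr::mutate(rank = rank(.data$contribution)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$treatment, .data$group_id, .data$participant_id, .data$round) |>
    dplyr::group_by(.data$treatment, .data$group_id, .data$participant_id) |>
    dplyr::mutate(
      prev_rank = dplyr::lag(.data$rank),
      prev_contribution = dplyr::lag(.data$contribution)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_rank))

  ranked |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      rank_autocorrelation = {
        ok <- stats::sd(.data$rank) > 0 && stats::sd(.data$prev_rank) > 0
        if (ok) stats::cor(.data$rank, .data$prev_rank) else NA_real_
      },
      n_directed = sum(.data$prev_rank != mean(.data$rank)),
      rank_conformity_rate = {
        mid <- mean(.data$rank)  # (n + 1) / 2 for complete groups
        directed <- .data$prev_rank != mid
        if (any(directed)) {
          mean((.data$prev_rank[directed] > mid &
                  .data$contribution[directed] < .data$prev_contribution[directed]) |
                 (.data$prev_rank[directed] < mid &
                    .data$contribution[directed] > .data$prev_contribution[directed]))
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    )
}
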