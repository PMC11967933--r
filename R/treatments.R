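#' Define a treatment (experimental condition) of the threshold public goods game
#'
#' A treatment bundles all parameters of one condition of the game: the
#' per-round endowment, the public-pot multiplier, the group size, the number
#' of rounds, the per-round probability of a random check, the threshold rule
#' the group total is compared against when a check occurs, and the wipe rule
#' applied when the group fails a check.
#'
#' @param name Condition label, e.g. `"Control"`, `"10P"`, `"40P"`, `"70P"`,
#'   `"100P"`, `"Impact"`, `"Level"`.
#' @param check_prob Probability `p` of a check in each round, in `[0, 1]`.
#' @param threshold Either a single integer (fixed threshold, default 60) or a
#'   length-2 integer vector `c(lo, hi)`; in the latter case the threshold is
#'   drawn uniformly from the integers `lo:hi` in each check round, after
#'   contributions are made.
#' @param wipe_rule `"full"` (a failed check zeroes both the individual and the
#'   group accounts) or `"impact"` (one of individual / group / both, each with
#'   probability 1/3). Under `"impact"`, an "individual" wipe zeroes every
#'   player's individual account.
#' @param endowment Units given to each player per round (default 20).
#' @param multiplier Factor applied to the pot before it is added to the group
#'   account (default 1.6).
#' @param group_size Players per group (default 4).
#' @param n_rounds Rounds per session (default 20).
#'
#' @return An object of class `"treatment_spec"` (a named list).
#' @examples
#' treatment_spec("40P", check_prob = 0.4)
#' treatment_spec("Level", check_prob = 0.4, threshold = c(50, 70))
#' @export
treatment_spec <- function(name,
                           check_prob,
                           threshold = 60L,
                           wipe_rule = c("full", "impact"),
                           endowment = 20L,
                           multiplier = 1.6,
                           group_size = 4L,
                           n_rounds = 20L) {
  wipe_rule <- match.arg(wipe_rule)
  stopifnot(
    is.numeric(check_prob), length(check_prob) == 1L,
    check_prob >= 0, check_prob <= 1,
    is.numeric(threshold), length(threshold) %in% c(1L, 2L),
    all(threshold == round(threshold)),
    endowment > 0, multiplier > 1, group_size >= 2, n_rounds >= 1
  )
  if (length(threshold) == 2L && threshold[1] > threshold[2]) {
    stop("threshold range must satisfy lo <= hi", call. = FALSE)
  }
  structure(
    list(
      name = as.character(name),
      check_prob = as.numeric(check_prob),
      threshold = as.integer(threshold),
      wipe_rule = wipe_rule,
      endowment = as.integer(endowment),
      multiplier = as.numeric(multiplier),
      group_size = as.integer(group_size),
      n_rounds = as.integer(n_rounds)
    ),
    class = "treatment_spec"
  )
}

#' @export
print.treatment_spec <- function(x, ...) {
  thr <- if (length(x$threshold) == 1L) {
    as.character(x$threshold)
  } else {
    sprintf("uniform on {%d, ..., %d}", x$threshold[1], x$threshold[2])
  }
  cat(sprintf(
    "<treatment_spec> %s: p = %.2f, threshold %s, wipe = %s, e = %d, m = %.1f, n = %d, R = %d\n",
    x$name, x$check_prob, thr, x$wipe_rule,
    x$endowment, x$multiplier, x$group_size, x$n_rounds
  ))
  invisible(x)
}

#' The standard set of experimental conditions
#'
#' Returns the conditions used in the study design: a deterministic `Control`
#' (no checks), check-probability treatments `10P`/`40P`/`70P`/`100P` with a
#' fixed threshold at 75% of the group endowment (60 units), `Impact` (40%
#' checks, wipe target uncertain), and `Level` (40% checks, threshold uniform
#' on 50--70, revealed after contributing).
#'
#' @return A named list of [treatment_spec()] objects.
#' @export
default_treatments <- function() {
  list(
    Control = treatment_spec("Control", check_prob = 0),
    `10P`   = treatment_spec("10P",  check_prob = 0.1),
    `40P`   = treatment_spec("40P",  check_prob = 0.4),
    `70P`   = treatment_spec("70P",  check_prob = 0.7),
    `100P`  = treatment_spec("100P", check_prob = 1.0),
    Impact  = treatment_spec("Impact", check_prob = 0.4, wipe_rule = "impact"),
    Level   = treatment_spec("Level",  check_prob = 0.4, threshold = c(50L, 70L))
  )
}

#' Read treatment definitions from a JSON configuration file
#'
#' The file must be a JSON object keyed by treatment name; each entry may set
#' `check_prob`, `threshold` (scalar or `[lo, hi]`), `wipe_rule`, `endowment`,
#' `multiplier`, `group_size` and `n_rounds`. Missing fields take the
#' [treatment_spec()] defaults.
#'
#' @param path Path to the JSON file.
#' @return A named list of [treatment_spec()] objects.
#' @export
read_treatments_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == "")) {
    stop("treatment config must be a JSON object keyed by treatment name",
         call. = FALSE)
  }
  lapply(stats::setNames(names(raw), names(raw)), function(nm) {
    entry <- raw[[nm]]
    allowed <- c("check_prob", "threshold", "wipe_rule", "endowment",
                 "multiplier", "group_size", "n_rounds")
    bad <- setdiff(names(entry), allowed)
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in treatment '%s': %s",
                   nm, paste(bad, collapse = ", ")), call. = FALSE)
    }
    do.call(treatment_spec, c(list(name = nm), entry))
  })
}

# Probability that a drawn threshold exceeds the group total S, given a check.
# Vectorised over S. For a fixed threshold T this is 1{S < T}; for a uniform
# integer threshold on {lo, ..., hi} it is #{t : t > S} / (hi - lo + 1).
threshold_fail_prob <- function(S, spec) {
  thr <- spec$threshold
  if (length(thr) == 1L) {
    as.numeric(S < thr)
  } else {
    n_vals <- thr[2] - thr[1] + 1
    pmin(pmax(thr[2] - pmax(floor(S), thr[1] - 1), 0), n_vals) / n_vals
  }
}

# Draw one threshold value for a check round.
draw_threshold <- function(spec) {
  thr <- spec$threshold
  if (length(thr) == 1L) thr else sample(thr[1]:thr[2], 1L)
}
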