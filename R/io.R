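RECORD_COLUMNS <- c(
  "session_id", "treatment", "group_id", "participant_id", "round",
  "contribution", "others_mean_prev", "check_occurred", "threshold",
  "passed", "wipe_outcome", "individual_balance", "group_balance"
)

#' Validate a long-format records table
#'
#' Hard schema validation of the long format shared by all modules: required
#' columns present, contributions integers in `[0, endowment]`, rounds
#' positive integers, flags boolean, `others_mean_prev` missing exactly in
#' round 1, `threshold`/`passed` present iff a check occurred, and wipes only
#' on failed checks. Violations raise an error naming the first offending row
#' and column.
#'
#' @param records A data frame.
#' @param endowment Contribution cap (default 20).
#' @return The validated records, invisibly, as a tibble.
#' @export
validate_records <- function(records, endowment = 20) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  fail <- function(rows, col, why) {
    stop(sprintf("invalid records: row %d, column '%s': %s",
                 which(rows)[1], col, why), call. = FALSE)
  }
  bad <- is.na(records$contribution) |
    records$contribution != round(records$contribution) |
    records$contribution < 0 | records$contribution > endowment
  if (any(bad)) fail(bad, "contribution",
                     sprintf("must be an integer in [0, %d]", endowment))
  bad <- is.na(records$round) | records$round < 1 |
    records$round != round(records$round)
  if (any(bad)) fail(bad, "round", "must be a positive integer")
  if (!is.logical(records$check_occurred) || anyNA(records$check_occurred)) {
    stop("invalid records: column 'check_occurred' must be TRUE/FALSE with no missing values",
         call. = FALSE)
  }
  bad <- records$round == 1 & !is.na(records$others_mean_prev)
  if (any(bad)) fail(bad, "others_mean_prev", "must be missing in round 1")
  bad <- records$round >= 2 & is.na(records$others_mean_prev)
  if (any(bad)) fail(bad, "others_mean_prev", "must be present from round 2 on")
  bad <- records$check_occurred & (is.na(records$threshold) | is.na(records$passed))
  if (any(bad)) fail(bad, "threshold", "threshold and passed required when a check occurred")
  bad <- !records$check_occurred & (!is.na(records$threshold) | !is.na(records$passed))
  if (any(bad)) fail(bad, "threshold", "threshold/passed must be missing without a check")
  bad <- records$wipe_outcome != "none" &
    (!records$check_occurred | is.na(records$passed) | records$passed)
  if (any(bad)) fail(bad, "wipe_outcome", "wipes require a failed check")
  if (any(!records$wipe_outcome %in% c("none", "individual", "group", "both"))) {
    stop("invalid records: column 'wipe_outcome' has an unknown value", call. = FALSE)
  }
  bad <- is.na(records$individual_balance) | records$individual_balance < 0 |
    is.na(records$group_balance) | records$group_balance < 0
  if (any(bad)) fail(bad, "individual_balance", "balances must be nonnegative")
  invisible(records)
}

#' Read a long-format records CSV
#'
#' Reads and validates a records file written by [write_records()] (or any CSV
#' with the same schema).
#'
#' @param path CSV path.
#' @param endowment Contribution cap used in validation (default 20).
#' @return A validated tibble.
#' @export
read_records <- function(path, endowment = 20) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  for (col in c("session_id", "treatment", "group_id", "participant_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  for (col in c("check_occurred", "passed")) {
    records[[col]] <- as.logical(records[[col]])
  }
  for (col in c("round", "contribution", "threshold")) {
    records[[col]] <- as.integer(records[[col]])
  }
  for (col in c("others_mean_prev", "individual_balance", "group_balance")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$wipe_outcome <- as.character(records$wipe_outcome)
  records$wipe_outcome[is.na(records$wipe_outcome)] <- "none"
  validate_records(records, endowment = endowment)
  records
}

#' Write a long-format records CSV
#'
#' @param records A records tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full pipeline: synthesise, classify, summarise, simulate
#'
#' A thin orchestrator over the package's stages. Generates a synthetic cohort,
#' classifies it, computes conformity and responses-to-check summaries, runs
#' the UC-proportion sweep, and writes every artifact plus a manifest (seed,
#' per-stage record counts, output file hashes) under `out_dir`. The single
#' `seed` is expanded into independent per-stage seeds, so adding a stage does
#' not perturb the streams of earlier ones.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; recorded in the manifest.
#' @param cohort A [cohort_config()] (default: 10 groups of every standard
#'   treatment).
#' @param uc_grid UC proportions for the sweep.
#' @param abm_args Extra arguments for [sweep_uc()] (e.g. `n_groups`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir,
                         seed = 1L,
                         cohort = cohort_config(n_groups = 10),
                         uc_grid = seq(0, 1, by = 0.1),
                         abm_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seeds <- derive_stage_seeds(seed, c("synth", "classify", "stats", "abm"))
  timings <- list()
  paths <- character()

  stamp <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    value
  }

  set.seed(stage_seeds[["synth"]])
  cohort_out <- stamp("synth", generate_cohort(cohort))
  paths["records"] <- file.path(out_dir, "records.csv")
  paths["truth"] <- file.path(out_dir, "truth.csv")
  write_records(cohort_out$records, paths["records"])
  utils::write.csv(cohort_out$truth, paths["truth"], row.names = FALSE)

  set.seed(stage_seeds[["classify"]])
  classified <- stamp("classify", classify_dataset(cohort_out$records))
  paths["classification"] <- file.path(out_dir, "classification.csv")
  paths["type_shares"] <- file.path(out_dir, "type_shares.json")
  utils::write.csv(classified$participants, paths["classification"], row.names = FALSE)
  jsonlite::write_json(classified$shares, paths["type_shares"],
                       dataframe = "rows", digits = NA)

  set.seed(stage_seeds[["stats"]])
  rac <- stamp("stats", rounds_after_check(cohort_out$records))
  paths["rounds_after_check"] <- file.path(out_dir, "rounds_after_check.csv")
  utils::write.csv(rac$by_lag, paths["rounds_after_check"], row.names = FALSE)

  set.seed(stage_seeds[["abm"]])
  curve <- stamp("abm", do.call(sweep_uc, c(list(uc_grid = uc_grid), abm_args)))
  paths["uc_curve"] <- file.path(out_dir, "uc_curve.csv")
  utils::write.csv(curve, paths["uc_curve"], row.names = FALSE)

  manifest <- list(
    seed = seed,
    stage_seeds = as.list(stage_seeds),
    n_records = nrow(cohort_out$records),
    n_participants = nrow(cohort_out$truth),
    timings_sec = timings,
    outputs = lapply(as.list(paths), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Expand one master seed into named per-stage seeds (kept below 2^31).
derive_stage_seeds <- function(seed, stages) {
  stats::setNames(
    (as.numeric(seed) %% 2147483647 + seq_along(stages) * 1000003) %% 2147483647,
    stages
  )
}
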