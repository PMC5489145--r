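TRIAL_COLUMNS <- c("subject_id", "trial_index", "block_id", "scenario_type",
                   "group_size", "revision_allowed", "J1", "confidence_raw",
                   "C", "JS", "D", "J1_norm_abs", "J2")

#' Write a trial table to CSV
#'
#' Writes the canonical trial-table schema: one row per trial, columns
#' `subject_id, trial_index, block_id, scenario_type, group_size,
#' revision_allowed, J1, confidence_raw, C, JS, D, J1_norm_abs, J2`, with
#' `J2` left empty on no-revision trials. `group_size` is stored as the
#' jury size (5/20); the 0/1 flag `G` is derived again on read.
#'
#' @param trials Trial table (extra columns are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss) > 0) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  }
  write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Validates the canonical schema (raising a schema error that names the
#' first missing column) and derives the group-size flag `G` (0 for the
#' smaller jury size present, 1 for the larger).
#'
#' @param path CSV path written by [write_trials()] (or any file with the
#'   same columns).
#' @return A trial data frame with the canonical columns plus `G`.
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  for (col in TRIAL_COLUMNS) {
    if (!col %in% names(trials)) {
      stop(structure(
        class = c("jurybayes_schema_error", "error", "condition"),
        list(message = paste0("trial CSV is missing column: ", col),
             call = NULL)
      ))
    }
  }
  if (nrow(trials) == 0L) {
    stop(structure(
      class = c("jurybayes_schema_error", "error", "condition"),
      list(message = "trial CSV contains no rows", call = NULL)
    ))
  }
  trials$revision_allowed <- as.logical(trials$revision_allowed)
  trials$J2 <- as.numeric(trials$J2)
  sizes <- sort(unique(trials$group_size))
  trials$G <- match(trials$group_size, sizes) - 1L
  if (length(sizes) == 1L) trials$G <- rep(0L, nrow(trials))
  trials
}

#' Write per-subject ground truth as JSON
#'
#' @param truth Ground-truth table from [generate_dataset()] (must carry a
#'   `subject_id` column).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(!is.null(truth$subject_id))
  recs <- lapply(seq_len(nrow(truth)), function(i) {
    as.list(truth[i, setdiff(names(truth), "subject_id"), drop = FALSE])
  })
  names(recs) <- truth$subject_id
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-subject ground truth from JSON
#'
#' @param path JSON path written by [write_truth()].
#' @return A data frame with `subject_id` plus the parameter columns.
#' @export
read_truth <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- do.call(rbind, lapply(names(recs), function(sid) {
    data.frame(subject_id = sid, as.data.frame(recs[[sid]]))
  }))
  rownames(out) <- NULL
  out
}

#' Default run configuration
#'
#' The flat key-value configuration consumed by the command-line entry
#' points: the task design, the ground-truth sampler settings, and the
#' fitting settings. Every key can be overridden from a YAML file.
#'
#' @return A named list of defaults.
#' @export
default_run_config <- function() {
  list(
    n_subjects = 23L,
    n_trials_per_subject = 60L,
    n_no_revision = 8L,
    judgment_min = 0,
    judgment_max = 30,
    default_judgment = 15,
    d_min = 4,
    d_max = 10,
    group_size_small = 5L,
    group_size_large = 20L,
    coupling = 0.65,
    master_seed = 1L,
    generating_model = "bayes",
    truth_eps = 0.5,
    fit_n_starts = 10L,
    fit_eps2_floor = 1e-6,
    recovery_sign_rate_floor = 0.8,
    recovery_rank_cor_floor = 0.5
  )
}

#' Read a run configuration file
#'
#' Reads a YAML file of flat keys, overlaying them on
#' [default_run_config()]; unknown keys raise an error.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg
}

#' Write a run configuration file
#'
#' @param config Configuration list (from [read_run_config()] or edited).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build a design_config from a flat run configuration.
run_config_to_design <- function(cfg) {
  design_config(
    n_subjects = cfg$n_subjects,
    n_trials_per_subject = cfg$n_trials_per_subject,
    n_no_revision = cfg$n_no_revision,
    judgment_min = cfg$judgment_min,
    judgment_max = cfg$judgment_max,
    default_judgment = cfg$default_judgment,
    d_min = cfg$d_min,
    d_max = cfg$d_max,
    group_sizes = c(cfg$group_size_small, cfg$group_size_large),
    coupling = cfg$coupling,
    master_seed = cfg$master_seed
  )
}

#' Read a one-column numeric series
#'
#' Accepts plain one-column text or CSV (the first numeric column of a
#' headed CSV is used).
#'
#' @param path File path.
#' @return A numeric vector.
#' @export
read_series <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first) || grepl("[A-Za-z]", first)) {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    num <- vapply(tab, is.numeric, logical(1))
    if (!any(num)) stop("no numeric column found in ", path)
    return(tab[[which(num)[1]]])
  }
  scan(path, quiet = TRUE)
}
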