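#' Task design configuration
#'
#' Describes the structure of one synthetic experiment: how many subjects and
#' trials, the judgment scale, the allowed gap between the initial judgment
#' and the group judgment, the two jury sizes, and the confidence scale.
#'
#' Defaults mirror the jury task: 60 trials per subject of which 8 allow no
#' revision (52 valid trials), punishment judgments on a continuous 0--30
#' year slider with a default of 15 years, a group judgment differing from
#' the initial judgment by 4 to 10 years with the direction counterbalanced,
#' jury sizes of 5 or 20 presented in blocks, and a 10-item confidence
#' Likert scale from -5 to +5 (no 0).
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_trials_per_subject Trials per subject.
#' @param n_no_revision Trials per subject on which no revision is allowed.
#' @param judgment_min,judgment_max Bounds of the judgment scale (years).
#' @param default_judgment Starting position of the slider (years).
#' @param d_min,d_max Bounds on `|JS - J1|`, the absolute gap between the
#'   group judgment and the initial judgment (years).
#' @param group_sizes Length-2 integer vector, small and large jury size.
#' @param confidence_levels The ordered Likert labels; 10 items, none zero.
#' @param coupling Strength in `[0, 1]` of the association between judgment
#'   extremity and confidence (see [sample_initial_state()]).
#' @param master_seed Integer master seed; all per-subject seeds derive from
#'   it deterministically.
#' @return An object of class `design_config` (a named list).
#' @examples
#' cfg <- design_config(n_subjects = 2, master_seed = 42)
#' cfg$n_trials_per_subject
#' @export
design_config <- function(n_subjects = 23L,
                          n_trials_per_subject = 60L,
                          n_no_revision = 8L,
                          judgment_min = 0,
                          judgment_max = 30,
                          default_judgment = 15,
                          d_min = 4,
                          d_max = 10,
                          group_sizes = c(5L, 20L),
                          confidence_levels = c(-5:-1, 1:5),
                          coupling = 0.65,
                          master_seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    n_no_revision = as.integer(n_no_revision),
    judgment_min = judgment_min,
    judgment_max = judgment_max,
    default_judgment = default_judgment,
    d_min = d_min,
    d_max = d_max,
    group_sizes = as.integer(group_sizes),
    confidence_levels = as.integer(confidence_levels),
    coupling = coupling,
    master_seed = as.integer(master_seed)
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

#' Validate a design configuration
#'
#' @param config A `design_config`.
#' @return `config`, invisibly, if valid; otherwise an error of class
#'   `jurybayes_config_error`.
#' @export
validate_design_config <- function(config) {
  fail <- function(msg) {
    stop(structure(
      class = c("jurybayes_config_error", "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  if (!is.list(config)) fail("config must be a design_config list")
  if (config$n_subjects < 1L) fail("n_subjects must be >= 1")
  if (config$judgment_max <= config$judgment_min) {
    fail("judgment_max must exceed judgment_min")
  }
  if (config$default_judgment <= config$judgment_min ||
      config$default_judgment >= config$judgment_max) {
    fail("default_judgment must lie strictly inside the judgment range")
  }
  if (config$d_min < 0) fail("d_min must be >= 0")
  if (config$d_max > config$judgment_max - config$judgment_min) {
    fail("d_max must not exceed the judgment range")
  }
  if (config$d_min > config$d_max) fail("d_min must not exceed d_max")
  if (config$n_no_revision >= config$n_trials_per_subject) {
    fail("n_no_revision must be smaller than n_trials_per_subject")
  }
  if (config$n_no_revision < 0L) fail("n_no_revision must be >= 0")
  if (length(config$group_sizes) != 2L || any(config$group_sizes < 1L)) {
    fail("group_sizes must be two positive counts")
  }
  if (length(config$confidence_levels) != 10L ||
      any(config$confidence_levels == 0L)) {
    fail("confidence_levels must have exactly 10 nonzero entries")
  }
  if (config$coupling < 0 || config$coupling > 1) {
    fail("coupling must be in [0, 1]")
  }
  invisible(config)
}

# Balanced +/-1 labels of length n in random order (extra label random if odd).
balanced_signs <- function(n) {
  half <- n %/% 2L
  lab <- c(rep(-1L, half), rep(1L, half))
  if (n %% 2L == 1L) lab <- c(lab, sample(c(-1L, 1L), 1L))
  sample(lab)
}

#' Generate the trial skeleton of one subject
#'
#' Lays out the within-subject design: blocks of constant jury size with
#' equal numbers of valid small- and large-group trials, `n_no_revision`
#' pseudo-randomly placed no-revision trials, scenario types balanced half
#' sympathetic / half nonsympathetic among valid trials, and a
#' counterbalanced direction (+1 severer / -1 milder) for the upcoming group
#' judgment. Judgments are not yet sampled.
#'
#' @param config A [design_config()].
#' @param subject_seed Integer seed; the same seed reproduces the same
#'   skeleton exactly.
#' @return A data frame with one row per trial and columns `trial_index`,
#'   `block_id`, `scenario_type` (-1 sympathetic, +1 nonsympathetic),
#'   `group_size`, `G` (0 small, 1 large), `revision_allowed`, and the
#'   planned gap `direction`.
#' @examples
#' head(generate_design(design_config(), subject_seed = 7))
#' @export
generate_design <- function(config, subject_seed) {
  validate_design_config(config)
  with_seed(subject_seed, {
    n <- config$n_trials_per_subject
    n_blocks <- if (n %% 6L == 0L) 6L else 2L
    block_len <- n %/% n_blocks
    block_G <- sample(rep(c(0L, 1L), each = n_blocks %/% 2L))
    G <- rep(block_G, each = block_len)
    block_id <- rep(seq_len(n_blocks), each = block_len)

    # no-revision trials: split evenly between the two jury-size halves so
    # the valid trials stay balanced across group size
    revision_allowed <- rep(TRUE, n)
    n_no <- config$n_no_revision
    n_no_half <- c(n_no %/% 2L, n_no %/% 2L)
    if (n_no %% 2L == 1L) {
      extra <- sample(1:2, 1L)
      n_no_half[extra] <- n_no_half[extra] + 1L
    }
    for (g in 0:1) {
      idx <- which(G == g)
      if (n_no_half[g + 1L] > 0L) {
        revision_allowed[sample(idx, n_no_half[g + 1L])] <- FALSE
      }
    }

    # scenario type and gap direction: balanced among valid trials within
    # each jury-size half; no-revision trials labelled at random
    scenario_type <- integer(n)
    direction <- integer(n)
    for (g in 0:1) {
      valid_idx <- which(G == g & revision_allowed)
      invalid_idx <- which(G == g & !revision_allowed)
      scenario_type[valid_idx] <- balanced_signs(length(valid_idx))
      direction[valid_idx] <- balanced_signs(length(valid_idx))
      if (length(invalid_idx) > 0L) {
        scenario_type[invalid_idx] <- sample(c(-1L, 1L), length(invalid_idx),
                                             replace = TRUE)
        direction[invalid_idx] <- sample(c(-1L, 1L), length(invalid_idx),
                                         replace = TRUE)
      }
    }

    data.frame(
      trial_index = seq_len(n),
      block_id = paste0("B", block_id),
      scenario_type = scenario_type,
      group_size = config$group_sizes[G + 1L],
      G = G,
      revision_allowed = revision_allowed,
      direction = direction
    )
  })
}
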