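#' Level of conformity
#'
#' The fraction of the individual--group gap closed by the revised
#' judgment: `LC = (J2 - J1) / (JS - J1)`. `LC = 1` means full adoption of
#' the group judgment, `LC = 0` no change, negative values movement away
#' from the group.
#'
#' @param J1,J2,JS Judgments in years (vectorized). `JS` must differ from
#'   `J1` (the task design guarantees this).
#' @return Unitless conformity levels.
#' @examples
#' level_of_conformity(10, 14, 20)  # 0.4
#' @export
level_of_conformity <- function(J1, J2, JS) {
  if (any(JS == J1)) {
    stop(structure(
      class = c("jurybayes_undefined_lc", "error", "condition"),
      list(message = "level of conformity is undefined when JS equals J1",
           call = NULL)
    ))
  }
  (J2 - J1) / (JS - J1)
}

#' Classify trials as conformity or nonconformity
#'
#' A trial counts as conformity when `LC > 0`; the boundary `LC = 0` (no
#' change) is nonconformity.
#'
#' @param LC Level-of-conformity values.
#' @return Character vector `"conformity"` / `"nonconformity"`.
#' @export
classify_conformity <- function(LC) {
  stopifnot(all(is.finite(LC)))
  ifelse(LC > 0, "conformity", "nonconformity")
}

#' Median split of confidence ratings
#'
#' Splits one subject's trials into high- and low-confidence halves at the
#' subject's own median confidence. Trials exactly at the median are
#' assigned to the low half (a deterministic tie rule); a constant
#' confidence vector triggers a degenerate-split warning and labels every
#' trial low.
#'
#' @param C Normalized confidence values of one subject (length >= 2).
#' @return Character vector of `"high"` / `"low"` labels.
#' @examples
#' median_split_confidence(c(0.2, 0.4, 0.6, 0.8))
#' @export
median_split_confidence <- function(C) {
  stopifnot(length(C) >= 2L)
  if (length(unique(C)) == 1L) {
    warning("constant confidence: degenerate median split, all trials low")
    return(rep("low", length(C)))
  }
  m <- median(C)
  ifelse(C > m, "high", "low")
}

#' Descriptive conformity summary of a trial table
#'
#' Computes the descriptive behavioral statistics of the task on valid
#' trials: per-trial level of conformity and its mean, conformity /
#' nonconformity counts, mean revised judgment split by the direction of
#' the group judgment (severer `D > 0` / milder `D < 0`) crossed with the
#' within-subject confidence median split, mean absolute judgment change by
#' confidence half, mean `|D|` overall and by group size, mean level of
#' conformity by group size, and the mean confidence on both the model
#' scale (`C` in `[-1, 1]`) and the 0--1 reporting scale.
#'
#' @param trials A trial table (one or more subjects); rows without `J2`
#'   are ignored.
#' @return An object of class `conformity_summary` with elements `pooled`
#'   (a named list) and `by_subject` (a data frame).
#' @export
conformity_summary <- function(trials) {
  if (is.null(trials$subject_id)) trials$subject_id <- "S01"
  tv <- trials[trials$revision_allowed & !is.na(trials$J2), , drop = FALSE]
  if (nrow(tv) == 0L) stop("no valid trials with J2 present")
  tv$LC <- level_of_conformity(tv$J1, tv$J2, tv$JS)
  tv$conformity <- classify_conformity(tv$LC)
  tv$D <- tv$JS - tv$J1
  tv$conf_half <- NA_character_
  for (s in unique(tv$subject_id)) {
    idx <- tv$subject_id == s
    tv$conf_half[idx] <- median_split_confidence(tv$C[idx])
  }
  mean_in <- function(cond, x) if (any(cond)) mean(x[cond]) else NA_real_
  pooled <- list(
    n_valid = nrow(tv),
    mean_LC = mean(tv$LC),
    n_conformity = sum(tv$conformity == "conformity"),
    n_nonconformity = sum(tv$conformity == "nonconformity"),
    mean_J2_severer_low = mean_in(tv$D > 0 & tv$conf_half == "low", tv$J2),
    mean_J2_severer_high = mean_in(tv$D > 0 & tv$conf_half == "high", tv$J2),
    mean_J2_milder_low = mean_in(tv$D < 0 & tv$conf_half == "low", tv$J2),
    mean_J2_milder_high = mean_in(tv$D < 0 & tv$conf_half == "high", tv$J2),
    mean_abs_change_low = mean_in(tv$conf_half == "low", abs(tv$J2 - tv$J1)),
    mean_abs_change_high = mean_in(tv$conf_half == "high",
                                   abs(tv$J2 - tv$J1)),
    mean_abs_D = mean(abs(tv$D)),
    mean_abs_D_small = mean_in(tv$G == 0, abs(tv$D)),
    mean_abs_D_large = mean_in(tv$G == 1, abs(tv$D)),
    mean_LC_small = mean_in(tv$G == 0, tv$LC),
    mean_LC_large = mean_in(tv$G == 1, tv$LC),
    mean_confidence_C = mean(tv$C),
    mean_confidence_01 = mean((tv$C + 1) / 2)
  )
  by_subject <- do.call(rbind, lapply(unique(tv$subject_id), function(s) {
    ts <- tv[tv$subject_id == s, , drop = FALSE]
    data.frame(
      subject_id = s,
      n_valid = nrow(ts),
      mean_LC = mean(ts$LC),
      n_conformity = sum(ts$conformity == "conformity"),
      n_nonconformity = sum(ts$conformity == "nonconformity"),
      mean_abs_D = mean(abs(ts$D)),
      mean_LC_small = mean_in(ts$G == 0, ts$LC),
      mean_LC_large = mean_in(ts$G == 1, ts$LC),
      mean_confidence_C = mean(ts$C),
      mean_confidence_01 = mean((ts$C + 1) / 2)
    )
  }))
  structure(list(pooled = pooled, by_subject = by_subject,
                 trials = tv[, c("subject_id", "trial_index", "LC",
                                 "conformity", "conf_half")]),
            class = "conformity_summary")
}

#' @export
print.conformity_summary <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<conformity_summary> %d valid trials, %d subjects\n",
              p$n_valid, nrow(x$by_subject)))
  cat(sprintf("  mean LC = %.3f (%d conformity / %d nonconformity trials)\n",
              p$mean_LC, p$n_conformity, p$n_nonconformity))
  cat(sprintf("  mean |D| = %.2f (small %.2f, large %.2f)\n",
              p$mean_abs_D, p$mean_abs_D_small, p$mean_abs_D_large))
  cat(sprintf("  mean LC by group size: small %.3f, large %.3f\n",
              p$mean_LC_small, p$mean_LC_large))
  invisible(x)
}
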