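#' Likelihood of a candidate series explaining a reference series
#'
#' Generic single-coefficient series comparison: the reference series is
#' modelled as `eta * candidate + error`, with `eta` and the error variance
#' profiled exactly as in [profile_scale()], scored by the deviance of
#' [neg2_log_likelihood()], and penalized with BIC at `k = 1` (the single
#' coefficient). Candidates are mean-centered by default, since the model
#' has no intercept.
#'
#' @param reference Numeric reference series (e.g. a region-of-interest
#'   beta series), length >= 2.
#' @param candidate Candidate prediction series of the same length.
#' @param center Mean-center the candidate before fitting (default `TRUE`).
#' @param eps2_floor Lower bound on the profiled error variance.
#' @return A list with `eta`, `eps2`, `neg2ll` and `bic`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50)
#' series_neg2ll(2 * x + rnorm(50, 0, 0.1), x)
#' @export
series_neg2ll <- function(reference, candidate, center = TRUE,
                          eps2_floor = 1e-6) {
  if (length(reference) != length(candidate)) {
    stop("reference and candidate must have equal length")
  }
  if (length(reference) < 2L) stop("series must have length >= 2")
  if (!all(is.finite(reference)) || !all(is.finite(candidate))) {
    stop("series must be finite")
  }
  if (center) candidate <- candidate - mean(candidate)
  ps <- profile_scale(reference, candidate, eps2_floor)
  n2 <- neg2_log_likelihood(reference, candidate, ps$eta, ps$eps2,
                            eps2_floor)
  list(eta = ps$eta, eps2 = ps$eps2, neg2ll = n2,
       bic = bic(n2, 1L, length(reference)))
}

#' Rank candidate series by BIC against a reference
#'
#' Scores each candidate with [series_neg2ll()] and returns the comparison
#' table sorted by ascending BIC; exact ties keep the input order.
#'
#' @param reference Numeric reference series.
#' @param candidates A (preferably named) list of candidate series, all of
#'   the same length as the reference.
#' @inheritParams series_neg2ll
#' @return A data frame with columns `label`, `eta`, `eps2`, `neg2ll`,
#'   `bic`, `rank`.
#' @export
rank_candidates <- function(reference, candidates, center = TRUE,
                            eps2_floor = 1e-6) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  labels <- names(candidates)
  if (is.null(labels)) labels <- paste0("candidate", seq_along(candidates))
  rows <- lapply(seq_along(candidates), function(i) {
    sc <- series_neg2ll(reference, candidates[[i]], center = center,
                        eps2_floor = eps2_floor)
    data.frame(label = labels[i], eta = sc$eta, eps2 = sc$eps2,
               neg2ll = sc$neg2ll, bic = sc$bic)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$bic), , drop = FALSE]  # stable: ties keep input order
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
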