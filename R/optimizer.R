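#' Iteratively optimize interrater agreement by excluding discordant raters
#'
#' Runs the circular identification-and-exclusion loop on one feature's panel.
#' Round 1 always runs: a first leave-one-out identification is performed on
#' every panel regardless of its starting reliability. Each round runs
#' [leave_one_out()] on the current panel, excludes every rater flagged
#' discordant in one batch, and recomputes the panel AC1. The loop continues
#' while the recomputed reliability stays at or below `threshold`, new
#' discordant raters keep being found, the panel stays at or above
#' `min_raters`, and fewer than `max_rounds` rounds have run. Reaching
#' `r_after > threshold` (the strict "substantial" cut) stops with
#' `converged = TRUE`; exhaustion of discordant raters below the threshold is
#' a valid non-converged outcome.
#'
#' A round whose batch exclusion would shrink the panel below `min_raters` is
#' not executed; the loop stops with the panel unchanged.
#'
#' @param ratings a [ratings_matrix()] with at least `min_raters` raters.
#' @param threshold convergence cut-point on AC1 (default 0.6, the lower edge
#'   of the "substantial" benchmark band).
#' @param min_raters smallest admissible panel (default 3; leave-one-out
#'   needs the remaining panel to hold >= 2 raters).
#' @param max_rounds safety cap on executed rounds.
#' @param ci_multiplier passed to [leave_one_out()].
#' @return an [optimization_trace()].
#' @export
optimize_agreement <- function(ratings, threshold = 0.6, min_raters = 3,
                               max_rounds = 50, ci_multiplier = 2) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  if (min_raters < 3) stop("min_raters must be >= 3")
  if (n_raters(ratings) < min_raters)
    stop("panel smaller than min_raters")
  current <- ratings
  r_initial <- gwet_ac1(ratings)$coefficient
  rounds <- list()
  t <- 0L
  repeat {
    t <- t + 1L
    loo <- leave_one_out(current, ci_multiplier = ci_multiplier)
    disc <- loo$rater_id[loo$discordant]
    if (length(disc) == 0) break
    if (n_raters(current) - length(disc) < min_raters) break
    current <- drop_raters(current, disc)
    r_after <- gwet_ac1(current)$coefficient
    rounds[[t]] <- recognition_round(t, disc, n_raters(current), r_after)
    if (r_after > threshold) break
    if (t >= max_rounds) break
    if (n_raters(current) - 1 < min_raters) break  # next exclusion impossible
  }
  optimization_trace(ratings$feature_id, r_initial, rounds,
                     threshold = threshold, n_raters = n_raters(ratings))
}

#' Optimize every feature of a panel independently
#'
#' @param features list of [ratings_matrix()] objects (one per feature).
#' @param ... passed to [optimize_agreement()].
#' @return a list of [optimization_trace()] objects, one per feature that
#'   optimized without error; per-feature errors are collected (not fatal) in
#'   the `"errors"` attribute, a named character vector.
#' @seealso [optimization_summary()] for the per-feature results table.
#' @export
optimize_all <- function(features, ...) {
  if (length(features) == 0) stop("no features supplied")
  errors <- character(0)
  traces <- list()
  for (rm in features) {
    tr <- tryCatch(optimize_agreement(rm, ...), error = function(e) e)
    if (inherits(tr, "error")) {
      errors[rm$feature_id] <- conditionMessage(tr)
    } else {
      traces[[rm$feature_id]] <- tr
    }
  }
  attr(traces, "errors") <- errors
  traces
}

#' Per-feature optimization summary table
#'
#' One row per trace: recognition rounds run, raters remaining, and the
#' interrater agreement before and after optimization.
#'
#' @param traces list of [optimization_trace()] objects.
#' @return data.frame with columns `feature_id`, `recognition_times`,
#'   `rest_raters`, `r_before`, `r_after`, `converged`.
#' @export
optimization_summary <- function(traces) {
  rows <- lapply(traces, function(tr) {
    m <- length(tr$rounds)
    data.frame(feature_id = tr$feature_id,
               recognition_times = m,
               rest_raters = if (m > 0) tr$rounds[[m]]$n_remaining else tr$n_raters,
               r_before = tr$r_initial,
               r_after = tr$r_final,
               converged = tr$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
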