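#' Recognition round record
#'
#' One pass of leave-one-out detection followed by batch exclusion of every
#' discordant rater found in that pass.
#'
#' @param round_index 1-based round number.
#' @param identified_raters non-empty character vector of excluded rater ids.
#' @param n_remaining panel size after the exclusion.
#' @param r_after AC1 of the remaining panel.
#' @export
recognition_round <- function(round_index, identified_raters, n_remaining, r_after) {
  if (length(identified_raters) == 0)
    stop("a recorded round must identify at least one rater")
  structure(list(round_index = as.integer(round_index),
                 identified_raters = as.character(identified_raters),
                 n_remaining = as.integer(n_remaining),
                 r_after = as.numeric(r_after)),
            class = "recognition_round")
}

#' Optimization trace
#'
#' Full history of the circular identification-and-exclusion loop for one
#' feature: the initial panel reliability, every executed round, and whether
#' the final reliability exceeds the "substantial" threshold.
#'
#' @param feature_id feature label.
#' @param r_initial AC1 of the full panel before any exclusion.
#' @param rounds list of [recognition_round()] objects in execution order.
#' @param threshold convergence cut-point (default benchmark 0.6).
#' @param n_raters size of the original panel (before round 1).
#' @return an object of class `optimization_trace` with derived fields
#'   `r_final` (last round's `r_after`, or `r_initial` when no round was
#'   recorded) and `converged` (`r_final > threshold`, strict).
#' @export
optimization_trace <- function(feature_id, r_initial, rounds, threshold = 0.6,
                               n_raters = NA_integer_) {
  rounds <- unname(rounds)
  if (length(rounds) > 0) {
    idx <- vapply(rounds, function(r) r$round_index, integer(1))
    if (!identical(idx, seq_along(rounds)))
      stop("round indices must be 1..m in order")
    rem <- vapply(rounds, function(r) r$n_remaining, integer(1))
    if (any(diff(rem) >= 0) ||
        (!is.na(n_raters) && rem[1] >= n_raters))
      stop("n_remaining must strictly decrease across rounds")
  }
  r_final <- if (length(rounds) > 0) rounds[[length(rounds)]]$r_after else r_initial
  structure(list(feature_id = as.character(feature_id)[1],
                 r_initial = as.numeric(r_initial),
                 rounds = rounds,
                 r_final = as.numeric(r_final),
                 converged = r_final > threshold,
                 threshold = as.numeric(threshold),
                 n_raters = as.integer(n_raters)),
            class = "optimization_trace")
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("<optimization_trace> feature '%s': AC1 %.4f -> %.4f over %d round(s), %s (threshold %.2f)\n",
              x$feature_id, x$r_initial, x$r_final, length(x$rounds),
              if (x$converged) "converged" else "not converged", x$threshold))
  for (r in x$rounds)
    cat(sprintf("  round %d: excluded %d (%s), %d remain, AC1 = %.4f\n",
                r$round_index, length(r$identified_raters),
                paste(r$identified_raters, collapse = ", "),
                r$n_remaining, r$r_after))
  invisible(x)
}

#' Total raters excluded by a trace
#' @param trace an [optimization_trace()].
#' @export
excluded_raters <- function(trace) {
  unlist(lapply(trace$rounds, function(r) r$identified_raters), use.names = FALSE)
}

#' Serialize an optimization trace to JSON
#'
#' The file round-trips losslessly through [read_trace()].
#'
#' @param trace an [optimization_trace()].
#' @param path output file path.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "optimization_trace")) stop("expected an optimization_trace")
  x <- list(
    feature_id = trace$feature_id,
    r_initial = trace$r_initial,
    threshold = trace$threshold,
    n_raters = trace$n_raters,
    r_final = trace$r_final,
    converged = trace$converged,
    rounds = lapply(trace$rounds, function(r)
      list(round_index = r$round_index,
           identified_raters = as.list(r$identified_raters),
           n_remaining = r$n_remaining,
           r_after = r$r_after)))
  # digits = I(17): doubles must survive the text round-trip bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rounds <- lapply(x$rounds, function(r)
    recognition_round(r$round_index,
                      unlist(r$identified_raters, use.names = FALSE),
                      r$n_remaining, r$r_after))
  tr <- optimization_trace(x$feature_id, x$r_initial, rounds,
                           threshold = x$threshold,
                           n_raters = if (is.null(x$n_raters)) NA_integer_ else x$n_raters)
  if (abs(tr$r_final - x$r_final) > 1e-9 || !identical(tr$converged, x$converged))
    stop("trace file is internally inconsistent: ", path)
  tr
}
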