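#' Disagreement scores from an optimization trace
#'
#' Converts a feature's trace into the per-rater external-consistency score:
#' with `m` recognition rounds in total, a rater first excluded in round `t`
#' scores `m - t + 1` (so round-1 raters — the most discordant — score `m`,
#' and raters caught only in the final round score 1); every never-excluded
#' rater scores 0. A higher score means earlier, stronger disagreement with
#' the rest of the panel.
#'
#' @param trace an [optimization_trace()].
#' @param all_raters character vector: the full original rater universe. Every
#'   rater the trace excludes must be a member.
#' @return an object of class `disagreement_scores`: list with `feature_id`,
#'   `m` (rounds), and `scores`, a named non-negative integer vector covering
#'   every rater in `all_raters` exactly once (in that order).
#' @export
disagreement_scores <- function(trace, all_raters) {
  all_raters <- as.character(all_raters)
  if (anyDuplicated(all_raters)) stop("duplicated ids in all_raters")
  m <- length(trace$rounds)
  excl <- excluded_raters(trace)
  if (anyDuplicated(excl))
    stop("a rater appears in more than one round; exclusion semantics violated")
  unknown <- setdiff(excl, all_raters)
  if (length(unknown) > 0)
    stop("trace excludes raters outside the universe: ",
         paste(unknown, collapse = ", "))
  scores <- stats::setNames(integer(length(all_raters)), all_raters)
  for (r in trace$rounds)
    scores[r$identified_raters] <- m - r$round_index + 1L
  structure(list(feature_id = trace$feature_id, m = m, scores = scores),
            class = "disagreement_scores")
}

#' @export
print.disagreement_scores <- function(x, ...) {
  cat(sprintf("<disagreement_scores> feature '%s': m = %d rounds, %d of %d raters scored > 0\n",
              x$feature_id, x$m, sum(x$scores > 0), length(x$scores)))
  invisible(x)
}

#' Aggregate disagreement scores across features
#'
#' @param tables list of [disagreement_scores()] objects sharing one rater
#'   universe.
#' @param method `"mean"`, `"sum"`, or `"max"` across features.
#' @return named numeric vector, one aggregate per rater.
#' @export
aggregate_scores <- function(tables, method = c("mean", "sum", "max")) {
  method <- match.arg(method)
  if (length(tables) == 0) stop("no score tables supplied")
  universe <- names(tables[[1]]$scores)
  for (tb in tables)
    if (!setequal(names(tb$scores), universe))
      stop("score tables have inconsistent rater universes")
  M <- vapply(tables, function(tb) tb$scores[universe], numeric(length(universe)))
  M <- matrix(M, nrow = length(universe), dimnames = list(universe, NULL))
  fn <- switch(method, mean = rowMeans,
               sum = rowSums,
               max = function(x) apply(x, 1, max))
  fn(M)
}

#' Write per-feature disagreement scores to CSV
#'
#' Rows are raters, one column per feature, plus an `aggregate` column.
#'
#' @inheritParams aggregate_scores
#' @param path output CSV path.
#' @export
write_scores_csv <- function(tables, path, method = "mean") {
  agg <- aggregate_scores(tables, method = method)
  universe <- names(agg)
  df <- data.frame(rater_id = universe, stringsAsFactors = FALSE)
  for (tb in tables) df[[tb$feature_id]] <- unname(tb$scores[universe])
  df$aggregate <- unname(agg)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
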