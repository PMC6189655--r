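#' Select raters by internal and/or external consistency
#'
#' Implements the three panel-curation policies, per feature:
#' * **A** — internal consistency: keep raters whose intrarater agreement is
#'   strictly above `intra_threshold` ("substantial" self-agreement).
#' * **B** — external consistency: keep raters whose disagreement score for
#'   that feature is exactly 0 (never excluded by the optimizer).
#' * **C** — both: the intersection of A and B.
#'
#' @param intra data.frame of intrarater estimates with columns `feature_id`,
#'   `rater_id`, `coefficient` (see [intrarater_all()]); required for methods
#'   A and C.
#' @param scores list of [disagreement_scores()] tables (one per feature);
#'   required for methods B and C.
#' @param method `"A"`, `"B"`, or `"C"`.
#' @param intra_threshold strict lower cut on intrarater agreement
#'   (default 0.6).
#' @return named list mapping feature_id to the character vector of selected
#'   rater ids. Features selecting no rater map to `character(0)` with a
#'   warning (they are unestimable downstream).
#' @export
select_experts <- function(intra = NULL, scores = NULL,
                           method = c("A", "B", "C"), intra_threshold = 0.6) {
  method <- match.arg(method)
  need_intra <- method %in% c("A", "C")
  need_scores <- method %in% c("B", "C")
  if (need_intra && is.null(intra))
    stop("method ", method, " needs intrarater estimates")
  if (need_scores && is.null(scores))
    stop("method ", method, " needs disagreement score tables")
  score_map <- NULL
  if (need_scores) {
    score_map <- stats::setNames(scores, vapply(scores, function(s) s$feature_id, ""))
  }
  feats <- if (method == "A") unique(intra$feature_id)
           else if (method == "B") names(score_map)
           else intersect(unique(intra$feature_id), names(score_map))
  if (length(feats) == 0) stop("no feature covered by the supplied inputs")
  out <- lapply(feats, function(f) {
    sel_a <- sel_b <- NULL
    if (need_intra) {
      sub <- intra[intra$feature_id == f, , drop = FALSE]
      sel_a <- sub$rater_id[!is.na(sub$coefficient) & sub$coefficient > intra_threshold]
    }
    if (need_scores) {
      sc <- score_map[[f]]$scores
      sel_b <- names(sc)[sc == 0]
    }
    switch(method, A = sel_a, B = sel_b, C = intersect(sel_a, sel_b))
  })
  names(out) <- feats
  empty <- feats[vapply(out, length, 0L) == 0]
  if (length(empty) > 0)
    warning("no rater selected for feature(s): ", paste(empty, collapse = ", "))
  out
}

#' Evaluate a rater selection over a panel
#'
#' Recomputes Gwet's AC1 per feature on the selected subset of raters and
#' summarizes the per-feature coefficients as median and interquartile range
#' (the field's conventional report for skewed agreement distributions).
#' Features whose subset holds fewer than two raters are unestimable and
#' dropped from the summary with a warning.
#'
#' @param features list of [ratings_matrix()] objects; ratings should already
#'   be restricted to the single-presentation (nontesting) items.
#' @param subsets named list mapping feature_id to selected rater ids, e.g.
#'   from [select_experts()]. Features absent from `subsets` are skipped.
#' @param method label stored on the outcome (e.g. `"original"`, `"A"`).
#' @return an object of class `selection_outcome`: list with `method`,
#'   `per_feature` (feature_id -> list(raters, estimate)), `coefficients`
#'   (named numeric), `summary_median`, `summary_iqr` (25th, 75th
#'   percentiles).
#' @export
evaluate_selection <- function(features, subsets, method = "selection") {
  names(features) <- vapply(features, function(x) x$feature_id, "")
  per_feature <- list()
  dropped <- character(0)
  for (f in intersect(names(features), names(subsets))) {
    sel <- subsets[[f]]
    if (length(sel) < 2) { dropped <- c(dropped, f); next }
    est <- gwet_ac1(keep_raters(features[[f]], sel))
    per_feature[[f]] <- list(raters = sel, estimate = est)
  }
  if (length(dropped) > 0)
    warning("feature(s) unestimable (<2 selected raters): ",
            paste(dropped, collapse = ", "))
  if (length(per_feature) == 0) stop("no feature is estimable under this selection")
  coefs <- vapply(per_feature, function(p) p$estimate$coefficient, numeric(1))
  structure(list(method = method,
                 per_feature = per_feature,
                 coefficients = coefs,
                 summary_median = stats::median(coefs),
                 summary_iqr = unname(stats::quantile(coefs, c(0.25, 0.75)))),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("<selection_outcome> method %s: median AC1 %.2f [%.2f-%.2f] over %d feature(s)\n",
              x$method, x$summary_median, x$summary_iqr[1], x$summary_iqr[2],
              length(x$coefficients)))
  invisible(x)
}

#' Compare per-feature agreement distributions across selection methods
#'
#' Each outcome contributes its vector of per-feature coefficients as one
#' group. Group normality is checked with the Shapiro-Wilk test at
#' `normality_alpha`; when every group passes, the parametric path runs a
#' heteroscedastic (Welch) one-way omnibus test with Dunnett-T3-style
#' pairwise comparisons (pairwise Welch t tests, Sidak-adjusted); otherwise
#' the rank path runs a Kruskal-Wallis omnibus test with Dunn post hoc
#' pairwise z tests under Bonferroni adjustment. Groups with zero variance
#' everywhere make the comparison undefined and are flagged rather than
#' tested.
#'
#' @param outcomes list of [evaluate_selection()] outcomes (>= 2, each with
#'   >= 2 features).
#' @param normality_alpha alpha for the Shapiro-Wilk gate.
#' @param alpha significance level for the pairwise flags.
#' @return an object of class `method_comparison`: list with `path`
#'   (`"anova_dunnett_t3"`, `"kruskal_dunn"`, or `"undefined"`), `normality`
#'   (per-group p-values), `omnibus` (statistic, p_value, method), `pairwise`
#'   data.frame (`group1`, `group2`, `statistic`, `p_value`, `p_adjusted`,
#'   `significant`), and `alpha`.
#' @export
compare_methods <- function(outcomes, normality_alpha = 0.05, alpha = 0.05) {
  if (length(outcomes) < 2) stop("need >= 2 outcomes to compare")
  groups <- lapply(outcomes, function(o) unname(o$coefficients))
  names(groups) <- vapply(outcomes, function(o) o$method, "")
  if (anyDuplicated(names(groups))) stop("duplicated method labels")
  if (any(vapply(groups, length, 0L) < 2))
    stop("every outcome needs >= 2 per-feature coefficients")
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    return(structure(list(path = "undefined", normality = NULL, omnibus = NULL,
                          pairwise = NULL, alpha = alpha,
                          note = "all groups have zero variance; comparison undefined"),
                     class = "method_comparison"))
  }
  norm_p <- vapply(groups, function(g) {
    if (stats::var(g) == 0 || length(g) < 3) return(0)  # constant/tiny: treat as non-normal
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  if (all(norm_p > normality_alpha)) {
    path <- "anova_dunnett_t3"
    ow <- stats::oneway.test(values ~ group, data = .stack_groups(groups),
                             var.equal = FALSE)
    omnibus <- list(statistic = unname(ow$statistic), p_value = ow$p.value,
                    method = "Welch one-way ANOVA")
    pw <- apply(pairs, 2, function(p) {
      x <- groups[[p[1]]]; y <- groups[[p[2]]]
      tt <- stats::t.test(x, y, var.equal = FALSE)
      c(statistic = unname(tt$statistic), p_value = tt$p.value)
    })
    p_adj <- pmin(1, 1 - (1 - pw["p_value", ])^n_pairs)  # Sidak-type, T3 family
  } else {
    path <- "kruskal_dunn"
    stacked <- .stack_groups(groups)
    kw <- stats::kruskal.test(values ~ group, data = stacked)
    omnibus <- list(statistic = unname(kw$statistic), p_value = kw$p.value,
                    method = "Kruskal-Wallis rank sum test")
    dz <- .dunn_z(groups)
    pw <- rbind(statistic = dz, p_value = 2 * stats::pnorm(-abs(dz)))
    p_adj <- pmin(1, pw["p_value", ] * n_pairs)  # Bonferroni
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         statistic = unname(pw["statistic", ]),
                         p_value = unname(pw["p_value", ]),
                         p_adjusted = unname(p_adj),
                         stringsAsFactors = FALSE)
  pairwise$significant <- pairwise$p_adjusted < alpha
  structure(list(path = path, normality = norm_p, omnibus = omnibus,
                 pairwise = pairwise, alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> path: %s\n", x$path))
  if (x$path == "undefined") { cat("  ", x$note, "\n"); return(invisible(x)) }
  cat(sprintf("  omnibus %s: statistic %.3f, p = %.4g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

.stack_groups <- function(groups) {
  data.frame(values = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups))))
}

# Dunn post hoc z statistics from pooled mean ranks with tie correction
.dunn_z <- function(groups) {
  stacked <- .stack_groups(groups)
  N <- nrow(stacked)
  rk <- rank(stacked$values)
  mean_rank <- tapply(rk, stacked$group, mean)
  n_g <- tapply(rk, stacked$group, length)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  apply(pairs, 2, function(p) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[p[1]] + 1 / n_g[p[2]]))
    unname((mean_rank[p[1]] - mean_rank[p[2]]) / se)
  })
}
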