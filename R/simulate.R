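#' Configuration for the synthetic rating-panel generator
#'
#' Defaults mirror the motivating study design: 50 experts rating 230
#' single-presentation (nontesting) binary items per feature, 35 further
#' items repeated twice for intrarater assessment, and 25 features. The
#' generative model is latent truth plus independent rater error: each item
#' carries a latent binary truth drawn at the feature's prevalence; a rater
#' reports the truth with their accuracy, otherwise errs. A discordant
#' profile plants raters whose accuracy is lower and whose errors may be
#' biased toward category `"1"`.
#'
#' @param n_raters panel size (default 50).
#' @param n_items nontesting items per feature (default 230).
#' @param n_repeat_items items repeated twice per rater (default 35).
#' @param n_features number of features (default 25).
#' @param prevalence per-feature probability of latent truth `"1"`; scalar
#'   (recycled) or length `n_features`. Default spreads features evenly over
#'   `[0.2, 0.8]`, covering rare through common findings.
#' @param good_rater_accuracy P(report truth) for unplanted raters
#'   (default 0.9).
#' @param discordant_profiles list of profiles, each a list with `count`,
#'   `accuracy`, and optional `bias` (probability an erroneous report is
#'   category `"1"`; `NULL` = symmetric error, i.e. report the complement).
#'   Default: one profile of 10 raters at accuracy 0.55.
#' @param replicate_flip_prob probability a second-occasion rating flips the
#'   first; scalar or length `n_raters` (default 0.1).
#' @param seed integer seed governing all randomness.
#' @return a validated list of class `panel_config`.
#' @export
panel_config <- function(n_raters = 50, n_items = 230, n_repeat_items = 35,
                         n_features = 25, prevalence = NULL,
                         good_rater_accuracy = 0.9,
                         discordant_profiles = list(list(count = 10, accuracy = 0.55, bias = NULL)),
                         replicate_flip_prob = 0.1, seed = 1) {
  if (n_raters < 2 || n_items < 1 || n_features < 1 || n_repeat_items < 0)
    stop("invalid panel dimensions")
  if (is.null(prevalence))
    prevalence <- if (n_features == 1) 0.5 else seq(0.2, 0.8, length.out = n_features)
  prevalence <- rep_len(prevalence, n_features)
  probs <- c(prevalence, good_rater_accuracy, replicate_flip_prob,
             unlist(lapply(discordant_profiles, function(p) c(p$accuracy, p$bias))))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (any(prevalence <= 0 | prevalence >= 1)) stop("prevalence must lie in (0, 1)")
  counts <- vapply(discordant_profiles, function(p) as.integer(p$count), integer(1))
  if (sum(counts) > n_raters)
    stop("discordant profile counts exceed the panel size")
  structure(list(n_raters = as.integer(n_raters), n_items = as.integer(n_items),
                 n_repeat_items = as.integer(n_repeat_items),
                 n_features = as.integer(n_features), prevalence = prevalence,
                 good_rater_accuracy = good_rater_accuracy,
                 discordant_profiles = discordant_profiles,
                 replicate_flip_prob = rep_len(replicate_flip_prob, n_raters),
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Generate a synthetic rating panel with known ground truth
#'
#' Fully seeded and reproducible: the same config (including seed) yields a
#' bit-identical panel. Categories are coded `"0"`/`"1"` (absent/present).
#' Nontesting items populate the per-feature ratings matrices; the repeated
#' items appear only in the replicate tables (occasion 2 equals occasion 1
#' flipped independently with the rater's `replicate_flip_prob`).
#'
#' @param config a [panel_config()].
#' @return list of class `rating_panel` with elements
#'   * `ratings` — named list of [ratings_matrix()] (nontesting items only),
#'   * `replicates` — list of [replicate_table()] (one per feature x rater),
#'   * `truth` — `ground_truth`: per-feature latent item truths, the planted
#'     discordant rater ids, and the per-rater accuracy map.
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "panel_config")) stop("expected a panel_config")
  set.seed(config$seed)
  n <- config$n_raters
  raters <- sprintf("rater %d", seq_len(n))
  acc <- rep(config$good_rater_accuracy, n)
  bias <- rep(NA_real_, n)
  discordant <- character(0)
  pool <- sample.int(n)
  idx <- 1L
  for (prof in config$discordant_profiles) {
    cnt <- as.integer(prof$count)
    if (cnt == 0) next
    take <- pool[idx:(idx + cnt - 1L)]
    idx <- idx + cnt
    acc[take] <- prof$accuracy
    bias[take] <- if (is.null(prof$bias)) NA_real_ else prof$bias
    discordant <- c(discordant, raters[take])
  }
  item_ids <- sprintf("img%03d", seq_len(config$n_items))
  rep_ids <- if (config$n_repeat_items > 0)
    sprintf("rep%02d", seq_len(config$n_repeat_items)) else character(0)
  feats <- sprintf("feature_%02d", seq_len(config$n_features))
  ratings <- list()
  replicates <- list()
  truths <- list()
  n_tot <- config$n_items + config$n_repeat_items
  for (f in seq_len(config$n_features)) {
    z <- stats::rbinom(n_tot, 1, config$prevalence[f])
    grid <- matrix(NA_integer_, n_tot, n)
    for (j in seq_len(n)) {
      correct <- stats::rbinom(n_tot, 1, acc[j]) == 1
      err <- if (is.na(bias[j])) 1L - z else stats::rbinom(n_tot, 1, bias[j])
      grid[, j] <- ifelse(correct, z, err)
    }
    m <- matrix(as.character(grid[seq_len(config$n_items), , drop = FALSE]),
                config$n_items, n, dimnames = list(item_ids, raters))
    ratings[[feats[f]]] <- ratings_matrix(m, feature_id = feats[f],
                                          categories = c("0", "1"))
    if (config$n_repeat_items > 0) {
      rep_rows <- config$n_items + seq_len(config$n_repeat_items)
      for (j in seq_len(n)) {
        o1 <- grid[rep_rows, j]
        flips <- stats::rbinom(config$n_repeat_items, 1, config$replicate_flip_prob[j]) == 1
        o2 <- ifelse(flips, 1L - o1, o1)
        replicates[[length(replicates) + 1L]] <-
          replicate_table(feats[f], raters[j], rep_ids,
                          as.character(o1), as.character(o2))
      }
    }
    truths[[feats[f]]] <- stats::setNames(z[seq_len(config$n_items)], item_ids)
  }
  truth <- structure(list(item_truth = truths,
                          discordant = discordant,
                          accuracy = stats::setNames(acc, raters)),
                     class = "ground_truth")
  structure(list(ratings = ratings, replicates = replicates, truth = truth),
            class = "rating_panel")
}

#' Sensitivity and specificity of discordant-rater recovery
#'
#' @param detected character vector of rater ids flagged/excluded by the
#'   pipeline; must be a subset of the panel's rater universe.
#' @param truth the `ground_truth` element of [generate_panel()] output.
#' @return list with `sensitivity` (fraction of planted discordant raters
#'   detected; `NA` when none were planted) and `specificity` (fraction of
#'   unplanted raters left alone).
#' @export
recovery_metrics <- function(detected, truth) {
  universe <- names(truth$accuracy)
  unknown <- setdiff(detected, universe)
  if (length(unknown) > 0)
    stop("detected ids outside the rater universe: ", paste(unknown, collapse = ", "))
  disc <- truth$discordant
  non_disc <- setdiff(universe, disc)
  sens <- if (length(disc) == 0) NA_real_
          else length(intersect(detected, disc)) / length(disc)
  spec <- if (length(non_disc) == 0) NA_real_
          else length(setdiff(non_disc, detected)) / length(non_disc)
  list(sensitivity = sens, specificity = spec)
}
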