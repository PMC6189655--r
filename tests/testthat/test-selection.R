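# small hand-built inputs: two features, four raters
mk_scores <- function(f, sc) structure(list(feature_id = f, m = max(c(sc, 0L)),
                                            scores = sc), class = "disagreement_scores")

test_that("the three policies apply their definitions per feature", {
  intra <- data.frame(feature_id = "f1",
                      rater_id = c("r1", "r2", "r3", "r4"),
                      coefficient = c(0.65, 0.9, 0.4, 0.6))
  scores <- list(mk_scores("f1", c(r1 = 2L, r2 = 0L, r3 = 0L, r4 = 0L)))
  a <- select_experts(intra = intra, method = "A")
  b <- select_experts(scores = scores, method = "B")
  cc <- select_experts(intra = intra, scores = scores, method = "C")
  # r1: substantial self-agreement but a positive disagreement score
  expect_true("r1" %in% a$f1)
  expect_false("r1" %in% b$f1)
  expect_false("r1" %in% cc$f1)
  # the 0.6 cut is strict: r4 at exactly 0.6 is out of A
  expect_setequal(a$f1, c("r1", "r2"))
  expect_setequal(b$f1, c("r2", "r3", "r4"))
  expect_setequal(cc$f1, "r2")
  expect_error(select_experts(intra = intra, method = "B"), "needs disagreement")
  expect_error(select_experts(scores = scores, method = "A"), "needs intrarater")
})

test_that("perfect raters are kept by every policy; C is always the intersection", {
  intra <- data.frame(feature_id = rep(c("f1", "f2"), each = 3),
                      rater_id = rep(c("r1", "r2", "r3"), 2),
                      coefficient = 1)
  scores <- list(mk_scores("f1", c(r1 = 0L, r2 = 0L, r3 = 0L)),
                 mk_scores("f2", c(r1 = 0L, r2 = 0L, r3 = 0L)))
  for (m in c("A", "B", "C"))
    expect_true(all(vapply(select_experts(intra, scores, m),
                           function(x) setequal(x, c("r1", "r2", "r3")), logical(1))))
})

test_that("C equals A intersect B on a simulated panel, feature by feature", {
  cfg <- panel_config(n_raters = 12, n_items = 40, n_repeat_items = 12,
                      n_features = 4,
                      discordant_profiles = list(list(count = 3, accuracy = 0.55, bias = NULL)),
                      replicate_flip_prob = rep(c(0.05, 0.45), length.out = 12),
                      seed = 77)
  pan <- generate_panel(cfg)
  traces <- optimize_all(pan$ratings)
  scores <- lapply(traces, disagreement_scores,
                   all_raters = rater_ids(pan$ratings[[1]]))
  intra <- intrarater_all(pan$replicates)
  a <- suppressWarnings(select_experts(intra, scores, "A"))
  b <- suppressWarnings(select_experts(intra, scores, "B"))
  cc <- suppressWarnings(select_experts(intra, scores, "C"))
  for (f in names(cc)) {
    expect_setequal(cc[[f]], intersect(a[[f]], b[[f]]))
    expect_true(all(cc[[f]] %in% a[[f]]))   # nesting
    expect_true(all(cc[[f]] %in% b[[f]]))
  }
})

test_that("evaluating the identity selection reproduces the per-feature estimates", {
  cfg <- panel_config(n_raters = 8, n_items = 30, n_repeat_items = 0,
                      n_features = 3, discordant_profiles = list(), seed = 5)
  pan <- generate_panel(cfg)
  full <- lapply(pan$ratings, rater_ids)
  out <- evaluate_selection(pan$ratings, full, method = "original")
  for (f in names(pan$ratings))
    expect_equal(out$coefficients[[f]], gwet_ac1(pan$ratings[[f]])$coefficient)
  # single-feature input: degenerate summary
  one <- evaluate_selection(pan$ratings[1], full[1], method = "single")
  expect_equal(one$summary_median, one$coefficients[[1]])
  expect_equal(one$summary_iqr, rep(one$coefficients[[1]], 2))
})

test_that("features with under two selected raters are dropped, not imputed", {
  cfg <- panel_config(n_raters = 6, n_items = 20, n_repeat_items = 0,
                      n_features = 2, discordant_profiles = list(), seed = 8)
  pan <- generate_panel(cfg)
  subsets <- list(feature_01 = rater_ids(pan$ratings[[1]]),
                  feature_02 = "rater 1")
  expect_warning(out <- evaluate_selection(pan$ratings, subsets), "unestimable")
  expect_named(out$per_feature, "feature_01")
  expect_error(suppressWarnings(
    evaluate_selection(pan$ratings, list(feature_01 = "rater 1"))),
    "no feature is estimable")
})

test_that("identical groups show no pairwise significance", {
  set.seed(2)
  g <- rnorm(25, 0.5, 0.1)
  cmp <- compare_methods(list(fake_outcome("x", g), fake_outcome("y", g)))
  expect_false(any(cmp$pairwise$significant))
})

test_that("well-separated normal groups are flagged, agreeing with a permutation oracle", {
  set.seed(14)
  g1 <- rnorm(25, 0.5, 0.01)
  g2 <- rnorm(25, 0.8, 0.01)
  cmp <- compare_methods(list(fake_outcome("low", g1), fake_outcome("high", g2)))
  expect_identical(cmp$path, "anova_dunnett_t3")
  expect_true(all(cmp$pairwise$significant))
  expect_lt(perm_pvalue(g1, g2), 0.05)
})

test_that("with one shifted skewed group, only its pairs are flagged (Dunn path)", {
  set.seed(30)
  base1 <- exp(rnorm(25, 0, 0.4))
  base2 <- exp(rnorm(25, 0, 0.4))
  shifted <- exp(rnorm(25, 2.5, 0.4))
  cmp <- compare_methods(list(fake_outcome("a", base1), fake_outcome("b", base2),
                              fake_outcome("c", shifted)))
  expect_identical(cmp$path, "kruskal_dunn")
  pw <- cmp$pairwise
  involves_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$significant[involves_c]))
  expect_false(any(pw$significant[!involves_c]))
  expect_lt(perm_pvalue(base1, shifted), 0.05)
  expect_gt(perm_pvalue(base1, base2), 0.05)
})

test_that("all-constant groups make the comparison undefined rather than tested", {
  cmp <- compare_methods(list(fake_outcome("x", rep(0.5, 10)),
                              fake_outcome("y", rep(0.5, 10))))
  expect_identical(cmp$path, "undefined")
  expect_match(cmp$note, "zero variance")
})
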