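test_that("wide CSV reads into a complete ratings matrix and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item,rater 1,rater 2", "img1,1,0", "img2,1,1", "img3,0,0"), path)
  out <- read_ratings_csv(path, layout = "wide", feature_id = "crack")
  expect_length(out, 1)
  rm <- out[[1]]
  expect_s3_class(rm, "ratings_matrix")
  expect_identical(dim(rm$ratings), c(3L, 2L))
  expect_identical(sum(is.na(rm$ratings)), 0L)
  expect_identical(rm$ratings["img1", "rater 2"], "0")
  expect_identical(rm$categories, c("0", "1"))
})

test_that("long CSV partitions rows by occasion and keeps blanks as missing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,item,rater,occasion,rating",
               "f1,i1,r1,1,1", "f1,i1,r2,1,", "f1,i2,r1,1,0", "f1,i2,r2,1,1",
               "f1,rep1,r1,1,1", "f1,rep1,r1,2,0",
               "f1,rep2,r1,1,0", "f1,rep2,r1,2,0"), path)
  mats <- read_ratings_csv(path, layout = "long")
  rm <- mats[["f1"]]
  # occasion-2 rows never enter the matrix
  expect_true(all(c("i1", "i2", "rep1", "rep2") %in% item_ids(rm)))
  expect_true(is.na(rm$ratings["i1", "r2"]))
  reps <- read_replicates_csv(path)
  expect_length(reps, 1)
  expect_setequal(reps[[1]]$item_ids, c("rep1", "rep2"))
  # partition property: occasion-1 + occasion-2 rows = all data rows
  df <- read.csv(path, colClasses = "character")
  expect_identical(sum(df$occasion == "1") + sum(df$occasion == "2"), nrow(df))
  # repeated items are removable for interrater work
  nt <- exclude_testing_items(rm, reps)
  expect_setequal(item_ids(nt), c("i1", "i2"))
})

test_that("duplicate rows and out-of-set categories are hard errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,item,rater,occasion,rating",
               "f1,i1,r1,1,1", "f1,i1,r1,1,0"), path)
  expect_error(read_ratings_csv(path, layout = "long"), "duplicate")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,item,rater,occasion,rating",
               "f1,i1,r1,1,1", "f1,i1,r2,1,maybe"), path2)
  expect_error(read_ratings_csv(path2, layout = "long", categories = c("0", "1")),
               "outside the declared set")
  expect_silent(read_ratings_csv(path2, layout = "long"))
})

test_that("replicate reader pairs occasions and drops unpaired items with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- c("feature,item,rater,occasion,rating",
            sprintf("f1,rep%02d,r1,1,%d", 1:35, rep(c(0, 1), length.out = 35)),
            sprintf("f1,rep%02d,r1,2,%d", 1:35, rep(c(0, 1), length.out = 35)),
            sprintf("f1,rep%02d,r2,1,1", 1:35),
            sprintf("f1,rep%02d,r2,2,1", 1:35))
  writeLines(rows, path)
  reps <- read_replicates_csv(path)
  expect_length(reps, 2)
  r1 <- reps[[which(vapply(reps, function(r) r$rater_id, "") == "r1")]]
  expect_length(r1$item_ids, 35)
  expect_identical(r1$occasion1, r1$occasion2)
  expect_equal(intrarater_ac1(r1)$coefficient, 1)
  # drop rater 1's occasion-2 row of rep35 -> their table shrinks to 34, warning
  writeLines(rows[-71], path)
  expect_warning(reps2 <- read_replicates_csv(path), "single occasion")
  r1b <- reps2[[which(vapply(reps2, function(r) r$rater_id, "") == "r1")]]
  expect_length(r1b$item_ids, 34)
})

test_that("panel writer round-trips matrices and replicates through the readers", {
  m <- matrix(c("1", NA, "0", "1", "0", "0"), nrow = 3,
              dimnames = list(paste0("i", 1:3), c("r1", "r2")))
  rm <- ratings_matrix(m, feature_id = "f1")
  rt <- replicate_table("f1", "r1", c("rep1", "rep2"), c("1", "0"), c("1", "1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(rm, path, replicates = list(rt))
  back <- read_ratings_csv(path, layout = "long")[["f1"]]
  nt <- exclude_testing_items(back, list(rt))
  expect_identical(nt$ratings[rownames(m), colnames(m)], m)
  reps <- read_replicates_csv(path)
  expect_identical(reps[[1]]$occasion1, rt$occasion1)
  expect_identical(reps[[1]]$occasion2, rt$occasion2)
})

test_that("trace serialization is lossless, including the empty trace", {
  tr0 <- optimization_trace("flat", 0.8, list(), threshold = 0.6, n_raters = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_trace(tr0, path)
  expect_identical(read_trace(path), tr0)
  expect_length(read_trace(path)$rounds, 0)

  tr <- read_trace(fixture_trace_path())
  path2 <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, path2)
  expect_identical(read_trace(path2), tr)
})

test_that("the published 8-round trace fixture is internally consistent", {
  tr <- read_trace(fixture_trace_path())
  expect_length(tr$rounds, 8)
  counts <- vapply(tr$rounds, function(r) length(r$identified_raters), integer(1))
  expect_identical(counts, c(6L, 4L, 2L, 2L, 4L, 5L, 4L, 7L))
  expect_identical(sum(counts), 34L)
  remaining <- vapply(tr$rounds, function(r) r$n_remaining, integer(1))
  # remaining-rater arithmetic: n - cumulative exclusions, ending at 16
  expect_identical(remaining, 50L - cumsum(counts))
  expect_identical(remaining[8], 16L)
  expect_equal(tr$r_initial, 0.0948)
  expect_equal(tr$r_final, 0.6333)
  expect_true(tr$converged)
})

test_that("type constructors enforce their invariants", {
  expect_error(ratings_matrix(matrix("1", 2, 2,
                                     dimnames = list(c("a", "a"), c("r1", "r2")))),
               "duplicated item")
  expect_error(replicate_table("f", "r", c("a", "b"), "1", c("1", "0")),
               "length")
  expect_error(recognition_round(1, character(0), 5, 0.5), "at least one")
  bad_rounds <- list(recognition_round(1, "r1", 5, 0.2),
                     recognition_round(2, "r2", 5, 0.3))
  expect_error(optimization_trace("f", 0.1, bad_rounds), "strictly decrease")
})
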