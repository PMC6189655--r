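#' Construct a ratings matrix
#'
#' A `ratings_matrix` holds one feature's nominal ratings as an items x raters
#' character grid. Missing ratings are `NA`. Categories are opaque strings;
#' binary panels (e.g. "existed"/"not existed", coded `"1"`/`"0"`) are the
#' common case but nothing assumes two categories.
#'
#' @param ratings character (or coercible) matrix, rows = items, columns =
#'   raters. Row and column names are used as item and rater ids; defaults are
#'   generated when absent. Empty strings are treated as missing.
#' @param feature_id feature label carried through all downstream artifacts.
#' @param categories optional ordered character vector of admissible category
#'   codes. When omitted, the sorted set of observed values is used. Supplying
#'   an explicit set turns any unknown observed value into an error.
#' @return an object of class `ratings_matrix` with fields `feature_id`,
#'   `ratings`, `categories`.
#' @examples
#' m <- matrix(c("1", "1", "0", "1", "0", "0"), nrow = 3,
#'             dimnames = list(paste0("img", 1:3), c("rater 1", "rater 2")))
#' ratings_matrix(m, feature_id = "crack")
#' @export
ratings_matrix <- function(ratings, feature_id = "feature", categories = NULL) {
  if (!is.matrix(ratings)) stop("`ratings` must be a matrix")
  storage <- matrix(as.character(ratings), nrow(ratings), ncol(ratings),
                    dimnames = dimnames(ratings))
  storage[!is.na(storage) & storage == ""] <- NA_character_
  if (is.null(rownames(storage)))
    rownames(storage) <- paste0("item", seq_len(nrow(storage)))
  if (is.null(colnames(storage)))
    colnames(storage) <- paste0("rater", seq_len(ncol(storage)))
  if (anyDuplicated(rownames(storage)))
    stop("duplicated item ids in ratings matrix")
  if (anyDuplicated(colnames(storage)))
    stop("duplicated rater ids in ratings matrix")
  observed <- sort(unique(storage[!is.na(storage)]))
  if (is.null(categories)) {
    categories <- observed
  } else {
    categories <- as.character(categories)
    if (anyDuplicated(categories)) stop("duplicated category codes")
    unknown <- setdiff(observed, categories)
    if (length(unknown) > 0)
      stop("ratings contain categories outside the declared set: ",
           paste(unknown, collapse = ", "))
  }
  structure(
    list(feature_id = as.character(feature_id)[1],
         ratings = storage,
         categories = categories),
    class = "ratings_matrix"
  )
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf("<ratings_matrix> feature '%s': %d items x %d raters, %d categories (%s), %d missing\n",
              x$feature_id, nrow(x$ratings), ncol(x$ratings),
              length(x$categories), paste(x$categories, collapse = ", "),
              sum(is.na(x$ratings))))
  invisible(x)
}

#' @rdname ratings_matrix
#' @param x a `ratings_matrix`.
#' @export
item_ids <- function(x) rownames(x$ratings)

#' @rdname ratings_matrix
#' @export
rater_ids <- function(x) colnames(x$ratings)

#' @rdname ratings_matrix
#' @export
n_raters <- function(x) ncol(x$ratings)

#' Subset the rater panel of a ratings matrix
#'
#' @param x a [ratings_matrix()].
#' @param raters character vector of rater ids.
#' @return a `ratings_matrix` restricted to (or purged of) the given raters.
#' @export
keep_raters <- function(x, raters) {
  missing_ids <- setdiff(raters, rater_ids(x))
  if (length(missing_ids) > 0)
    stop("unknown rater ids: ", paste(missing_ids, collapse = ", "))
  ratings_matrix(x$ratings[, raters, drop = FALSE],
                 feature_id = x$feature_id, categories = x$categories)
}

#' @rdname keep_raters
#' @export
drop_raters <- function(x, raters) {
  keep_raters(x, setdiff(rater_ids(x), raters))
}

#' Restrict a ratings matrix to a set of items
#'
#' @inheritParams keep_raters
#' @param items character vector of item ids to retain.
#' @export
keep_items <- function(x, items) {
  missing_ids <- setdiff(items, item_ids(x))
  if (length(missing_ids) > 0)
    stop("unknown item ids: ", paste(missing_ids, collapse = ", "))
  ratings_matrix(x$ratings[items, , drop = FALSE],
                 feature_id = x$feature_id, categories = x$categories)
}

#' Drop repeated (test-retest) items from a ratings matrix
#'
#' Interrater agreement is conventionally computed over the single-presentation
#' ("nontesting") items; items that appear in any replicate table were shown
#' twice for intrarater assessment and are removed here.
#'
#' @param x a [ratings_matrix()].
#' @param replicates a list of [replicate_table()] objects (any features).
#' @export
exclude_testing_items <- function(x, replicates) {
  rep_items <- unique(unlist(lapply(replicates, function(r) r$item_ids)))
  keep_items(x, setdiff(item_ids(x), rep_items))
}

#' Construct a replicate (test-retest) table
#'
#' Holds one rater's paired ratings of the items that were presented twice,
#' used for intrarater agreement. In the motivating study 35 of 300 tongue
#' images were repeated for every expert.
#'
#' @param feature_id,rater_id labels.
#' @param item_ids ids of the repeated items.
#' @param occasion1,occasion2 category codes given at each presentation; must
#'   match `item_ids` in length.
#' @return an object of class `replicate_table`.
#' @export
replicate_table <- function(feature_id, rater_id, item_ids, occasion1, occasion2) {
  item_ids <- as.character(item_ids)
  occasion1 <- as.character(occasion1)
  occasion2 <- as.character(occasion2)
  if (length(occasion1) != length(item_ids) || length(occasion2) != length(item_ids))
    stop("occasion vectors must match item_ids in length")
  if (anyDuplicated(item_ids)) stop("duplicated item ids in replicate table")
  structure(
    list(feature_id = as.character(feature_id)[1],
         rater_id = as.character(rater_id)[1],
         item_ids = item_ids,
         occasion1 = occasion1,
         occasion2 = occasion2),
    class = "replicate_table"
  )
}

#' @export
print.replicate_table <- function(x, ...) {
  cat(sprintf("<replicate_table> feature '%s', rater '%s': %d repeated items, %d self-disagreements\n",
              x$feature_id, x$rater_id, length(x$item_ids),
              sum(x$occasion1 != x$occasion2, na.rm = TRUE)))
  invisible(x)
}

.long_required_cols <- c("feature", "item", "rater", "occasion", "rating")

.read_long <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.long_required_cols, names(df))
  if (length(missing_cols) > 0)
    stop("long ratings file lacks columns: ", paste(missing_cols, collapse = ", "))
  df$occasion <- as.integer(df$occasion)
  if (any(is.na(df$occasion)) || !all(df$occasion %in% c(1L, 2L)))
    stop("occasion must be 1 or 2")
  key <- paste(df$feature, df$item, df$rater, df$occasion, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (feature, item, rater, occasion) rows in ", path)
  df$rating[!is.na(df$rating) & df$rating == ""] <- NA_character_
  df
}

#' Read rating matrices from CSV
#'
#' Two dialects are supported. `layout = "wide"` reads one feature per file:
#' first column item id, remaining columns one per rater, blank cells missing.
#' `layout = "long"` reads tidy rows `(feature, item, rater, occasion, rating)`
#' and returns one matrix per feature built from the occasion-1 rows;
#' occasion-2 rows belong to the replicate design and are read by
#' [read_replicates_csv()].
#'
#' @param path CSV file path.
#' @param layout `"long"` or `"wide"`.
#' @param categories optional explicit category set applied to every feature;
#'   observed values outside it are an error.
#' @param feature_id feature label for `layout = "wide"`; defaults to the file
#'   name without extension.
#' @return a named list of [ratings_matrix()] objects (one element for a wide
#'   file).
#' @seealso [write_ratings_csv()] for the inverse of the long layout.
#' @export
read_ratings_csv <- function(path, layout = c("long", "wide"),
                             categories = NULL, feature_id = NULL) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    if (ncol(df) < 2) stop("wide ratings file needs an item column plus >=1 rater column")
    if (is.null(feature_id))
      feature_id <- tools::file_path_sans_ext(basename(path))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    out <- list(ratings_matrix(m, feature_id = feature_id, categories = categories))
    names(out) <- feature_id
    return(out)
  }
  df <- .read_long(path)
  df <- df[df$occasion == 1L, , drop = FALSE]
  feats <- unique(df$feature)
  out <- lapply(feats, function(f) {
    sub <- df[df$feature == f, , drop = FALSE]
    items <- unique(sub$item)
    raters <- unique(sub$rater)
    m <- matrix(NA_character_, length(items), length(raters),
                dimnames = list(items, raters))
    m[cbind(match(sub$item, items), match(sub$rater, raters))] <- sub$rating
    ratings_matrix(m, feature_id = f, categories = categories)
  })
  names(out) <- feats
  out
}

#' Read replicate (test-retest) tables from a long CSV
#'
#' Pairs the occasion-1 and occasion-2 rows of a long ratings file into one
#' [replicate_table()] per (feature, rater). Items carrying only one occasion
#' for a rater cannot contribute to intrarater agreement and are dropped; a
#' single warning reports how many were dropped.
#'
#' @inheritParams read_ratings_csv
#' @return a list of [replicate_table()] objects.
#' @export
read_replicates_csv <- function(path) {
  df <- .read_long(path)
  twice <- df[df$occasion == 2L, c("feature", "item", "rater"), drop = FALSE]
  if (nrow(twice) == 0) return(list())
  # replicate design = items any rater saw twice for that feature
  rep_keys <- unique(paste(twice$feature, twice$item, sep = "\r"))
  df <- df[paste(df$feature, df$item, sep = "\r") %in% rep_keys, , drop = FALSE]
  groups <- split(df, paste(df$feature, df$rater, sep = "\r"))
  dropped <- 0L
  out <- list()
  for (g in groups) {
    o1 <- g[g$occasion == 1L, ]
    o2 <- g[g$occasion == 2L, ]
    items <- intersect(o1$item, o2$item)
    dropped <- dropped + length(union(o1$item, o2$item)) - length(items)
    if (length(items) == 0) next
    out[[length(out) + 1L]] <- replicate_table(
      feature_id = g$feature[1], rater_id = g$rater[1], item_ids = items,
      occasion1 = o1$rating[match(items, o1$item)],
      occasion2 = o2$rating[match(items, o2$item)])
  }
  if (dropped > 0)
    warning(sprintf("%d item-rater pairs had a single occasion and were dropped", dropped))
  out
}

#' Write a rating panel to a long CSV
#'
#' Emits tidy rows `(feature, item, rater, occasion, rating)`: every cell of
#' every ratings matrix as occasion 1 (missing cells as blank ratings), and
#' both occasions of every replicate table. The output round-trips through
#' [read_ratings_csv()] / [read_replicates_csv()].
#'
#' @param ratings a [ratings_matrix()] or list of them.
#' @param path output CSV path.
#' @param replicates optional list of [replicate_table()] objects.
#' @export
write_ratings_csv <- function(ratings, path, replicates = NULL) {
  if (inherits(ratings, "ratings_matrix")) ratings <- list(ratings)
  rows <- lapply(ratings, function(rm) {
    data.frame(feature = rm$feature_id,
               item = rep(item_ids(rm), times = n_raters(rm)),
               rater = rep(rater_ids(rm), each = nrow(rm$ratings)),
               occasion = 1L,
               rating = as.vector(rm$ratings),
               stringsAsFactors = FALSE)
  })
  rep_rows <- lapply(replicates, function(rt) {
    data.frame(feature = rt$feature_id,
               item = rep(rt$item_ids, 2L),
               rater = rt$rater_id,
               occasion = rep(c(1L, 2L), each = length(rt$item_ids)),
               rating = c(rt$occasion1, rt$occasion2),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, rep_rows))
  df$rating[is.na(df$rating)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
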