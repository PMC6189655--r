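# Independent brute-force oracles: every quantity is evaluated directly from
# its definition with explicit loops, sharing no code with the package paths
# they check.

# AC1 by direct summation over items and categories
oracle_ac1 <- function(mat, categories = NULL) {
  if (is.null(categories)) categories <- sort(unique(mat[!is.na(mat)]))
  Q <- length(categories)
  pa_vals <- numeric(0)
  pi_rows <- NULL
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    row <- row[!is.na(row)]
    r_i <- length(row)
    riq <- vapply(categories, function(q) sum(row == q), numeric(1))
    if (r_i >= 2) {
      s <- 0
      for (q in seq_len(Q)) s <- s + riq[q] * (riq[q] - 1)
      pa_vals <- c(pa_vals, s / (r_i * (r_i - 1)))
    }
    if (r_i >= 1) pi_rows <- rbind(pi_rows, riq / r_i)
  }
  pa <- mean(pa_vals)
  piq <- colMeans(pi_rows)
  pe <- if (Q >= 2) sum(piq * (1 - piq)) / (Q - 1) else 0
  list(pa = pa, pe = pe, ac1 = (pa - pe) / (1 - pe))
}

# percent agreement by enumerating all rater pairs per item
oracle_pa_pairwise <- function(mat) {
  vals <- numeric(0)
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    row <- row[!is.na(row)]
    if (length(row) < 2) next
    agree <- 0; total <- 0
    for (a in seq_len(length(row) - 1))
      for (b in (a + 1):length(row)) {
        total <- total + 1
        if (row[a] == row[b]) agree <- agree + 1
      }
    vals <- c(vals, agree / total)
  }
  mean(vals)
}

# delete-one-item jackknife SD by an explicit loop over usable items
oracle_jackknife_sd <- function(mat) {
  ri <- apply(mat, 1, function(r) sum(!is.na(r)))
  usable <- which(ri >= 2)
  vals <- vapply(usable, function(i) oracle_ac1(mat[-i, , drop = FALSE])$ac1,
                 numeric(1))
  m <- mean(vals)
  sqrt((length(vals) - 1) / length(vals) * sum((vals - m)^2))
}

# two-rater Cohen kappa from the confusion marginals
oracle_cohen_kappa <- function(x, y) {
  cats <- sort(unique(c(x, y)))
  po <- mean(x == y)
  pe <- sum(vapply(cats, function(q) mean(x == q) * mean(y == q), numeric(1)))
  (po - pe) / (1 - pe)
}

oracle_spearman_brown <- function(r, k) k * r / (1 + (k - 1) * r)

# random binary panel with missing cells; guarantees >= 2 usable items
random_binary_panel <- function(n_items, n_raters, miss_prob = 0.15, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("0", "1"), n_items * n_raters, replace = TRUE),
              n_items, n_raters)
  m[stats::runif(length(m)) < miss_prob] <- NA
  m[1:2, 1:2] <- matrix(sample(c("0", "1"), 4, replace = TRUE), 2, 2)
  rownames(m) <- paste0("i", seq_len(n_items))
  colnames(m) <- paste0("r", seq_len(n_raters))
  m
}

# two-sided permutation test on the difference of group means
perm_pvalue <- function(x, y, nperm = 2000, seed = 42) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  hits <- 0
  for (i in seq_len(nperm)) {
    idx <- sample(length(pooled), nx)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12)
      hits <- hits + 1
  }
  (hits + 1) / (nperm + 1)
}

# the worked 4 items x 3 raters grid used across agreement tests
grid_4x3 <- function() {
  ratings_matrix(matrix(c("1","1","0","1", "1","1","0","0", "0","1","0","0"),
                        nrow = 4,
                        dimnames = list(paste0("i", 1:4), paste0("r", 1:3))))
}

fixture_trace_path <- function() {
  system.file("extdata", "moderate_texture_trace.json", package = "panelagree")
}

fake_outcome <- function(method, coefs) {
  structure(list(method = method, coefficients = coefs,
                 summary_median = stats::median(coefs)),
            class = "selection_outcome")
}
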