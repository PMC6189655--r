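#' @title Chance-corrected agreement for multi-rater nominal panels
#' @description
#' Gwet's first-order agreement coefficient (AC1) for an items x raters panel
#' of nominal ratings with missing cells allowed. Writing `r_iq` for the
#' number of raters placing item `i` in category `q` and `r_i = sum_q r_iq`:
#'
#' \deqn{P_a = \mathrm{mean}_{i: r_i \ge 2} \sum_q \frac{r_{iq}(r_{iq}-1)}{r_i(r_i-1)}}
#' \deqn{\pi_q = \mathrm{mean}_{i: r_i \ge 1} \; r_{iq}/r_i, \qquad
#'       P_e = \frac{1}{Q-1} \sum_q \pi_q (1-\pi_q)}
#' \deqn{AC_1 = \frac{P_a - P_e}{1 - P_e}}
#'
#' Items with fewer than two non-missing ratings carry no pairwise agreement
#' information; they are excluded from `P_a` (and from `n_items_used`) but
#' still inform the category marginals `pi_q` when they have one rating.
#' Unlike kappa-type statistics, the chance term is built from the marginal
#' category probabilities in a way that stays in line with the raw percent
#' agreement under extreme prevalence (the "kappa paradox" regime).
#'
#' The standard error is a delete-one-item jackknife over the usable items:
#' recompute AC1 leaving each usable item out, then
#' \eqn{SD = \sqrt{ \frac{n'-1}{n'} \sum_i (AC_{1,(-i)} - \overline{AC_1})^2 }}.
#'
#' @param ratings a [ratings_matrix()] with >= 2 raters and at least one item
#'   holding >= 2 non-missing ratings.
#' @return an object of class `agreement_estimate`: a list with fields
#'   `coefficient`, `sd` (jackknife), `n_items_used`, `n_raters`, `pa`, `pe`,
#'   `method`.
#' @examples
#' m <- matrix(c("1","1","0","1", "1","1","0","0", "0","1","0","0"), nrow = 4,
#'             dimnames = list(paste0("i", 1:4), paste0("r", 1:3)))
#' gwet_ac1(ratings_matrix(m))
#' @export
gwet_ac1 <- function(ratings) {
  C <- .count_matrix(ratings)
  st <- .ac1_stats(C, ncol(C))
  .agreement_estimate(
    coefficient = st$ac1, sd = .ac1_jackknife_sd(C, ncol(C)),
    n_items_used = st$n_used, n_raters = n_raters(ratings),
    pa = st$pa, pe = st$pe, method = "AC1")
}

#' Observed percent agreement
#'
#' The raw pairwise concordance `P_a` of [gwet_ac1()] with no chance
#' correction (`pe = 0`). Useful for diagnosing paradoxical kappa values:
#' a chance-corrected coefficient far below the percent agreement under
#' skewed prevalence is the classic warning sign.
#'
#' @inheritParams gwet_ac1
#' @return an `agreement_estimate` with `method = "percent"`.
#' @export
percent_agreement <- function(ratings) {
  C <- .count_matrix(ratings)
  st <- .ac1_stats(C, ncol(C))
  .agreement_estimate(
    coefficient = st$pa, sd = .pa_jackknife_sd(C),
    n_items_used = st$n_used, n_raters = n_raters(ratings),
    pa = st$pa, pe = 0, method = "percent")
}

#' Intrarater (test-retest) agreement
#'
#' Treats a rater's two presentations of the repeated items as a two-rater
#' panel and applies [gwet_ac1()]. This is the internal-consistency measure of
#' a rater: agreement of the rater with themself across occasions.
#'
#' @param replicates a [replicate_table()] with >= 2 repeated items.
#' @return an `agreement_estimate` (`n_raters = 2`).
#' @export
intrarater_ac1 <- function(replicates) {
  if (length(replicates$item_ids) < 2)
    stop("intrarater agreement needs >= 2 repeated items")
  m <- cbind(occ1 = replicates$occasion1, occ2 = replicates$occasion2)
  rownames(m) <- replicates$item_ids
  rm <- ratings_matrix(m, feature_id = replicates$feature_id)
  est <- gwet_ac1(rm)
  est
}

#' Intrarater agreement for every replicate table
#'
#' @param replicates list of [replicate_table()] objects.
#' @return data.frame with one row per (feature, rater): `feature_id`,
#'   `rater_id`, `coefficient`, `sd`, `n_items`. Tables on which the estimate
#'   is undefined yield `NA` with a warning.
#' @export
intrarater_all <- function(replicates) {
  rows <- lapply(replicates, function(rt) {
    est <- tryCatch(intrarater_ac1(rt), error = function(e) NULL)
    data.frame(feature_id = rt$feature_id, rater_id = rt$rater_id,
               coefficient = if (is.null(est)) NA_real_ else est$coefficient,
               sd = if (is.null(est)) NA_real_ else est$sd,
               n_items = length(rt$item_ids), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$coefficient)))
    warning(sum(is.na(out$coefficient)), " replicate tables had no defined estimate")
  out
}

#' Jackknife standard error of AC1
#'
#' Delete-one-item jackknife: AC1 is recomputed leaving out each usable item
#' (>= 2 non-missing ratings) in turn and the jackknife SD formula is applied
#' over those leave-one-out values.
#'
#' @inheritParams gwet_ac1
#' @return a non-negative scalar.
#' @export
ac1_sd <- function(ratings) {
  C <- .count_matrix(ratings)
  .ac1_jackknife_sd(C, ncol(C))
}

#' @export
print.agreement_estimate <- function(x, ...) {
  cat(sprintf("<agreement_estimate> %s = %.4f (SD %.4f), Pa = %.4f, Pe = %.4f, %d items x %d raters\n",
              x$method, x$coefficient, x$sd, x$pa, x$pe, x$n_items_used, x$n_raters))
  invisible(x)
}

.agreement_estimate <- function(coefficient, sd, n_items_used, n_raters, pa, pe, method) {
  structure(list(coefficient = coefficient, sd = sd,
                 n_items_used = n_items_used, n_raters = n_raters,
                 pa = pa, pe = pe, method = method),
            class = "agreement_estimate")
}

# items x Q category count matrix r_iq from a ratings_matrix
.count_matrix <- function(rm) {
  if (!inherits(rm, "ratings_matrix")) stop("expected a ratings_matrix")
  if (n_raters(rm) < 2) stop("interrater agreement needs >= 2 raters")
  Q <- max(length(rm$categories), 1L)
  codes <- matrix(match(rm$ratings, rm$categories), nrow(rm$ratings))
  C <- matrix(0, nrow(codes), Q)
  for (q in seq_len(Q)) C[, q] <- rowSums(codes == q, na.rm = TRUE)
  rownames(C) <- rownames(rm$ratings)
  C
}

# AC1 from the count matrix; Q = number of admissible categories.
# Q = 1 (a single observed category everywhere) is the degenerate unanimous
# panel: Pe is taken as 0 so that perfect agreement yields AC1 = 1.
.ac1_stats <- function(C, Q) {
  ri <- rowSums(C)
  use_pa <- ri >= 2
  if (!any(use_pa))
    stop("no item has >= 2 non-missing ratings; agreement undefined")
  pa_i <- rowSums(C[use_pa, , drop = FALSE] * (C[use_pa, , drop = FALSE] - 1)) /
    (ri[use_pa] * (ri[use_pa] - 1))
  pa <- mean(pa_i)
  use_pi <- ri >= 1
  P <- C[use_pi, , drop = FALSE] / ri[use_pi]
  piq <- colMeans(P)
  pe <- if (Q >= 2) sum(piq * (1 - piq)) / (Q - 1) else 0
  if (1 - pe < 1e-12)
    stop("chance agreement Pe = 1; coefficient undefined (degenerate marginals)")
  list(pa = pa, pe = pe, ac1 = (pa - pe) / (1 - pe),
       n_used = sum(use_pa), pa_i = pa_i, use_pa = use_pa, use_pi = use_pi)
}

# vectorized delete-one-item jackknife SD of AC1 over the usable items
.ac1_jackknife_sd <- function(C, Q) {
  ri <- rowSums(C)
  use_pa <- ri >= 2
  nU <- sum(use_pa)
  if (nU < 2) stop("jackknife SD needs >= 2 usable items")
  st <- .ac1_stats(C, Q)
  use_pi <- st$use_pi
  n1 <- sum(use_pi)
  P <- C[use_pi, , drop = FALSE] / ri[use_pi]
  Spi <- colSums(P)
  S_pa <- sum(st$pa_i)
  pa_loo <- (S_pa - st$pa_i) / (nU - 1)
  Pu <- C[use_pa, , drop = FALSE] / ri[use_pa]   # usable rows subset of use_pi
  pi_loo <- (matrix(Spi, nU, Q, byrow = TRUE) - Pu) / (n1 - 1)
  pe_loo <- if (Q >= 2) rowSums(pi_loo * (1 - pi_loo)) / (Q - 1) else numeric(nU)
  if (any(1 - pe_loo < 1e-12))
    stop("jackknife replicate with Pe = 1; SD undefined")
  ac1_loo <- (pa_loo - pe_loo) / (1 - pe_loo)
  m <- mean(ac1_loo)
  sqrt((nU - 1) / nU * sum((ac1_loo - m)^2))
}

.pa_jackknife_sd <- function(C) {
  ri <- rowSums(C)
  use_pa <- ri >= 2
  nU <- sum(use_pa)
  if (nU < 2) stop("jackknife SD needs >= 2 usable items")
  pa_i <- rowSums(C[use_pa, , drop = FALSE] * (C[use_pa, , drop = FALSE] - 1)) /
    (ri[use_pa] * (ri[use_pa] - 1))
  pa_loo <- (sum(pa_i) - pa_i) / (nU - 1)
  m <- mean(pa_loo)
  sqrt((nU - 1) / nU * sum((pa_loo - m)^2))
}
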