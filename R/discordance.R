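#' Spearman-Brown reliability prediction
#'
#' Predicts the reliability of a panel whose length is scaled by `k_factor`
#' from the reliability `r` of the current panel:
#' \deqn{R' = \frac{k\,r}{1 + (k-1)\,r}.}
#' In the leave-one-out detection procedure `k_factor = n/(n-1)` steps an
#' (n-1)-rater reliability back up to a predicted n-rater reliability.
#'
#' @param r reliability in \[-1, 1\] (vectorized).
#' @param k_factor positive panel-length multiplier.
#' @return predicted reliability, same length as `r`.
#' @export
spearman_brown_predict <- function(r, k_factor) {
  if (!is.numeric(k_factor) || length(k_factor) != 1 || k_factor <= 0)
    stop("k_factor must be a positive scalar")
  denom <- 1 + (k_factor - 1) * r
  if (any(abs(denom) < 1e-12))
    stop("Spearman-Brown denominator is zero")
  k_factor * r / denom
}

#' Leave-one-out detection of discordant raters
#'
#' For each rater `i` of an n-rater panel: the reliability of the remaining
#' n-1 raters (`r_loo`, Gwet's AC1) and its jackknife SD (`sd_loo`) are
#' computed, the Spearman-Brown formula predicts the n-rater reliability
#' `r_predicted` from `r_loo`, and the gap
#' \deqn{\Delta R = R_n - (R_{pred} - c \cdot SD)}
#' compares the panel's actual reliability `R_n` with the lower end of the
#' prediction interval (`c` = `ci_multiplier`, default 2, as in outlier
#' screening). `delta_r < 0` means the panel does measurably better without
#' rater `i` than the interval predicts with them: the rater is flagged
#' `discordant`. The opposite tail (`R_n` above the upper interval end) is
#' recorded as `beneficial` for information only; a beneficial rater is never
#' excluded.
#'
#' @param ratings a [ratings_matrix()] with >= 3 raters.
#' @param ci_multiplier half-width of the prediction interval in SD units.
#' @return a data.frame of class `loo_records`, one row per rater in panel
#'   order, with columns `rater_id`, `r_loo`, `sd_loo`, `r_predicted`,
#'   `delta_r`, `discordant`, `beneficial`; the full-panel reliability is
#'   attached as attribute `r_n`.
#' @export
leave_one_out <- function(ratings, ci_multiplier = 2) {
  n <- n_raters(ratings)
  if (n < 3) stop("leave-one-out detection needs >= 3 raters")
  if (!is.numeric(ci_multiplier) || ci_multiplier <= 0)
    stop("ci_multiplier must be positive")
  Q <- max(length(ratings$categories), 1L)
  C <- .count_matrix(ratings)
  rn <- .ac1_stats(C, Q)$ac1
  codes <- matrix(match(ratings$ratings, ratings$categories), nrow(ratings$ratings))
  k <- n / (n - 1)
  rec <- vector("list", n)
  for (j in seq_len(n)) {
    Dj <- matrix(0, nrow(C), Q)
    seen <- which(!is.na(codes[, j]))
    Dj[cbind(seen, codes[seen, j])] <- 1
    Cj <- C - Dj
    st <- .ac1_stats(Cj, Q)
    sdj <- .ac1_jackknife_sd(Cj, Q)
    pred <- spearman_brown_predict(st$ac1, k)
    rec[[j]] <- c(r_loo = st$ac1, sd_loo = sdj, r_predicted = pred)
  }
  rec <- do.call(rbind, rec)
  out <- data.frame(rater_id = rater_ids(ratings), rec,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$delta_r <- rn - (out$r_predicted - ci_multiplier * out$sd_loo)
  out$discordant <- out$delta_r < 0
  out$beneficial <- rn > out$r_predicted + ci_multiplier * out$sd_loo
  attr(out, "r_n") <- rn
  class(out) <- c("loo_records", "data.frame")
  out
}
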