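# Umbrella weights over the cyclic phase grid. Samples are assigned a phase
# (index mod period); a hypothesis is an ordered (trough, peak) phase pair:
# expression rises monotonically along the circle from the trough to the
# peak and falls monotonically from the peak back to the trough, wrapping
# the period boundary. Pairs of samples within the same arm are expected
# concordant with their position along the arm; pairs straddling the two
# arms carry no expectation (a rank test cannot order across arms). The
# symmetric cosine shape is the special case rise length = fall length.
umbrella_weights <- function(n, period) {
  pairs <- pair_index(n)
  m <- period
  phase <- (seq_len(n) - 1L) %% m
  cols <- list()
  peaks <- integer()
  for (k in seq_len(m) - 1L) {
    for (tau in seq_len(m) - 1L) {
      if (tau == k) next
      rise_len <- (k - tau) %% m
      d_rise <- (phase - tau) %% m      # position along the rising arm
      d_fall <- (phase - k) %% m        # position along the falling arm
      d_fall[phase == tau] <- m - rise_len
      in_rise <- d_rise <= rise_len
      in_fall <- d_rise >= rise_len | phase == tau
      w <- numeric(nrow(pairs))
      i <- pairs[, 1]
      j <- pairs[, 2]
      rr <- in_rise[i] & in_rise[j]
      ff <- in_fall[i] & in_fall[j] & !rr
      w[rr] <- sign(d_rise[i[rr]] - d_rise[j[rr]])
      w[ff] <- -sign(d_fall[i[ff]] - d_fall[j[ff]])
      cols[[length(cols) + 1L]] <- w
      peaks[length(peaks) + 1L] <- k
    }
  }
  W <- do.call(cbind, cols)
  keep <- !duplicated(t(W))
  list(W = W[, keep, drop = FALSE], peak = peaks[keep], pairs = pairs)
}

#' Rank umbrella periodicity test (RAIN-style)
#'
#' For each candidate peak phase within one period, scores the series with a
#' Jonckheere--Terpstra-type statistic for a monotone rise to the peak
#' followed by a monotone fall, takes the one-sided permutation p-value, and
#' Bonferroni-corrects the minimum over the distinct peak hypotheses. Unlike
#' the cosine correlation, this detects asymmetric rise/fall shapes.
#'
#' @inheritParams jtk_test
#' @return A tibble with one row per gene: `gene_id`, `p_rain`, the best
#'   `peak` phase (sample index within the period, 0-based), `peak_hours`,
#'   and a `degenerate` flag for all-tied series.
#' @export
rain_test <- function(tc, params = periodicity_params()) {
  validate_timecourse(tc)
  X <- timecourse_matrix(tc)
  n <- ncol(X)
  grid <- umbrella_weights(n, params$rain_period)
  res <- rank_score_test(X, grid$W, mode = params$mode,
                         n_perm = params$n_perm,
                         seed = sub_seed(params$seed, 23L))
  n_hyp <- ncol(grid$W)
  # normalized score breaks ties among hypotheses at the permutation-p floor
  strength <- sweep(res$score, 2, pmax(colSums(abs(grid$W)), 1), "/")
  best <- max.col(strength - res$p * 1e7, ties.method = "first")
  times <- timecourse_times(tc)
  tibble(gene_id = tc$gene_id,
         p_rain = pmin(res$p[cbind(seq_len(nrow(X)), best)] * n_hyp, 1),
         peak = grid$peak[best],
         peak_hours = times[1] + grid$peak[best] * params$interval,
         degenerate = res$degenerate)
}

#' @rdname rain_test
#' @param series a single numeric expression series.
#' @export
rain_pvalue <- function(series, params = periodicity_params()) {
  tc <- timecourse("g", matrix(series, 1L),
                   seq(2, by = params$interval, length.out = length(series)),
                   nonnegative = FALSE)
  rain_test(tc, params)
}
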