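#' Parameters for the periodicity tests
#'
#' Bundles the settings shared by the two rank-based tests. Periods are
#' expressed in *samples*, not hours: with the default 0.75 h sampling
#' interval, the default cosine period grid of 14--16 samples corresponds to
#' 10.5--12 h, and the umbrella test's period of 16 samples spans the whole
#' 16-point series (one full oscillation).
#'
#' @param periods integer vector of candidate cosine periods, in samples.
#' @param rain_period single integer period for the umbrella test, in samples.
#' @param interval sampling interval in hours.
#' @param n_perm number of permutations for the sampled null (series longer
#'   than 7 points); at least 1000.
#' @param mode `"auto"` (exact enumeration of all n! permutations for series
#'   of length <= 7, sampled permutations otherwise), `"exact"`, or `"perm"`.
#' @param seed integer seed governing the sampled permutation null.
#' @return A list of class `periodicity_params`.
#' @export
periodicity_params <- function(periods = c(14L, 15L, 16L), rain_period = 16L,
                               interval = 0.75, n_perm = 20000,
                               mode = c("auto", "exact", "perm"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(periods >= 4), rain_period >= 4, interval > 0)
  structure(list(periods = as.integer(periods),
                 rain_period = as.integer(rain_period),
                 interval = interval, n_perm = n_perm, mode = mode,
                 seed = as.integer(seed)),
            class = "periodicity_params")
}

# Discretized cosine reference waveforms over the (period, lag) grid,
# reduced to their pairwise sign patterns. Duplicate hypotheses (identical
# sign patterns) are collapsed; the Bonferroni factor is the distinct count.
jtk_reference_grid <- function(n, periods) {
  pairs <- pair_index(n)
  cols <- list()
  meta <- list()
  for (m in periods) {
    for (lag in seq_len(m) - 1L) {
      r <- cos(2 * pi * ((seq_len(n) - 1L) - lag) / m)
      cols[[length(cols) + 1L]] <- pair_signs(matrix(r, 1L), pairs, tol = 1e-8)[1L, ]
      meta[[length(meta) + 1L]] <- c(period = m, lag = lag)
    }
  }
  W <- do.call(cbind, cols)
  keep <- !duplicated(t(W))
  list(W = W[, keep, drop = FALSE],
       meta = as_tibble(do.call(rbind, meta))[keep, ],
       pairs = pairs)
}

#' Cosine-correlation periodicity test (JTK-style)
#'
#' Scores every gene's series against discretized cosine reference waveforms
#' over a grid of periods and phase lags using the (tie-aware) Kendall rank
#' correlation, takes the per-waveform one-sided permutation p-value, and
#' Bonferroni-corrects the minimum over the grid by the number of distinct
#' waveform hypotheses.
#'
#' @param tc a time-course tibble (see [timecourse()]).
#' @param params a [periodicity_params()] object.
#' @return A tibble with one row per gene: `gene_id`, `p_jtk`, the best
#'   waveform's `period` (samples), `lag` (samples), `lag_hours`, its
#'   tie-corrected Kendall `tau`, and a `degenerate` flag for all-tied series.
#' @export
jtk_test <- function(tc, params = periodicity_params()) {
  validate_timecourse(tc)
  X <- timecourse_matrix(tc)
  n <- ncol(X)
  grid <- jtk_reference_grid(n, params$periods)
  res <- rank_score_test(X, grid$W, mode = params$mode,
                         n_perm = params$n_perm,
                         seed = sub_seed(params$seed, 11L))
  n_hyp <- ncol(grid$W)
  n0 <- nrow(grid$pairs)
  n2 <- colSums(grid$W == 0)
  # tau-b against every waveform; used to break ties among waveforms whose
  # permutation p-values hit the same floor
  denom_all <- sqrt(outer(n0 - res$tied_pairs, n0 - n2))
  tau_all <- ifelse(denom_all > 0, res$score / denom_all, 0)
  best <- max.col(tau_all - res$p * 1e7, ties.method = "first")
  pick <- cbind(seq_len(nrow(X)), best)
  tau <- tau_all[pick]
  times <- timecourse_times(tc)
  tibble(gene_id = tc$gene_id,
         p_jtk = pmin(res$p[pick] * n_hyp, 1),
         period = grid$meta$period[best],
         lag = grid$meta$lag[best],
         lag_hours = times[1] + grid$meta$lag[best] * params$interval,
         tau = ifelse(res$degenerate, NA_real_, tau),
         degenerate = res$degenerate)
}

#' @rdname jtk_test
#' @param series a single numeric expression series.
#' @export
jtk_pvalue <- function(series, params = periodicity_params()) {
  tc <- timecourse("g", matrix(series, 1L),
                   seq(2, by = params$interval, length.out = length(series)),
                   nonnegative = FALSE)
  jtk_test(tc, params)
}
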