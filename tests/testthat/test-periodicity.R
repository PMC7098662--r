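params_fast <- periodicity_params(n_perm = 2000, seed = 7)

test_that("degenerate and noiseless series behave at the extremes", {
  const <- jtk_pvalue(rep(3, 16), params_fast)
  expect_equal(const$p_jtk, 1)
  expect_true(const$degenerate)
  expect_equal(rain_pvalue(rep(3, 16), params_fast)$p_rain, 1)

  # a noiseless cosine at period 16 samples, lag 0, attains the smallest
  # p reachable on the grid and is assigned the generating waveform
  x <- cos(2 * pi * (0:15) / 16)
  pdeep <- periodicity_params(seed = 7)
  hit <- jtk_pvalue(x, pdeep)
  expect_equal(hit$period, 16)
  expect_equal(hit$lag, 0)
  # reference ties (symmetric cosine samples) keep tau-b just below 1
  expect_gt(hit$tau, 0.95)
  expect_lt(hit$p_jtk, 0.01)
  n_hyp <- ncol(cyclotome:::jtk_reference_grid(16, c(14, 15, 16))$W)
  # minimum achievable combined p: no permutation beats the generating
  # waveform, so the per-waveform p is at its floor
  floor_p <- cyclotome:::rank_score_test(
    matrix(x, 1), cyclotome:::jtk_reference_grid(16, c(14, 15, 16))$W,
    mode = "perm", n_perm = pdeep$n_perm, seed = cyclotome:::sub_seed(7, 11L))$p
  expect_equal(hit$p_jtk, min(floor_p) * n_hyp)
})

test_that("sign reversal gives the same p with the lag shifted half a period", {
  p16 <- periodicity_params(periods = 16L, n_perm = 2000, seed = 3)
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(16)
    a <- jtk_pvalue(x, p16)
    b <- jtk_pvalue(-x, p16)
    expect_equal(a$p_jtk, b$p_jtk)
    expect_equal((a$lag - b$lag) %% 16, 8)
  }
})

test_that("umbrella test rewards rise-to-peak-then-fall and reports the peak", {
  # the minimum reachable p is n_hyp / (n_perm + 1), so the default 2e4
  # permutations are needed to resolve clear signals below 0.05
  pdeep <- periodicity_params(seed = 7)
  x <- c(1:8, 8:1)  # strict rise to sample 8 then strict fall
  res <- rain_pvalue(x, pdeep)
  expect_lt(res$p_rain, 0.05)
  expect_equal(res$peak, 7)  # 0-based phase of the maximum
  # and an asymmetric sawtooth (fast rise, slow fall) is still caught
  saw <- c(seq(0, 1, length.out = 4), seq(1, 0, length.out = 12))
  expect_lt(rain_pvalue(saw, pdeep)$p_rain, 0.05)
})

test_that("both tests are never anti-conservative under i.i.d. noise", {
  tc <- noise_timecourse(400, seed = 21)
  j <- jtk_test(tc, params_fast)
  r <- rain_test(tc, params_fast)
  for (alpha in c(0.01, 0.05, 0.2)) {
    # binomial 99.9% upper bound at nominal alpha
    ub <- qbinom(0.999, 400, alpha) / 400
    expect_lte(mean(j$p_jtk < alpha), ub)
    expect_lte(mean(r$p_rain < alpha), ub)
  }
})

test_that("rank combination reproduces the hand-computed BH example", {
  pv <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       p_jtk = c(0.001, 0.5, 0.9),
                       p_rain = c(0.002, 0.8, 0.4))
  tab <- rank_and_combine(pv)
  expect_equal(tab$combined_rank, c(2, 5, 5))
  expect_true(all(tab$q_jtk >= tab$p_jtk))
  expect_true(all(tab$q_jtk <= 1))
  # monotone: BH order follows raw order
  expect_equal(order(tab$q_jtk), order(tab$p_jtk))

  # all-tied p-values: ranks fall back to gene-id order, deterministically
  tied <- tibble::tibble(gene_id = c("b", "a", "c"),
                         p_jtk = rep(0.5, 3), p_rain = rep(0.5, 3))
  tt <- rank_and_combine(tied)
  expect_equal(tt$rank_jtk[order(tt$gene_id)], 1:3)
  expect_error(rank_and_combine(dplyr::mutate(pv, p_rain = NA_real_)), "missing")
})

test_that("replicate-consistency selection matches the hand-enumerated toy", {
  mk <- function(ranks) {
    tibble::tibble(gene_id = paste0("g", 1:5), combined_rank = ranks)
  }
  # loose = 3: candidates must rank <= 3 in both replicates
  t1 <- mk(c(1, 2, 3, 4, 5))
  t2 <- mk(c(2, 1, 5, 3, 4))
  ta <- mk(c(2, 1, 3, 4, 5))
  out <- select_periodic(t1, t2, ta, selection_rule(loose = 3, strict = 2))
  expect_setequal(out$gene_id[out$candidate], c("g1", "g2"))
  expect_setequal(out$gene_id[out$selected], c("g1", "g2"))

  # a manual include enters even when ranked far beyond the cutoffs
  out2 <- select_periodic(t1, t2, ta,
                          selection_rule(loose = 3, strict = 2,
                                         manual_include = "g5"))
  expect_setequal(out2$gene_id[out2$selected], c("g1", "g2", "g5"))
  expect_error(
    select_periodic(t1, t2, ta, selection_rule(manual_include = "nope")),
    "nope")

  # loose = strict = n selects everything
  all_in <- select_periodic(t1, t2, ta, selection_rule(loose = 5, strict = 5))
  expect_true(all(all_in$selected))
})

test_that("enlarging the loose cutoff never drops a selected gene", {
  set.seed(9)
  n <- 60
  mk <- function() {
    tibble::tibble(gene_id = sprintf("g%02d", 1:n),
                   combined_rank = sample(n))
  }
  t1 <- mk(); t2 <- mk(); ta <- mk()
  prev <- character()
  for (loose in c(10, 20, 35, 60)) {
    out <- select_periodic(t1, t2, ta, selection_rule(loose = loose, strict = 10))
    sel <- out$gene_id[out$selected]
    if (sum(out$candidate) <= 10) expect_true(all(prev %in% sel))
    prev <- sel
  }
})

test_that("the full detector flags planted oscillations, not drifts", {
  sim <- simulate_timecourse(simulation_config(
    n_genes = 150, periodic_fraction = 0.2, drift_fraction = 0.3, seed = 13))
  det <- detect_periodic(sim$replicates[[1]], sim$replicates[[2]],
                         periodicity_params(n_perm = 2000, seed = 5),
                         selection_rule(loose = 50, strict = 30))
  truth <- sim$truth
  planted <- truth$gene_id[truth$is_periodic]
  sens <- mean(planted %in% det$selected)
  expect_gte(sens, 0.7)
  drifters <- truth$gene_id[truth$drift != 0]
  expect_lte(mean(drifters %in% det$selected), 0.2)
  expect_s3_class(tidy(det), "tbl_df")
  expect_equal(glance(det)$n_selected, length(det$selected))
})
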