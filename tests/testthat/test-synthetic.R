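test_that("the generator honours its contract and is bit-reproducible", {
  cfg <- simulation_config(n_genes = 50, periodic_fraction = 0, seed = 3)
  sim <- simulate_timecourse(cfg)
  expect_false(any(sim$truth$is_periodic))
  expect_true(all(sim$truth$amplitude == 0))

  cfg2 <- simulation_config(n_genes = 80, seed = 17)
  a <- simulate_timecourse(cfg2)
  b <- simulate_timecourse(cfg2)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$truth, b$truth)
  # different seed, different data
  c2 <- simulate_timecourse(simulation_config(n_genes = 80, seed = 18))
  expect_false(identical(a$replicates[[1]], c2$replicates[[1]]))

  # replicates share the deterministic signal, not the noise
  expect_false(identical(a$replicates[[1]], a$replicates[[2]]))
  expect_true(all(timecourse_matrix(a$replicates[[1]]) >= 0))

  # zero noise + zero amplitude + zero drift rows are flagged constant
  flat <- simulate_timecourse(simulation_config(
    n_genes = 20, periodic_fraction = 0.5, noise_sd = 0, drift_fraction = 0,
    seed = 1))
  expect_true(all(flat$truth$constant == !flat$truth$is_periodic))
  m <- timecourse_matrix(flat$replicates[[1]])
  expect_true(all(apply(m[flat$truth$constant, ], 1, function(r) length(unique(r))) == 1))
})

test_that("damping shrinks late-cycle amplitude like loss of synchrony", {
  cfg <- simulation_config(n_genes = 400, periodic_fraction = 1, noise_sd = 0,
                           damping_rate = 0.2, drift_fraction = 0, seed = 5)
  sim <- simulate_timecourse(cfg)
  m <- timecourse_matrix(sim$replicates[[1]])
  dev <- abs(m - sim$truth$baseline)
  # mean absolute deviation from baseline decays over the window
  early <- mean(dev[, 1:4])
  late <- mean(dev[, 13:16])
  expect_lt(late, early * exp(-0.2 * 6))
})

test_that("detection sensitivity rises with the signal-to-noise ratio", {
  sens <- vapply(c(0.5, 1, 2, 4), function(snr) {
    hits <- vapply(1:10, function(s) {
      sim <- simulate_timecourse(simulation_config(
        n_genes = 200, periodic_fraction = 0.1, amplitude_snr = snr,
        seed = 100 + s))
      det <- detect_periodic(sim$replicates[[1]], sim$replicates[[2]],
                             periodicity_params(n_perm = 4000, seed = s),
                             selection_rule(loose = 50, strict = 20))
      mean(sim$truth$gene_id[sim$truth$is_periodic] %in% det$selected)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_false(is.unsorted(sens))
  expect_gt(sens[4], sens[1])
})

test_that("orthogroup universes plant exactly the stated structure", {
  # strong planted sharing on a sparse background: every pairwise test rejects
  sat <- simulate_orthogroup_universe(n_species = 3, n_orthogroups = 400,
                                      periodic_prob = 0.05,
                                      shared_periodic_excess = 0.5, seed = 2)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    sa <- names(sat$periodic)[pr[1]]
    sb <- names(sat$periodic)[pr[2]]
    res <- pairwise_overlap_test(
      periodic_orthogroups(sat$universe, sa, sat$periodic[[sa]]),
      periodic_orthogroups(sat$universe, sb, sat$periodic[[sb]]),
      species_orthogroups(sat$universe, sa),
      species_orthogroups(sat$universe, sb))
    expect_lt(res$p_value, 1e-10)
  }
  expect_equal(sum(sat$truth$planted_shared), 200)
  # at full saturation the null itself is saturated (success probability 1):
  # shared equals both C and the expectation, so nothing can be "enriched"
  full <- simulate_orthogroup_universe(n_species = 2, n_orthogroups = 100,
                                       shared_periodic_excess = 1, seed = 4)
  res_full <- pairwise_overlap_test(
    periodic_orthogroups(full$universe, "sp1", full$periodic$sp1),
    periodic_orthogroups(full$universe, "sp2", full$periodic$sp2),
    species_orthogroups(full$universe, "sp1"),
    species_orthogroups(full$universe, "sp2"))
  expect_equal(res_full$shared, res_full$C)
  expect_equal(res_full$a_exp, res_full$C)

  # full presence, zero periodicity
  none <- simulate_orthogroup_universe(n_species = 2, n_orthogroups = 100,
                                       presence_prob = 1, periodic_prob = 0,
                                       seed = 3)
  expect_true(all(lengths(none$periodic) == 0))
  expect_equal(nrow(none$universe), 200)

  expect_error(simulate_orthogroup_universe(n_species = 1), "at least 2")
  # determinism
  u1 <- simulate_orthogroup_universe(seed = 9, n_orthogroups = 50)
  u2 <- simulate_orthogroup_universe(seed = 9, n_orthogroups = 50)
  expect_identical(u1, u2)
})

test_that("null universes give approximately uniform overlap p-values", {
  set.seed(4)
  pvals <- unlist(lapply(1:12, function(i) {
    u <- simulate_orthogroup_universe(n_species = 4, n_orthogroups = 2500,
                                      periodic_prob = 0.1, seed = 2000 + i)
    sp <- names(u$periodic)
    combn(sp, 2, function(pr) {
      pairwise_overlap_test(
        periodic_orthogroups(u$universe, pr[1], u$periodic[[pr[1]]]),
        periodic_orthogroups(u$universe, pr[2], u$periodic[[pr[2]]]),
        species_orthogroups(u$universe, pr[1]),
        species_orthogroups(u$universe, pr[2]))$p_value
    })
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  ci <- qbinom(c(0.005, 0.995), length(pvals), 0.05) / length(pvals)
  frac <- mean(pvals < 0.05)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})
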