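test_that("periodic orthogroups need only one periodic member", {
  uni <- tibble::tibble(
    orthogroup = c(rep("OG1", 10), "OG2", "OG3"),
    species = "sp1",
    gene_id = c(sprintf("a%02d", 1:10), "b1", "c1"))
  # one periodic member out of ten is enough
  expect_equal(periodic_orthogroups(uni, "sp1", "a07"), "OG1")
  expect_equal(periodic_orthogroups(uni, "sp1", character()), character(0))
  # a periodic gene outside any orthogroup contributes nothing (but is logged)
  expect_message(out <- periodic_orthogroups(uni, "sp1", "ghost"), "no orthogroup")
  expect_equal(out, character(0))
})

test_that("overlap test reproduces the expectation formula and exact tail", {
  uniA <- sprintf("OG%03d", 1:100)
  uniB <- uniA
  perA <- uniA[1:20]
  perB <- uniA[c(1:12, 51:68)]  # 12 shared, p2 = 30
  res <- pairwise_overlap_test(perA, perB, uniA, uniB)
  expect_equal(res$C, 100)
  expect_equal(res$p1, 20)
  expect_equal(res$p2, 30)
  expect_equal(res$shared, 12)
  expect_equal(res$a_exp, 6)  # p1 * p2 / C
  expect_equal(res$p_value, oracle_binom_upper(12, 100, 0.06), tolerance = 1e-12)

  # symmetry in the two species
  rev <- pairwise_overlap_test(perB, perA, uniB, uniA)
  expect_equal(rev[c("C", "p1", "p2", "shared", "a_exp", "p_value")],
               res[c("C", "p2", "p1", "shared", "a_exp", "p_value")],
               ignore_attr = TRUE)

  # no shared periodic orthogroups can never flag enrichment
  res0 <- pairwise_overlap_test(uniA[1:20], uniA[21:40], uniA, uniB)
  expect_equal(res0$shared, 0)
  expect_equal(res0$p_value, 1)
  # empty periodic set on one side
  e <- pairwise_overlap_test(character(), perB, uniA, uniB)
  expect_equal(e$a_exp, 0)
  expect_equal(e$p_value, 1)
  expect_error(pairwise_overlap_test("OGX", perB, uniA, uniB), "universe")
  expect_error(pairwise_overlap_test(character(), character(), "OG001", "OG999"),
               "C = 0")
})

test_that("observed counts at or below expectation give p >= 0.5", {
  set.seed(19)
  for (i in 1:50) {
    C <- sample(20:500, 1)
    p1 <- sample.int(C, 1)
    p2 <- sample.int(C, 1)
    a_exp <- p1 * p2 / C
    shared <- sample(0:floor(a_exp), 1)
    uni <- sprintf("OG%04d", seq_len(C))
    # construct sets realizing exactly (p1, p2, shared) within C
    if (shared > min(p1, p2) || p1 + p2 - shared > C) next
    perA <- uni[seq_len(p1)]
    perB <- uni[c(seq_len(shared), seq(p1 + 1, length.out = p2 - shared))]
    res <- pairwise_overlap_test(perA, perB, uni, uni)
    expect_equal(res$shared, shared)
    expect_gte(res$p_value, 0.5)
  }
})

test_that("adding a shared periodic orthogroup only strengthens the signal", {
  uni <- sprintf("OG%03d", 1:200)
  p_prev <- Inf
  for (shared in c(5, 10, 20, 40)) {
    perA <- uni[1:40]
    perB <- uni[c(seq_len(shared), seq(41, length.out = 40 - shared))]
    res <- pairwise_overlap_test(perA, perB, uni, uni)
    expect_lte(res$p_value, p_prev)
    p_prev <- res$p_value
  }
})

test_that("one-to-one overlap counts pairs and rejects duplicated genes", {
  pairs <- tibble::tibble(gene_a = sprintf("a%03d", 1:50),
                          gene_b = sprintf("b%03d", 1:50))
  # saturated sharing well above the null expectation is all but certain
  strong <- one_to_one_overlap_test(pairs, pairs$gene_a[1:25], pairs$gene_b[1:25])
  expect_equal(strong$shared, 25)
  expect_equal(strong$a_exp, 25 * 25 / 50)
  expect_lt(strong$p_value, 1e-3)
  # when literally every pair is periodic in both species the null is
  # saturated too (success probability 1), so the tail is 1 by construction
  all_per <- one_to_one_overlap_test(pairs, pairs$gene_a, pairs$gene_b)
  expect_equal(all_per$shared, 50)
  expect_equal(all_per$p_value, 1)
  empty <- one_to_one_overlap_test(pairs, character(), character())
  expect_equal(empty$p_value, 1)
  dup <- dplyr::bind_rows(pairs, tibble::tibble(gene_a = "a001", gene_b = "zzz"))
  expect_error(one_to_one_overlap_test(dup, "a001", "b001"), "a001")
})

test_that("one-to-one null rejection rate is nominal at alpha = 0.05", {
  set.seed(8)
  C <- 1000
  pairs <- tibble::tibble(gene_a = sprintf("a%04d", 1:C),
                          gene_b = sprintf("b%04d", 1:C))
  rej <- vapply(seq_len(500), function(i) {
    perA <- pairs$gene_a[runif(C) < 0.1]
    perB <- pairs$gene_b[runif(C) < 0.1]
    one_to_one_overlap_test(pairs, perA, perB)$p_value < 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 500, 0.05) / 500
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("the conserved core requires presence everywhere, periodicity everywhere", {
  uni <- tibble::tibble(
    orthogroup = c("OG1", "OG1", "OG1", "OG2", "OG2", "OG2", "OG3", "OG3"),
    species = c("s1", "s2", "s3", "s1", "s2", "s3", "s1", "s2"),
    gene_id = paste0("g", 1:8))
  per <- list(s1 = list(c("OG1", "OG3")), s2 = list("OG1", "OG2"), s3 = list("OG1"))
  expect_equal(core_conserved_set(uni, per), "OG1")
  # periodic in only 2 of 3 species: out
  per2 <- list(s1 = list("OG2"), s2 = list("OG2"), s3 = list(character()))
  expect_equal(core_conserved_set(uni, per2), character(0))
  # absent from one species: out regardless of periodicity (OG3)
  per3 <- list(s1 = list("OG3"), s2 = list("OG3"), s3 = list("OG3"))
  expect_equal(core_conserved_set(uni, per3), character(0))
  expect_error(core_conserved_set(uni, list(s1 = list("OG1"))), "at least 2")
  expect_error(core_conserved_set(uni, list(s1 = list(), s2 = list("OG1"))),
               "zero datasets")
})

test_that("species thresholds cap the list at a genome fraction", {
  ranked <- tibble::tibble(gene_id = sprintf("g%05d", 1:3000), rank = 1:3000)
  expect_equal(nrow(apply_species_threshold(ranked, 6000, 0.1)), 600)
  # the A. thaliana policy: 5% of 21200 genes = exactly 1060
  big <- tibble::tibble(gene_id = sprintf("g%05d", 1:2000), rank = 1:2000)
  expect_equal(floor(0.05 * 21200), 1060)
  expect_equal(nrow(apply_species_threshold(big, 21200, 0.05)), 1060)
  # a list already below the cap is unchanged
  small <- tibble::tibble(gene_id = paste0("g", 1:10), rank = 10:1)
  out <- apply_species_threshold(small, 1000, 0.1)
  expect_setequal(out$gene_id, small$gene_id)
  expect_false(is.unsorted(out$rank))
})
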