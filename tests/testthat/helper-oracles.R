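# Independent oracles the implementation is checked against. These are
# deliberately written with naive loops / direct enumeration, not with the
# package's pairwise-sign matrix machinery.

# every permutation of the elements of v, one per row (naive recursion)
oracle_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (k in seq_len(n)) {
    rest <- oracle_perms(v[-k])
    out <- rbind(out, cbind(v[k], rest))
  }
  out
}

# Kendall-type score of x against reference r: sum over pairs i<j of
# sign(x_i - x_j) * sign(r_i - r_j), naive double loop. Reference values that
# are equal up to floating-point noise (symmetric cosine samples) are ties.
oracle_tau_score <- function(x, r) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dr <- r[i] - r[j]
      if (abs(dr) < 1e-8) dr <- 0
      s <- s + sign(x[i] - x[j]) * sign(dr)
    }
  }
  s
}

# exhaustive one-sided permutation p-value of the tau score
oracle_perm_pvalue <- function(x, r) {
  perms <- oracle_perms(x)
  obs <- oracle_tau_score(x, r)
  null <- apply(perms, 1, oracle_tau_score, r = r)
  mean(null >= obs)
}

# upper-tail hypergeometric by direct pmf summation from log factorials
oracle_hyper_upper <- function(k, m, n_other, s) {
  kk <- max(k, 0):min(m, s)
  if (k > min(m, s)) return(0)
  sum(exp(lchoose(m, kk) + lchoose(n_other, s - kk) - lchoose(m + n_other, s)))
}

# two-sided Fisher p: sum of all hypergeometric outcomes no more probable
# than the observed one (with the classical relative tolerance)
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b
  n_other <- c + d
  s <- a + c
  support <- max(0, s - n_other):min(m, s)
  pmf <- exp(lchoose(m, support) + lchoose(n_other, s - support) -
               lchoose(m + n_other, s))
  p_obs <- pmf[support == a]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# upper-tail binomial by direct pmf summation
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  kk <- k:n
  sum(exp(lchoose(n, kk) + kk * log(p) + (n - kk) * log1p(-p)))
}

# brute-force Dollo minimizer: over every node (and tip) v whose clade
# contains the full presence set, count the losses needed (maximal pruned
# subtrees containing no presence leaf); return the label of the cheapest
# single-gain placement
oracle_dollo <- function(presence, tree) {
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  leaves_under <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], leaves_under))
  }
  losses <- function(v) {
    lv <- leaves_under(v)
    if (!any(lv %in% presence)) return(1L)  # prune this whole subtree: 1 loss
    if (v <= ntip) return(0L)
    sum(vapply(kids[[as.character(v)]], losses, integer(1)))
  }
  feasible <- which(vapply(seq_len(ntip + tree$Nnode),
                           function(v) all(presence %in% leaves_under(v)),
                           logical(1)))
  cost <- vapply(feasible, losses, integer(1))
  labels[feasible[which.min(cost)]]
}

# shared small fixtures -------------------------------------------------------

# six-age caterpillar tree with the focal species at the tip of the comb
fixture_tree <- function() {
  tr <- ape::read.tree(text = "(((((focal,s1),s2),s3),s4),s5)root;")
  label_tree_nodes(tr)
}

noise_timecourse <- function(n_genes, seed, n_time = 16) {
  set.seed(seed)
  timecourse(sprintf("g%04d", seq_len(n_genes)),
             matrix(rnorm(n_genes * n_time), n_genes),
             seq(2, by = 0.75, length.out = n_time), nonnegative = FALSE)
}

# two antiphase cosine waves with small noise, for planted clustering
planted_two_waves <- function(n_per_wave = 50, noise = 0.05, seed = 1) {
  set.seed(seed)
  times <- seq(2, by = 0.75, length.out = 16)
  base <- cos(2 * pi * (times - 2) / 11)
  m <- rbind(
    matrix(rep(base, each = n_per_wave), n_per_wave) ,
    matrix(rep(-base, each = n_per_wave), n_per_wave)
  ) + matrix(rnorm(2 * n_per_wave * 16, 0, noise), 2 * n_per_wave)
  tc <- timecourse(sprintf("g%03d", seq_len(2 * n_per_wave)), m, times,
                   nonnegative = FALSE)
  list(profiles = zscore_normalize(tc),
       labels = rep(1:2, each = n_per_wave))
}
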