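# Shared permutation machinery for the two rank-based periodicity tests.
#
# Both tests score a series x against a family of reference hypotheses, and
# every score is a linear functional of the pairwise sign pattern of x:
#   S_w(x) = sum over pairs (i<j) of W[pair, w] * sign(x_i - x_j)
# For the cosine-correlation test W is the pairwise sign matrix of a reference
# waveform (so S is the numerator of Kendall's tau-b); for the umbrella test W
# encodes expected rise/fall orderings around a candidate peak. The
# permutation null of S therefore depends on x only through its tie pattern,
# so nulls are computed once per tie pattern and shared across genes. Sampled
# permutation sets are closed under sign complement, which makes the antiphase
# symmetry (negated series vs. half-period-shifted reference) hold exactly.

pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

# X: rows are series; returns rows x npairs matrix of sign(x_i - x_j)
pair_signs <- function(X, pairs, tol = 0) {
  d <- X[, pairs[, 1], drop = FALSE] - X[, pairs[, 2], drop = FALSE]
  s <- sign(d)
  if (tol > 0) s[abs(d) < tol] <- 0
  s
}

# all n! permutations of 1..n, one per row (used for the exact null, n <= 8)
all_perms <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = nrow(sub) * n, ncol = n)
  for (k in seq_len(n)) {
    block <- seq_len(nrow(sub)) + (k - 1L) * nrow(sub)
    if (k > 1L) out[block, seq_len(k - 1L)] <- sub[, seq_len(k - 1L), drop = FALSE]
    out[block, k] <- n
    if (k < n) out[block, seq(k + 1L, n)] <- sub[, seq(k, n - 1L), drop = FALSE]
  }
  out
}

# Null score samples for permutations of the value multiset `v` against W.
# Returns a matrix (draws x hypotheses) with attribute `exact`.
null_scores <- function(v, W, pairs, mode, n_perm, seed) {
  n <- length(v)
  exact <- identical(mode, "exact") || (identical(mode, "auto") && n <= 7)
  if (exact) {
    perms <- all_perms(n)
    V <- matrix(v[perms], nrow = nrow(perms))
    out <- pair_signs(V, pairs) %*% W
    attr(out, "exact") <- TRUE
    return(out)
  }
  b2 <- ceiling(n_perm / 2)
  V <- with_seed(seed, {
    t(vapply(seq_len(b2), function(k) sample(v), numeric(n)))
  })
  half <- pair_signs(V, pairs) %*% W
  out <- rbind(half, -half)
  attr(out, "exact") <- FALSE
  out
}

# One-sided (upper-tail) permutation p-values of the scores of every row of X
# against every hypothesis column of W. Scores are integer-valued, so tail
# counts use exact half-unit offsets. Constant rows get p = 1 everywhere.
rank_score_test <- function(X, W, mode = c("auto", "exact", "perm"),
                            n_perm = 20000, seed = 1L) {
  mode <- match.arg(mode)
  n <- ncol(X)
  if (n < 4) abort("series must have at least 4 time points")
  if (mode != "exact" && n_perm < 1000) abort("n_perm must be at least 1000")
  pairs <- pair_index(n)
  SX <- pair_signs(X, pairs)
  S <- SX %*% W
  ranks <- t(apply(X, 1, rank))
  keys <- apply(ranks, 1, function(r) paste(sort(r), collapse = ","))
  P <- matrix(NA_real_, nrow(X), ncol(W))
  degenerate <- logical(nrow(X))
  for (key in unique(keys)) {
    rows <- which(keys == key)
    v <- as.numeric(strsplit(key, ",", fixed = TRUE)[[1]])
    if (length(unique(v)) == 1L) {
      P[rows, ] <- 1
      degenerate[rows] <- TRUE
      next
    }
    nil <- null_scores(v, W, pairs, mode, n_perm, seed)
    bt <- nrow(nil)
    is_exact <- attr(nil, "exact")
    for (w in seq_len(ncol(W))) {
      ns <- sort.int(nil[, w], method = "quick")
      cnt <- bt - findInterval(S[rows, w] - 0.5, ns)
      P[rows, w] <- if (is_exact) cnt / bt else (cnt + 1) / (bt + 1)
    }
  }
  list(p = P, score = S, tied_pairs = rowSums(SX == 0), degenerate = degenerate)
}
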