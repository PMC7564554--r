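# Independent brute-force oracles, kept deliberately separate from the
# package's own algorithms.

# all permutations of a vector by selection recursion (the package builds
# its permutation table by element insertion instead)
oracle_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], oracle_perms(v[-i]), deparse.level = 0)))
}

# exact two-sided Spearman permutation p: enumerate every permutation of
# y's ranks and count |rho| at least as extreme as observed
oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  P <- oracle_perms(seq_along(ry))
  rhos <- apply(P, 1, function(idx) stats::cor(rx, ry[idx]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-9))
}

# hypergeometric upper tail by exhaustive enumeration of all possible
# query draws from the universe
oracle_hyper_p <- function(universe_n, term_n, query_n, overlap_k) {
  draws <- utils::combn(universe_n, query_n)
  in_term <- colSums(draws <= term_n)  # term = elements 1..term_n
  mean(in_term >= overlap_k)
}

# Cohen's kappa recomputed from the 2x2 contingency table
oracle_kappa <- function(a, b, population) {
  ia <- factor(population %in% a, levels = c(FALSE, TRUE))
  ib <- factor(population %in% b, levels = c(FALSE, TRUE))
  tab <- table(ia, ib)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# binomial upper tail by naive pmf accumulation
oracle_binom_tail <- function(k, n, p) {
  if (k == 0) return(1)
  tot <- 0
  for (i in k:n) tot <- tot + stats::dbinom(i, n, p)
  tot
}
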