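# --- exact permutation null of Spearman's rho at small n -------------------
#
# For tie-free data the null distribution of rho over all n! equally likely
# rank orders depends only on n; it is enumerated once per n and cached.
# rho is computed from the sum of squared rank differences,
#   rho = 1 - 6 * sum(d^2) / (n^3 - n),
# which is exact in the absence of ties.

.spearman_cache <- new.env(parent = emptyenv())

# all permutations of 1..n as an (n! x n) integer matrix, deterministic order
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- permutations_of(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    # insert n at position i
    left <- p[, seq_len(i - 1L), drop = FALSE]
    right <- p[, seq(i, length.out = n - 1L - (i - 1L)), drop = FALSE]
    out[[i]] <- cbind(left, n, right, deparse.level = 0)
  }
  do.call(rbind, out)
}

# tabulated exact null: unique |rho| values with tail probabilities
# P(|rho_perm| >= value)
spearman_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  if (n > 9L) stop("exact null enumerated only for n <= 9")
  perm <- permutations_of(n)
  d2 <- rowSums((perm - rep(seq_len(n), each = nrow(perm)))^2)
  rho <- 1 - 6 * d2 / (n^3 - n)
  ar <- sort(unique(round(abs(rho), 12)), decreasing = TRUE)
  tail_p <- vapply(ar, function(v) mean(abs(rho) >= v - 1e-9), numeric(1))
  null <- list(abs_rho = ar, tail_p = tail_p, n_perm = nrow(perm))
  .spearman_cache[[key]] <- null
  null
}

# two-sided exact tail for an observed rho (tie-free case)
spearman_exact_p <- function(rho_obs, n) {
  null <- spearman_null(n)
  idx <- which(null$abs_rho <= abs(rho_obs) + 1e-9)
  if (!length(idx)) return(1)
  null$tail_p[idx[1L]]
}

#' Spearman correlation with an exact small-sample p-value
#'
#' Computes Spearman's rho from average ranks and a two-sided p-value from
#' the exact permutation distribution of rho: full enumeration of all n!
#' rank orders for tie-free data with n <= 9 (cached per n), a Monte-Carlo
#' permutation p-value when ties are present (fixed internal seed, so the
#' result is deterministic), and the t approximation for n > 9.
#'
#' @param x,y numeric vectors of equal length n >= 4.
#' @param mc_draws Monte-Carlo permutation draws used in the tie case
#'   (default 1e5).
#' @return list with `rho`, `p`, and `method` (one of `"exact"`,
#'   `"monte_carlo"`, `"t_approx"`); `rho` is `NA` (with `method`
#'   `"degenerate"`) when either vector is constant.
#' @export
spearman_exact <- function(x, y, mc_draws = 1e5) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, method = "degenerate"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (!ties && n <= 9) {
    return(list(rho = rho, p = spearman_exact_p(rho, n), method = "exact"))
  }
  if (ties && n <= 9) {
    p <- with_local_seed(104729L, {
      rxc <- rx - mean(rx)
      denom <- sqrt(sum(rxc^2) * sum((ry - mean(ry))^2))
      perm <- vapply(seq_len(mc_draws), function(b) sample(ry),
                     numeric(n))
      rho_b <- colSums(rxc * perm) / denom
      (sum(abs(rho_b) >= abs(rho) - 1e-9) + 1) / (mc_draws + 1)
    })
    return(list(rho = rho, p = p, method = "monte_carlo"))
  }
  tt <- abs(rho) * sqrt((n - 2) / max(1 - rho^2, 1e-300))
  list(rho = rho, p = 2 * stats::pt(-tt, n - 2), method = "t_approx")
}

# run an expression under a fixed RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
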