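#' Count fold-change sign concordance between two datasets
#'
#' A gene is concordant when its log2 fold change has the same (non-zero)
#' sign in both datasets. Genes with a zero fold change in either dataset
#' are indeterminate and excluded from the denominator; genes missing from
#' the reference are dropped and reported.
#'
#' @param internal named numeric vector of internal log2FC (names = gene
#'   ids), or a `de_table`.
#' @param external named numeric vector of reference log2FC.
#' @return list with `n` (informative genes), `k` (concordant), `flags`
#'   (data.frame gene_id, internal, external, concordant), `n_missing`,
#'   `n_indeterminate`.
#' @export
count_concordant <- function(internal, external) {
  if (inherits(internal, "de_table") || is.data.frame(internal)) {
    v <- internal$log2FC; names(v) <- internal$gene_id; internal <- v
  }
  if (is.null(names(internal)) || is.null(names(external)))
    stop("log2FC vectors must be named by gene id")
  common <- intersect(names(internal), names(external))
  n_missing <- length(internal) - length(common)
  if (n_missing)
    message(sprintf("count_concordant: %d gene(s) missing from reference",
                    n_missing))
  fi <- internal[common]; fe <- external[common]
  indet <- fi == 0 | fe == 0
  flags <- data.frame(gene_id = common, internal = unname(fi),
                      external = unname(fe),
                      concordant = ifelse(indet, NA,
                                          sign(fi) == sign(fe)),
                      stringsAsFactors = FALSE)
  list(n = sum(!indet), k = sum(flags$concordant, na.rm = TRUE),
       flags = flags, n_missing = n_missing,
       n_indeterminate = sum(indet))
}

#' Null success probability from a reference DE census
#'
#' The probability that a random lncRNA is differentially expressed in the
#' reference dataset: `(down + up) / total`.
#'
#' @param n_de_down,n_de_up counts of down- and up-regulated reference
#'   genes.
#' @param n_total total reference genes.
#' @return `p0` in (0, 1).
#' @export
estimate_p0 <- function(n_de_down, n_de_up, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_de_down < 0 || n_de_up < 0 || n_de_down + n_de_up > n_total)
    stop("invalid DE census counts")
  p0 <- (n_de_down + n_de_up) / n_total
  if (p0 <= 0 || p0 >= 1)
    stop("degenerate p0 (", p0, "): need 0 < p0 < 1")
  p0
}

#' Exact one-sided binomial concordance test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, summed
#' term by term in closed form (no normal approximation). This is the
#' probability of observing at least the seen number of sign-concordant
#' genes if concordance arose only from the reference dataset's background
#' DE rate.
#'
#' @param k observed concordant genes, `0 <= k <= n`.
#' @param n informative genes compared.
#' @param p0 null success probability in (0, 1).
#' @return The exact tail p-value.
#' @export
binomial_concordance_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (k == 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

#' Validate candidate fold changes against a reference dataset
#'
#' Convenience wrapper: counts sign concordance, estimates the null
#' success probability from the reference DE census, and runs the exact
#' binomial test.
#'
#' @param internal named internal log2FC vector or `de_table` restricted to
#'   the candidates.
#' @param external named reference log2FC vector.
#' @param n_de_down,n_de_up,n_total reference DE census for
#'   [estimate_p0()].
#' @param p0 optional: supply the success probability directly (e.g. a
#'   rounded published value) instead of the census.
#' @return A `concordance_result`: list with `n_candidates`,
#'   `n_concordant`, `p0`, `p0_numerator`, `p0_denominator`, `p_value`,
#'   `flags`.
#' @export
validate_concordance <- function(internal, external, n_de_down = NULL,
                                 n_de_up = NULL, n_total = NULL,
                                 p0 = NULL) {
  cc <- count_concordant(internal, external)
  if (is.null(p0)) {
    if (is.null(n_de_down) || is.null(n_de_up) || is.null(n_total))
      stop("supply either p0 or the reference DE census counts")
    p0 <- estimate_p0(n_de_down, n_de_up, n_total)
    num <- n_de_down + n_de_up; den <- n_total
  } else {
    num <- NA_integer_; den <- NA_integer_
  }
  structure(list(n_candidates = cc$n, n_concordant = cc$k, p0 = p0,
                 p0_numerator = num, p0_denominator = den,
                 p_value = binomial_concordance_test(cc$k, cc$n, p0),
                 flags = cc$flags),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance: %d/%d concordant; p0 = %.4f; exact binomial p = %.6g\n",
    x$n_concordant, x$n_candidates, x$p0, x$p_value))
  invisible(x)
}
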