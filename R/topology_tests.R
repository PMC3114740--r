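# Topology comparison tests ------------------------------------------------
#
# A suboptimal topology is compared to an optimal one character by character.
# The Templeton test is a two-tailed Wilcoxon signed-rank test on the nonzero
# per-character weighted length differences (midranks for tied magnitudes);
# for 20 or fewer nonzero differences the exact null is computed by
# convolution over all sign assignments, otherwise a tie-corrected normal
# approximation with continuity correction is used. The winning-sites test is
# the exact two-tailed binomial sign test on the signs alone.

#' Per-character length differences between two trees
#'
#' @param m a `char_matrix`.
#' @param weights a `weight_scheme`, numeric vector, or `NULL` (equal).
#' @param treeA,treeB `phylo` trees (or Newick) over identical tip sets;
#'   differences are lengths on `treeB` minus lengths on `treeA`.
#' @return a `pairwise_diff` list: `per_char_delta` (weighted), `n_nonzero`.
#' @export
per_character_diffs <- function(m, weights = NULL, treeA, treeB) {
  treeA <- as_phylo_tree(treeA); treeB <- as_phylo_tree(treeB)
  if (!setequal(treeA$tip.label, treeB$tip.label))
    stop("trees cover different tip sets")
  w <- scheme_weights(weights, m)
  scorer <- make_column_scorer(m)
  delta <- w * (scorer(treeB) - scorer(treeA))
  structure(list(per_char_delta = delta,
                 n_nonzero = sum(abs(delta) > 1e-9)),
            class = "pairwise_diff")
}

# Exact null distribution of W+ (sum of positive-signed midranks) by
# convolution. Midranks are multiples of 1/2, so doubling gives integers.
signed_rank_null <- function(ranks2) {
  # ranks2: doubled midranks (integers). Returns probability vector over
  # support 0..sum(ranks2) of W2+ = doubled W+.
  probs <- c(1)
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs)
    probs <- c(probs, rep(0, r)) / 2 + shifted / 2
  }
  probs
}

#' Templeton (Wilcoxon signed-rank) test between two topologies
#'
#' @param diffs a `pairwise_diff` from [per_character_diffs()].
#' @param exact_max largest number of nonzero differences for which the exact
#'   sign-enumeration null is used (default 20).
#' @return list with `statistic` (W+, the sum of positive midranks),
#'   `n_nonzero`, `p` (two-tailed), and `method` (`"exact"` or `"normal"`).
#'   With no nonzero differences `p = 1`.
#' @export
templeton_test <- function(diffs, exact_max = 20) {
  d <- diffs$per_char_delta
  d <- d[abs(d) > 1e-9]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, n_nonzero = 0L, p = 1, method = "exact"))
  r <- rank(abs(d))                      # midranks
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    probs <- signed_rank_null(ranks2)
    w2 <- 2 * w_plus; mu2 <- sum(ranks2) / 2
    dev <- abs(w2 - mu2)
    support <- seq_along(probs) - 1
    p <- sum(probs[abs(support - mu2) >= dev - 1e-9])
    return(list(statistic = w_plus, n_nonzero = n, p = min(1, p),
                method = "exact"))
  }
  # tie-corrected normal approximation with continuity correction
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2)
  list(statistic = w_plus, n_nonzero = n, p = min(1, 2 * pnorm(-z)),
       method = "normal")
}

#' Winning-sites (sign) test between two topologies
#'
#' Exact two-tailed binomial test on the signs of the nonzero per-character
#' differences with success probability 1/2.
#'
#' @param diffs a `pairwise_diff` from [per_character_diffs()].
#' @return two-tailed p value (1 when no characters differ).
#' @export
winning_sites_test <- function(diffs) {
  d <- diffs$per_char_delta
  d <- d[abs(d) > 1e-9]
  n <- length(d)
  if (n == 0) return(1)
  k <- sum(d > 0)
  # two-tailed: sum binomial(n, 1/2) probabilities not exceeding P(k)
  probs <- dbinom(0:n, n, 0.5)
  min(1, sum(probs[probs <= probs[k + 1] + 1e-12]))
}

#' Compare a suboptimal topology against an optimal one
#'
#' Convenience wrapper running [per_character_diffs()], [templeton_test()]
#' and [winning_sites_test()].
#'
#' @inheritParams per_character_diffs
#' @return list with `delta_total`, `n_nonzero`, `templeton` (statistic, p),
#'   `p_templeton`, `p_winning_sites`.
#' @export
topology_test <- function(m, weights = NULL, treeA, treeB) {
  diffs <- per_character_diffs(m, weights, treeA, treeB)
  tt <- templeton_test(diffs)
  list(delta_total = sum(diffs$per_char_delta),
       n_nonzero = diffs$n_nonzero,
       templeton = tt,
       p_templeton = tt$p,
       p_winning_sites = winning_sites_test(diffs))
}
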