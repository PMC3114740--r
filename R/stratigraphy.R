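# Stratigraphic congruence -------------------------------------------------
#
# Fit between a topology and the fossil record is measured through ghost
# lineages: each internal node is dated at the oldest first-appearance datum
# (FAD) among its descendants (the minimum age consistent with the record),
# and every branch whose parent is older than its child implies a gap. The
# summed gap is the minimum implied gap (MIG). MSM* = G_min / MIG scales MIG
# by the best conceivable value (the FAD range, achieved by a perfectly
# age-ordered pectinate tree) and is the consistency index of an irreversible
# stratigraphic character; GER = (G_max - MIG) / (G_max - G_min) scales it
# between best and worst (G_max = sum of distances from the oldest FAD) like
# a retention index. Significance comes from permuting the FADs across tips.

#' Construct / validate a taxon age table
#'
#' @param taxon character vector of taxon labels.
#' @param fad first appearance datum, Ma (>= 0). Missing values are allowed
#'   only for extant taxa and are set to 0.
#' @param lad last appearance datum, Ma (defaults to `fad`); must not exceed
#'   the FAD.
#' @param extant logical; extant taxa are forced to FAD 0 (the present day).
#' @return a data.frame of class `age_table`.
#' @export
age_table <- function(taxon, fad, lad = NULL, extant = FALSE) {
  n <- length(taxon)
  extant <- rep_len(as.logical(extant), n)
  fad <- as.numeric(rep_len(fad, n))
  fad[extant] <- 0
  if (is.null(lad)) lad <- fad
  lad <- as.numeric(rep_len(lad, n))
  lad[is.na(lad)] <- fad[is.na(lad)]
  lad[extant] <- 0
  bad <- which(is.na(fad) | fad < 0 | lad < 0 | lad > fad)
  if (length(bad))
    stop("invalid ages (negative, missing for a fossil, or LAD > FAD) for: ",
         paste(taxon[bad], collapse = ", "))
  if (anyDuplicated(taxon)) stop("duplicated taxa in age table")
  structure(data.frame(taxon = as.character(taxon), fad = fad, lad = lad,
                       extant = extant, stringsAsFactors = FALSE),
            class = c("age_table", "data.frame"))
}

ages_for_tips <- function(tree, ages) {
  idx <- match(tree$tip.label, ages$taxon)
  if (anyNA(idx)) stop("tip(s) missing from age table: ",
                       paste(tree$tip.label[is.na(idx)], collapse = ", "))
  setNames(ages$fad[idx], tree$tip.label)
}

#' Minimum node ages implied by tip first appearances
#'
#' Each internal node is dated at the maximum FAD over its tip descendants:
#' the youngest age consistent with the fossil record.
#'
#' @param tree a rooted `phylo` tree or Newick string (polytomies allowed).
#' @param ages an [age_table()] covering every tip.
#' @return named numeric vector of ages (Ma) for all nodes, tips included;
#'   internal nodes are named `"node<id>"` by their ape number.
#' @export
node_min_ages <- function(tree, ages) {
  tree <- as_phylo_tree(tree)
  fad <- ages_for_tips(tree, ages)
  et <- phylo_to_et(tree)
  cp <- compact_postorder(et)
  n_node <- cp$n_node
  age <- numeric(n_node)
  age[seq_len(et$n_tip)] <- fad
  for (i in seq_len(nrow(cp$edge))) {
    p <- cp$edge[i, 1]; ch <- cp$edge[i, 2]
    age[p] <- max(age[p], age[ch])
  }
  names(age) <- c(et$tip.label, paste0("node", seq_len(n_node - et$n_tip) + et$n_tip))
  age
}

#' Minimum implied gap (total ghost-lineage duration)
#'
#' @inheritParams node_min_ages
#' @return MIG in Ma: the sum over all branches of the parent's minimum age
#'   minus the child's (tips dated at their FAD).
#' @export
mig <- function(tree, ages) {
  sum(per_branch_ghosts(tree, ages)$ghost)
}

#' Per-branch ghost-lineage durations
#'
#' @inheritParams node_min_ages
#' @return data.frame with one row per branch: `node` (child label), `ghost`
#'   (Ma of implied unsampled history on that branch).
#' @export
per_branch_ghosts <- function(tree, ages) {
  tree <- as_phylo_tree(tree)
  fad <- ages_for_tips(tree, ages)
  et <- phylo_to_et(tree)
  cp <- compact_postorder(et)
  age <- numeric(cp$n_node)
  age[seq_len(et$n_tip)] <- fad
  for (i in seq_len(nrow(cp$edge))) {
    p <- cp$edge[i, 1]; ch <- cp$edge[i, 2]
    age[p] <- max(age[p], age[ch])
  }
  labs <- c(et$tip.label, paste0("node", seq_len(cp$n_node - et$n_tip) + et$n_tip))
  data.frame(node = labs[cp$edge[, 2]],
             ghost = age[cp$edge[, 1]] - age[cp$edge[, 2]],
             stringsAsFactors = FALSE)
}

strat_bounds <- function(fads) {
  list(g_min = max(fads) - min(fads),
       g_max = sum(max(fads) - fads))
}

#' Gap excess ratio
#'
#' `GER = (G_max - MIG) / (G_max - G_min)`, where `G_min` is the FAD range
#' (the MIG of a perfectly age-ordered pectinate tree) and `G_max` the sum of
#' all distances from the oldest FAD (every tip hanging directly from the
#' oldest lineage). 1 = perfect congruence, 0 = worst possible.
#'
#' @inheritParams node_min_ages
#' @return GER in `[0, 1]`.
#' @export
ger <- function(tree, ages) {
  tree <- as_phylo_tree(tree)
  fads <- ages_for_tips(tree, ages)
  b <- strat_bounds(fads)
  if (b$g_min == 0) stop("GER undefined: all first appearances are equal")
  (b$g_max - mig(tree, ages)) / (b$g_max - b$g_min)
}

#' Modified Manhattan stratigraphic measure (MSM*)
#'
#' `MSM* = G_min / MIG`: the minimum possible length of the irreversible
#' stratigraphic character divided by its length on this tree — its
#' consistency index. Defined as 1 when MIG is 0 (all tips the same age in a
#' perfectly congruent record).
#'
#' @inheritParams node_min_ages
#' @return MSM* in `(0, 1]`.
#' @export
msm_star <- function(tree, ages) {
  tree <- as_phylo_tree(tree)
  fads <- ages_for_tips(tree, ages)
  g_min <- max(fads) - min(fads)
  m <- mig(tree, ages)
  if (m == 0) {
    if (g_min > 0) stop("internal error: MIG 0 with a positive FAD range")
    return(1)
  }
  g_min / m
}

#' The irreversible stratigraphic character of an age table
#'
#' One state per distinct FAD, ordered oldest to youngest; transformations
#' toward younger states cost the age difference in Ma, reversals toward
#' older states are forbidden. The Sankoff length of this character on any
#' tree equals the tree's MIG.
#'
#' @param ages an [age_table()].
#' @return list with `spec` (a [char_spec()] of kind `"irreversible"`, state
#'   symbols `0-9` then `A-T` for additional states), `tip_states` (named
#'   symbol per taxon), and `state_ages` (named Ma per symbol).
#' @export
stratigraphic_character <- function(ages) {
  fads <- sort(unique(ages$fad), decreasing = TRUE)
  if (length(fads) < 2) stop("need at least two distinct first appearances")
  symbols <- c(0:9, LETTERS)[seq_along(fads)]
  if (length(fads) > length(c(0:9, LETTERS)))
    stop("more distinct ages than available state symbols")
  S <- length(fads)
  cost <- outer(fads, fads, "-")     # cost[i, j] = age_i - age_j
  cost[cost < 0] <- Inf              # no reversals toward older states
  diag(cost) <- 0
  spec <- char_spec("irreversible", as.character(symbols), weight = 1, cost = cost)
  tip_states <- setNames(as.character(symbols[match(ages$fad, fads)]), ages$taxon)
  list(spec = spec,
       tip_states = tip_states,
       state_ages = setNames(fads, symbols))
}

#' Permutation test of stratigraphic congruence
#'
#' Permutes the multiset of tip FADs across tips and compares the observed
#' MSM* with the permuted values: `p = (1 + #{MSM*_perm >= MSM*_obs}) /
#' (n_perm + 1)`, so the smallest attainable p with 999 permutations is
#' 0.001.
#'
#' @inheritParams node_min_ages
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list with `p_value`, `observed` MSM*, and the vector of permuted
#'   MSM* values.
#' @export
strat_permutation_test <- function(tree, ages, n_perm = 999, seed = 1) {
  tree <- as_phylo_tree(tree)
  fads <- ages_for_tips(tree, ages)
  if (length(unique(fads)) == 1) {
    return(list(p_value = 1, observed = 1, permuted = rep(1, n_perm)))
  }
  obs <- msm_star(tree, ages)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    shuffled <- sample(unname(fads))
    at <- age_table(names(fads), shuffled, extant = shuffled == 0)
    msm_star(tree, at)
  }, numeric(1)))
  list(p_value = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1),
       observed = obs, permuted = perm)
}

#' Full stratigraphic fit of a tree
#'
#' @inheritParams strat_permutation_test
#' @return a `strat_fit` list: `mig`, `g_min`, `g_max`, `msm_star`, `ger`,
#'   `p_value` (NULL unless `n_perm > 0`), and `per_branch_ghost`.
#' @export
strat_fit <- function(tree, ages, n_perm = 0, seed = 1) {
  tree <- as_phylo_tree(tree)
  fads <- ages_for_tips(tree, ages)
  b <- strat_bounds(fads)
  m <- mig(tree, ages)
  structure(list(
    mig = m, g_min = b$g_min, g_max = b$g_max,
    msm_star = msm_star(tree, ages),
    ger = if (b$g_min > 0) (b$g_max - m) / (b$g_max - b$g_min) else NA_real_,
    p_value = if (n_perm > 0)
      strat_permutation_test(tree, ages, n_perm, seed)$p_value else NULL,
    per_branch_ghost = per_branch_ghosts(tree, ages)
  ), class = "strat_fit")
}

#' @export
print.strat_fit <- function(x, ...) {
  cat(sprintf("strat_fit: MIG %.2f Ma (G_min %.2f, G_max %.2f), MSM* %.3f, GER %.3f",
              x$mig, x$g_min, x$g_max, x$msm_star, x$ger))
  if (!is.null(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
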