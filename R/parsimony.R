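# Parsimony scoring -------------------------------------------------------
#
# All lengths come from one generalized Sankoff dynamic programme (compiled,
# see src/sankoff.cpp): unordered characters use unit costs (equivalent to
# Fitch counting), ordered characters cost |i - j| state-order units, and
# irreversible characters use an explicit asymmetric table. Polymorphic and
# missing cells enter as state sets with zero internal cost, so a fully
# missing tip never adds steps.

cost_matrix_for <- function(spec) {
  S <- length(spec$state_space)
  m <- switch(spec$kind,
    unordered = 1 - diag(S),
    ordered = abs(outer(seq_len(S), seq_len(S), "-")),
    irreversible = {
      cm <- spec$cost
      cm[!is.finite(cm)] <- BIG
      cm
    })
  storage.mode(m) <- "double"
  m
}

tip_cost_matrix <- function(masks, S) {
  # S x n matrix: 0 where the state is allowed, BIG otherwise
  tc <- matrix(BIG, S, length(masks))
  for (s in seq_len(S)) {
    allowed <- bitwAnd(bitwShiftR(masks, s - 1L), 1L) == 1L
    tc[s, allowed] <- 0
  }
  tc
}

# Precompute everything scoring needs for repeated tree evaluation.
# Returns a function(et_or_phylo) -> numeric vector of per-character raw
# (unweighted) lengths, valid for trees whose tips are any subset of m$taxa.
# Tip costs and transformation costs are flattened once so the per-tree call
# stays cheap inside search loops.
make_column_scorer <- function(m) {
  nc <- n_char(m)
  S_per <- integer(nc)
  tip_list <- vector("list", nc)
  cost_list <- vector("list", nc)
  for (c_i in seq_len(nc)) {
    spec <- m$specs[[c_i]]
    S_per[c_i] <- length(spec$state_space)
    tip_list[[c_i]] <- tip_cost_matrix(m$masks[[c_i]], S_per[c_i])
    cost_list[[c_i]] <- cost_matrix_for(spec)
  }
  tip_flat <- as.numeric(unlist(tip_list, use.names = FALSE))
  cost_flat <- as.numeric(unlist(cost_list, use.names = FALSE))
  tip_off <- as.integer(cumsum(c(0, vapply(tip_list, length, 1)))[seq_len(nc)])
  cost_off <- as.integer(cumsum(c(0, S_per^2))[seq_len(nc)])
  taxa <- m$taxa
  identity_map <- as.integer(seq_along(taxa))
  function(tree) {
    et <- if (inherits(tree, "phylo")) phylo_to_et(tree) else tree
    cp <- compact_postorder(et)
    tipmap <- if (identical(et$tip.label, taxa)) identity_map else {
      tm <- match(et$tip.label, taxa)
      if (anyNA(tm)) stop("tree tip(s) missing from matrix: ",
                          paste(et$tip.label[is.na(tm)], collapse = ", "))
      as.integer(tm)
    }
    sankoff_lengths_cpp(cp$edge, cp$n_tip, cp$n_node, S_per,
                        tip_flat, tip_off, cost_flat, cost_off, tipmap)
  }
}

#' Parsimony length of a single character on a tree
#'
#' Minimum total transformation cost over all internal-node state assignments:
#' unit costs for unordered characters, state-order distances for ordered
#' ones, and the declared asymmetric table for irreversible ones. Polymorphic
#' cells contribute the cheapest member of their state set; missing cells
#' (full state set) contribute nothing.
#'
#' @param tree a `phylo` tree (or Newick string) whose tips all have cells.
#' @param column a named list/vector of state sets (names = taxa), or a named
#'   integer bitmask vector.
#' @param spec a [char_spec()].
#' @return minimum cost in (unweighted) steps.
#' @export
character_length <- function(tree, column, spec) {
  tree <- as_phylo_tree(tree)
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 tips")
  masks <- column_masks(column, spec, tree$tip.label)
  m <- new_char_matrix(tree$tip.label, list(masks), list(spec))
  out <- make_column_scorer(m)(tree)[1]
  if (out >= BIG / 2) stop("no admissible state assignment (cost table forbids all)")
  out
}

#' Minimum conceivable length of a character over all trees
#'
#' The best-case length used for homoplasy and between-character scaling:
#' for unordered characters, one fewer than the number of distinct fixed
#' (singleton-cell) states observed; for ordered characters, the span between
#' the smallest and largest fixed states in state-order units. Cells with the
#' full state set (missing) are ignored, and polymorphic cells are never
#' forced to contribute steps.
#'
#' @param column named state-set list/vector or named bitmask vector.
#' @param spec a [char_spec()].
#' @return minimum length in steps.
#' @export
min_length <- function(column, spec) {
  if (is.numeric(column) && !is.null(names(column))) {
    masks <- as.integer(column)
  } else {
    masks <- column_masks(column, spec, names(column))
  }
  S <- length(spec$state_space)
  fixed <- masks[vapply(masks, mask_size, 1L) == 1L & masks != full_mask(S)]
  if (!length(fixed)) return(0)
  idx <- log2(fixed) + 1  # singleton masks are powers of two
  idx <- unique(as.integer(round(idx)))
  switch(spec$kind,
    unordered = length(idx) - 1,
    ordered = ,
    irreversible = max(idx) - min(idx))
}

min_lengths_of <- function(m) {
  vapply(seq_len(n_char(m)), function(c_i)
    min_length(setNames(m$masks[[c_i]], m$taxa), m$specs[[c_i]]), numeric(1))
}

# Weight schemes -----------------------------------------------------------

#' Between-character scaling weights
#'
#' Down-weights ordered multistate characters by the inverse of their minimum
#' length so every variable character can contribute at most one step at its
#' best: an ordered character with observed state span `s > 0` receives weight
#' `1/s`; unordered multistate, binary and invariant characters keep weight 1.
#'
#' @param m a `char_matrix`.
#' @return a `weight_scheme` with mode `"scaled"`.
#' @export
scaling_weights <- function(m) {
  mins <- min_lengths_of(m)
  w <- rep(1, n_char(m))
  for (c_i in seq_len(n_char(m))) {
    if (m$specs[[c_i]]$kind == "ordered" && mins[c_i] > 0)
      w[c_i] <- 1 / mins[c_i]
  }
  structure(list(mode = "scaled", k = NULL, per_char = w),
            class = "weight_scheme")
}

#' Construct a weighting scheme
#'
#' @param mode `"equal"` (all weights 1), `"scaled"` (between-character
#'   scaling, see [scaling_weights()]), or `"implied"` (Goloboff-style concave
#'   fit `sum(h / (h + k))` computed on scaled steps).
#' @param m the `char_matrix` the scheme applies to (needed for `"scaled"` and
#'   `"implied"`).
#' @param k concavity constant for implied weighting (default 3).
#' @return a `weight_scheme`.
#' @export
weight_scheme <- function(mode = c("equal", "scaled", "implied"), m = NULL, k = 3) {
  mode <- match.arg(mode)
  if (mode == "equal") {
    per <- if (is.null(m)) NULL else rep(1, n_char(m))
    return(structure(list(mode = "equal", k = NULL, per_char = per),
                     class = "weight_scheme"))
  }
  if (is.null(m)) stop("scaled/implied schemes need the character matrix")
  ws <- scaling_weights(m)
  if (mode == "implied") {
    if (!is.numeric(k) || k <= 0) stop("k must be positive")
    ws$mode <- "implied"
    ws$k <- k
  }
  ws
}

scheme_weights <- function(weights, m) {
  if (is.null(weights)) return(rep(1, n_char(m)))
  if (inherits(weights, "weight_scheme")) {
    if (is.null(weights$per_char)) return(rep(1, n_char(m)))
    if (length(weights$per_char) != n_char(m))
      stop("weight scheme built for a different matrix")
    return(weights$per_char)
  }
  if (is.numeric(weights) && length(weights) == n_char(m)) return(weights)
  stop("weights must be a weight_scheme or a per-character numeric vector")
}

#' Weighted parsimony length of a tree
#'
#' @param tree a `phylo` tree or Newick string; its tips must be a subset of
#'   the matrix taxa.
#' @param m a `char_matrix`.
#' @param weights a `weight_scheme`, a per-character numeric vector, or `NULL`
#'   for equal weights.
#' @return a `length_report`: list with `per_char_length` (weighted steps per
#'   character), `total` (their sum), and `per_char_h` (extra steps beyond
#'   each character's minimum, in unweighted units).
#' @export
tree_length <- function(tree, m, weights = NULL) {
  w <- scheme_weights(weights, m)
  raw <- make_column_scorer(m)(as_phylo_tree(tree))
  if (any(raw >= BIG / 2)) stop("no admissible assignment for some character")
  mins <- min_lengths_of(m)
  structure(list(per_char_length = w * raw,
                 total = sum(w * raw),
                 per_char_h = raw - mins),
            class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat(sprintf("length_report: total %.4f weighted steps over %d characters (homoplasy %.2f raw steps)\n",
              x$total, length(x$per_char_length), sum(x$per_char_h)))
  invisible(x)
}

#' Implied-weighting score of a tree
#'
#' The concave objective `sum_c h_c / (h_c + k)`, where `h_c` is character
#' `c`'s homoplasy (steps beyond its minimum) measured on between-character
#' scaled steps, so an ordered character's homoplasy is expressed in
#' binary-equivalent units. Lower is better; a homoplasy-free tree scores 0.
#'
#' @inheritParams tree_length
#' @param k concavity constant (> 0); larger `k` is more tolerant of
#'   homoplasy.
#' @return the implied-weighting score (a real in `[0, n_char)`).
#' @export
implied_weight_score <- function(tree, m, k = 3) {
  if (k <= 0) stop("k must be positive")
  sw <- scaling_weights(m)$per_char
  raw <- make_column_scorer(m)(as_phylo_tree(tree))
  if (any(raw >= BIG / 2)) stop("no admissible assignment for some character")
  h <- sw * (raw - min_lengths_of(m))
  sum(h / (h + k))
}

# A tree -> score function for the search machinery. `weights` may be a
# weight_scheme (implied mode switches the objective) or a numeric vector.
parsimony_objective <- function(m, weights = NULL) {
  scorer <- make_column_scorer(m)
  if (inherits(weights, "weight_scheme") && weights$mode == "implied") {
    sw <- weights$per_char
    k <- weights$k
    mins <- min_lengths_of(m)
    return(function(tree) {
      h <- sw * (scorer(tree) - mins)
      sum(h / (h + k))
    })
  }
  w <- scheme_weights(weights, m)
  function(tree) sum(w * scorer(tree))
}
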