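# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: trees are enumerated as nested
# lists rendered to Newick, parsimony lengths come from a plain recursive
# Sankoff over ape edge matrices, and monophyly is checked with ape.

# Recursive Sankoff: minimum cost of one character on a rooted phylo.
# masks: named integer bitmasks over states 1..S; cm: S x S cost matrix.
ref_sankoff <- function(tree, masks, S, cm) {
  ntip <- length(tree$tip.label)
  rec <- function(node) {
    if (node <= ntip) {
      v <- rep(Inf, S)
      mask <- masks[[tree$tip.label[node]]]
      v[bitwAnd(bitwShiftR(mask, 0:(S - 1)), 1L) == 1L] <- 0
      return(v)
    }
    v <- rep(0, S)
    for (k in tree$edge[tree$edge[, 1] == node, 2]) {
      ck <- rec(k)
      v <- v + vapply(seq_len(S), function(s) min(ck + cm[s, ]), numeric(1))
    }
    v
  }
  min(rec(ntip + 1L))
}

ref_cost_matrix <- function(kind, S) {
  if (kind == "unordered") 1 - diag(S) else abs(outer(seq_len(S), seq_len(S), "-"))
}

# All unrooted topologies over `labels`, as phylo trees: nested-list insertion
# with the first label fixed as the outgroup of a rooted representation.
ref_all_topologies <- function(labels) {
  to_nwk <- function(x) {
    if (is.character(x)) x else paste0("(", to_nwk(x[[1]]), ",", to_nwk(x[[2]]), ")")
  }
  insert_all <- function(node, lab) {
    out <- list(list(node, lab))
    if (is.list(node)) {
      for (v in insert_all(node[[1]], lab))
        out <- c(out, list(list(v, node[[2]])))
      for (v in insert_all(node[[2]], lab))
        out <- c(out, list(list(node[[1]], v)))
    }
    out
  }
  rest <- list(labels[2])
  for (lab in labels[-(1:2)])
    rest <- unlist(lapply(rest, insert_all, lab), recursive = FALSE)
  lapply(rest, function(r)
    ape::read.tree(text = paste0("(", labels[1], ",", to_nwk(r), ");")))
}

# Unrooted monophyly via ape: root at a tip outside the clade, then test.
ref_is_clade <- function(tree, clade) {
  out_tip <- setdiff(tree$tip.label, clade)[1]
  ape::is.monophyletic(ape::root(tree, outgroup = out_tip), clade)
}

# Total reference length of a small matrix on a tree.
ref_matrix_length <- function(tree, m, weights = NULL) {
  w <- if (is.null(weights)) rep(1, length(m$specs)) else weights
  total <- 0
  for (c_i in seq_along(m$specs)) {
    spec <- m$specs[[c_i]]
    S <- length(spec$state_space)
    masks <- as.list(setNames(m$masks[[c_i]], m$taxa))
    total <- total + w[c_i] * ref_sankoff(tree, masks, S,
                                          ref_cost_matrix(spec$kind, S))
  }
  total
}

# A random small matrix over the given taxa: masks drawn over S states,
# occasionally polymorphic or missing, mixed ordered/unordered specs.
random_small_matrix <- function(taxa, n_chars, max_states = 3) {
  n <- length(taxa)
  specs <- vector("list", n_chars)
  masks <- vector("list", n_chars)
  for (c_i in seq_len(n_chars)) {
    S <- sample(2:max_states, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    specs[[c_i]] <- char_spec(kind, as.character(0:(S - 1)))
    vals <- seq_len(2^S - 1)
    popcount <- vapply(vals, function(v) sum(bitwAnd(bitwShiftR(v, 0:(S - 1)), 1L)), 1L)
    mk <- sample(vals, n, replace = TRUE,
                 prob = ifelse(popcount == 1, 6, 1))        # mostly fixed cells
    masks[[c_i]] <- as.integer(mk)
  }
  stratpars:::new_char_matrix(taxa, masks, specs)
}

sig_of <- function(tree) stratpars:::topology_signature(tree)

trees_identical_unrooted <- function(a, b) sig_of(a) == sig_of(b)

# brute-force MPR oracle: enumerate every internal (and uncertain-tip) state
# assignment and keep the minimum-cost ones
ref_mprs <- function(tree, masks, S, cm) {
  ntip <- length(tree$tip.label)
  n_node <- ntip + tree$Nnode
  choices <- lapply(seq_len(n_node), function(nd) {
    if (nd <= ntip) {
      mask <- masks[[tree$tip.label[nd]]]
      which(bitwAnd(bitwShiftR(mask, 0:(S - 1)), 1L) == 1L)
    } else seq_len(S)
  })
  grids <- as.matrix(expand.grid(choices))
  cost <- rowSums(vapply(seq_len(nrow(tree$edge)), function(e)
    cm[cbind(grids[, tree$edge[e, 1]], grids[, tree$edge[e, 2]])],
    numeric(nrow(grids))))
  best <- min(cost)
  list(length = best, assignments = grids[cost <= best + 1e-9, , drop = FALSE])
}
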