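# Tree utilities ----------------------------------------------------------
#
# Search and scoring work on a light edge-list representation ("etree"):
# tips are numbered 1..n_tip (matching tip.label), internal nodes carry
# arbitrary integer ids > n_tip (not necessarily contiguous, which makes tip
# attachment and subtree pruning renumbering-free), and the root is binary.
# Trees are compacted to ape's numbering convention on conversion to phylo or
# before scoring. Parsimony scores of reversible characters do not depend on
# the rooting, so the search treats topologies as unrooted and identifies them
# by their bipartition (split) sets.

etree <- function(edge, n_tip, tip_label) {
  list(edge = edge, n_tip = as.integer(n_tip), tip.label = tip_label)
}

et_root <- function(et) {
  parents <- unique(et$edge[, 1])
  r <- parents[!(parents %in% et$edge[, 2])]
  if (length(r) != 1L) stop("tree has no unique root")
  r
}

# children index: list over node ids (sparse via environment is overkill;
# max id stays small) — returns function(node) -> child edge rows
et_child_rows <- function(et) {
  split(seq_len(nrow(et$edge)), factor(et$edge[, 1], levels = sort(unique(et$edge[, 1]))))
}

# Edge rows in postorder (every edge below a node precedes the node's own
# incoming edge). Iterative DFS over a stack; node ids index plain vectors.
postorder_rows <- function(edge, root) {
  n_edge <- nrow(edge)
  max_id <- max(edge)
  # adjacency: rows grouped by parent, contiguous in `by_parent`
  ord <- order(edge[, 1])
  parents_sorted <- edge[ord, 1]
  first <- integer(max_id); count <- integer(max_id)
  for (i in seq_len(n_edge)) {
    p <- parents_sorted[i]
    if (count[p] == 0L) first[p] <- i
    count[p] <- count[p] + 1L
  }
  emit <- integer(n_edge); ei <- n_edge
  stack <- integer(n_edge + 1L); stack[1] <- root; sp <- 1L
  # reverse-preorder traversal emitted back-to-front gives postorder
  while (sp > 0L) {
    node <- stack[sp]; sp <- sp - 1L
    k <- count[node]
    if (k > 0L) {
      rows <- ord[seq.int(first[node], length.out = k)]
      for (r in rows) {
        emit[ei] <- r; ei <- ei - 1L
        sp <- sp + 1L; stack[sp] <- edge[r, 2]
      }
    }
  }
  emit
}

# Renumber internal ids to n_tip+1 .. n_node (root first), returning the
# compacted postordered edge matrix ready for the scoring kernel.
compact_postorder <- function(et) {
  root <- et_root(et)
  rows <- postorder_rows(et$edge, root)
  edge <- et$edge[rows, , drop = FALSE]
  internal_ids <- c(root, setdiff(unique(as.vector(edge)), c(seq_len(et$n_tip), root)))
  map <- setNames(seq_along(internal_ids) + et$n_tip, as.character(internal_ids))
  relabel <- function(v) {
    idx <- !(v %in% seq_len(et$n_tip))
    v[idx] <- map[as.character(v[idx])]
    v
  }
  edge2 <- cbind(relabel(edge[, 1]), relabel(edge[, 2]))
  storage.mode(edge2) <- "integer"
  list(edge = edge2, n_tip = et$n_tip, n_node = et$n_tip + length(internal_ids))
}

et_to_phylo <- function(et) {
  cp <- compact_postorder(et)
  # phylo wants root = n_tip + 1; our compaction puts the root there already
  ph <- list(edge = cp$edge[rev(seq_len(nrow(cp$edge))), , drop = FALSE],
             tip.label = et$tip.label,
             Nnode = cp$n_node - cp$n_tip)
  class(ph) <- "phylo"
  ph
}

phylo_to_et <- function(ph) {
  storage.mode(ph$edge) <- "integer"
  etree(ph$edge, length(ph$tip.label), ph$tip.label)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree)) return(read_newick(tree))
  stop("expected a phylo tree or a Newick string")
}

# tip ids (integers) below every node, as a list indexed by node id
tips_below_list <- function(et) {
  root <- et_root(et)
  rows <- postorder_rows(et$edge, root)
  out <- vector("list", max(et$edge))
  for (i in seq_len(et$n_tip)) out[[i]] <- i
  for (r in rows) {
    p <- et$edge[r, 1]; ch <- et$edge[r, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Splits -------------------------------------------------------------------

split_key <- function(side, all_labels) {
  ref <- min(all_labels)
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\r")
}

#' Nontrivial bipartitions of a tree
#'
#' Returns the unrooted splits (bipartitions with at least two tips on each
#' side) of a tree, encoded canonically so that split sets from differently
#' rooted or ordered trees compare directly.
#'
#' @param tree a `phylo` tree or Newick string.
#' @return character vector of canonical split keys.
#' @export
tree_splits <- function(tree) {
  et <- phylo_to_et(as_phylo_tree(tree))
  labs <- et$tip.label
  n <- et$n_tip
  below <- tips_below_list(et)
  root <- et_root(et)
  internals <- unique(et$edge[, 1])
  keys <- character(0)
  for (nd in internals) {
    tips <- below[[nd]]
    sz <- length(tips)
    if (sz >= 2L && sz <= n - 2L)
      keys <- c(keys, split_key(labs[tips], labs))
  }
  unique(keys)
}

#' Test whether a tip set forms a clade (unrooted monophyly)
#'
#' @param tree a `phylo` tree or Newick string.
#' @param clade character vector of tip labels.
#' @return `TRUE` if the bipartition separating `clade` from the remaining
#'   tips is present in the tree. Trivial groupings (fewer than two members,
#'   or all but at most one tip) are reported as present.
#' @export
has_clade <- function(tree, clade) {
  tree <- as_phylo_tree(tree)
  labs <- tree$tip.label
  if (!all(clade %in% labs)) stop("clade contains unknown tips")
  n <- length(labs); k <- length(unique(clade))
  if (k < 2L || k > n - 2L) return(TRUE)
  split_key(clade, labs) %in% tree_splits(tree)
}

#' Restrict a tree to a taxon subset
#'
#' Drops all other tips and suppresses the resulting degree-two nodes.
#'
#' @param tree a `phylo` tree or Newick string.
#' @param tips tip labels to keep.
#' @return a `phylo` tree.
#' @export
restrict_tree <- function(tree, tips) {
  tree <- as_phylo_tree(tree)
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) stop("tips absent from tree: ", paste(missing, collapse = ", "))
  ape::keep.tip(tree, tips)
}

# identical unrooted topology?
same_topology <- function(a, b) {
  a <- as_phylo_tree(a); b <- as_phylo_tree(b)
  setequal(a$tip.label, b$tip.label) &&
    setequal(tree_splits(a), tree_splits(b))
}

topology_signature <- function(tree) {
  paste(sort(tree_splits(tree)), collapse = ";")
}

# Consensus ----------------------------------------------------------------

rooted_clades <- function(tree) {
  et <- phylo_to_et(as_phylo_tree(tree))
  below <- tips_below_list(et)
  root <- et_root(et)
  nodes <- unique(et$edge[, 1])
  lapply(setdiff(nodes, root), function(nd)
    sort(et$tip.label[below[[nd]]]))
}

build_tree_from_clades <- function(labels, clades) {
  # clades: list of sorted label vectors, pairwise compatible, proper subsets
  clades <- clades[order(-vapply(clades, length, 1L))]
  grow <- function(members, remaining_clades) {
    inside <- remaining_clades[vapply(remaining_clades, function(cl)
      all(cl %in% members), TRUE)]
    used <- character(0)
    parts <- character(0)
    while (length(inside)) {
      cl <- inside[[1]]
      inside <- inside[-1]
      if (any(cl %in% used)) next
      sub <- inside[vapply(inside, function(x) all(x %in% cl), TRUE)]
      parts <- c(parts, grow(cl, sub))
      used <- c(used, cl)
      inside <- inside[!vapply(inside, function(x) all(x %in% cl), TRUE)]
    }
    singles <- setdiff(members, used)
    children <- c(parts, singles)
    if (length(children) == 1L) children else
      paste0("(", paste(children, collapse = ","), ")")
  }
  proper <- clades[vapply(clades, function(cl)
    length(cl) < length(labels) && length(cl) >= 2L, TRUE)]
  nwk <- paste0(grow(sort(labels), proper), ";")
  ape::read.tree(text = nwk)
}

consensus_clade_counts <- function(trees) {
  trees <- lapply(trees, as_phylo_tree)
  labs <- trees[[1]]$tip.label
  for (t in trees) if (!setequal(t$tip.label, labs))
    stop("consensus requires identical tip sets")
  keys <- unlist(lapply(trees, function(t)
    vapply(rooted_clades(t), paste, "", collapse = "\r")))
  table(keys)
}

#' Strict consensus of a set of trees
#'
#' Retains exactly the clades present in every input tree (trees are treated
#' as rooted, as written).
#'
#' @param trees list of `phylo` trees over an identical tip set.
#' @return a `phylo` tree, possibly with polytomies.
#' @export
strict_consensus <- function(trees) {
  trees <- lapply(trees, as_phylo_tree)
  counts <- consensus_clade_counts(trees)
  keep <- names(counts)[counts == length(trees)]
  build_tree_from_clades(trees[[1]]$tip.label,
                         lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]]))
}

#' Majority-rule consensus of a set of trees
#'
#' Retains clades occurring in more than `threshold` of the trees.
#'
#' @param trees list of `phylo` trees over an identical tip set.
#' @param threshold clade-frequency cutoff as a fraction (default 0.5); clades
#'   must appear in strictly more than this fraction of trees.
#' @return a `phylo` tree, possibly with polytomies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (threshold < 0.5) stop("threshold below 0.5 can select incompatible clades")
  trees <- lapply(trees, as_phylo_tree)
  counts <- consensus_clade_counts(trees)
  keep <- names(counts)[counts / length(trees) > threshold]
  build_tree_from_clades(trees[[1]]$tip.label,
                         lapply(keep, function(k) strsplit(k, "\r", fixed = TRUE)[[1]]))
}

# Surgery ------------------------------------------------------------------

new_internal_id <- function(et) max(c(et$n_tip, et$edge)) + 1L

# The minimal anchored tree on the first three labels: root children are tip 1
# and an internal node holding tips 2 and 3.
start_etree <- function(labels) {
  n <- length(labels)
  root <- n + 1L; a <- n + 2L
  etree(matrix(c(root, 1L, root, a, a, 2L, a, 3L), ncol = 2, byrow = TRUE),
        n, labels)
}

# Attach tip `tip_id` (already counted in n_tip / tip.label) by subdividing
# edge row `row`.
attach_tip_et <- function(et, row, tip_id) {
  z <- new_internal_id(et)
  e <- et$edge
  p <- e[row, 1]; c_ <- e[row, 2]
  e[row, ] <- c(p, z)
  et$edge <- rbind(e, c(z, c_), c(z, tip_id))
  et
}

# Rows whose subdivision yields distinct *unrooted* placements: all edges
# except one of the root's two child edges.
insertion_rows <- function(et) {
  root <- et_root(et)
  root_rows <- which(et$edge[, 1] == root)
  setdiff(seq_len(nrow(et$edge)), root_rows[1])
}

# Prune the subtree below edge row `row`. Returns list(base, sub_root,
# sub_edge, regraft_block) or NULL when the prune is degenerate (base would
# have < 2 tips).
prune_edge_et <- function(et, row) {
  e <- et$edge
  u <- e[row, 1]; v <- e[row, 2]
  # collect subtree rows below v
  sub_rows <- integer(0)
  frontier <- v
  repeat {
    new_rows <- which(e[, 1] %in% frontier)
    new_rows <- setdiff(new_rows, sub_rows)
    if (!length(new_rows)) break
    sub_rows <- c(sub_rows, new_rows)
    frontier <- e[new_rows, 2]
  }
  keep <- setdiff(seq_len(nrow(e)), c(row, sub_rows))
  base_edge <- e[keep, , drop = FALSE]
  root <- et_root(et)
  if (u == root) {
    w_row <- which(base_edge[, 1] == root)
    if (length(w_row) != 1L) stop("malformed root")
    w <- base_edge[w_row, 2]
    if (w <= et$n_tip) return(NULL)       # base degenerates to a single tip
    base_edge <- base_edge[-w_row, , drop = FALSE]
  } else {
    p_row <- which(base_edge[, 2] == u)
    s_row <- which(base_edge[, 1] == u)
    p <- base_edge[p_row, 1]; s <- base_edge[s_row, 2]
    base_edge[p_row, ] <- c(p, s)
    base_edge <- base_edge[-s_row, , drop = FALSE]
  }
  if (nrow(base_edge) < 2L) return(NULL)
  list(base = etree(base_edge, et$n_tip, et$tip.label),
       sub_root = v,
       sub_edge = if (length(sub_rows)) e[sub_rows, , drop = FALSE] else
         matrix(integer(0), 0, 2))
}

# Regraft a pruned subtree into edge row `row` of the base.
regraft_et <- function(base, sub_root, sub_edge, row) {
  z <- max(c(base$n_tip, base$edge, sub_root, sub_edge)) + 1L
  e <- base$edge
  p <- e[row, 1]; c_ <- e[row, 2]
  e[row, ] <- c(p, z)
  etree(rbind(e, c(z, c_), c(z, sub_root), sub_edge), base$n_tip, base$tip.label)
}

# All subtree-prune-regraft neighbours under the current rooting (generated
# lazily as a list of etrees). Regrafting into either root-child edge of the
# base yields the same unrooted topology, so one is skipped; the original
# position is skipped too.
spr_neighbors <- function(et) {
  out <- list()
  n_edge <- nrow(et$edge)
  for (row in seq_len(n_edge)) {
    pr <- prune_edge_et(et, row)
    if (is.null(pr)) next
    rows <- insertion_rows(pr$base)
    for (f in rows) {
      out[[length(out) + 1L]] <- regraft_et(pr$base, pr$sub_root, pr$sub_edge, f)
    }
  }
  out
}

# Reroot the unrooted topology so the root's children are `tip` and the rest.
reanchor_et <- function(et, tip) {
  ph <- et_to_phylo(et)
  ph2 <- ape::root(ph, outgroup = et$tip.label[tip], resolve.root = TRUE)
  phylo_to_et(ph2)
}

# Enumerate all unrooted binary topologies over `labels`, invoking
# fun(etree) on each. 3 taxa -> 1; 7 -> 945; 9 -> 135135.
for_each_topology <- function(labels, fun) {
  n <- length(labels)
  if (n < 3L) {
    if (n == 2L) {
      fun(etree(matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE), 2L, labels))
      return(invisible(NULL))
    }
    stop("need at least 2 taxa")
  }
  rec <- function(et, next_tip) {
    if (next_tip > n) { fun(et); return(invisible(NULL)) }
    for (row in insertion_rows(et)) {
      rec(attach_tip_et(et, row, next_tip), next_tip + 1L)
    }
  }
  rec(start_etree(labels), 4L)
  invisible(NULL)
}

n_unrooted_topologies <- function(n) {
  if (n < 3) return(1)
  prod(seq(1, 2 * n - 5, by = 2))
}
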