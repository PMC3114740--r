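# Tree search -------------------------------------------------------------
#
# Minimum-score trees are found either exhaustively (complete enumeration of
# unrooted topologies, feasible to 9 free taxa) or heuristically: random
# taxon-addition starting trees, each improved by subtree-prune-regraft hill
# climbing (which subsumes nearest-neighbour interchanges), with rerooted
# sweeps at local optima so the neighbourhood covers unrooted SPR/TBR-style
# rearrangements. Constraints are expressed as required and forbidden
# bipartitions evaluated on the candidate tree restricted to a taxon subset;
# a backbone ("molecular scaffold") constraint requires each backbone split
# in the restriction to the backbone taxa while every other taxon — fossils
# in the intended use — floats freely.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define a backbone constraint
#'
#' @param backbone a `phylo` tree (or Newick string) on a subset of the
#'   analysis taxa; candidate trees must display all of its bipartitions after
#'   restriction to these taxa.
#' @param floating taxa allowed to attach anywhere (typically the fossils).
#'   Informational plus validated against the backbone tip set.
#' @return an object of class `backbone_constraint`.
#' @export
backbone_constraint <- function(backbone, floating = character(0)) {
  backbone <- as_phylo_tree(backbone)
  if (length(intersect(backbone$tip.label, floating)))
    stop("floating taxa cannot appear in the backbone")
  structure(list(backbone = backbone, floating = as.character(floating)),
            class = "backbone_constraint")
}

#' Does a tree satisfy a backbone constraint?
#'
#' The tree restricted to the backbone taxa (suppressing degree-two nodes)
#' must display every backbone bipartition; extra resolution in the tree is
#' allowed, as is any placement of non-backbone (floating) taxa.
#'
#' @param tree a `phylo` tree or Newick string.
#' @param constraint a [backbone_constraint()].
#' @return logical.
#' @export
satisfies_constraint <- function(tree, constraint) {
  tree <- as_phylo_tree(tree)
  bb <- constraint$backbone
  missing <- setdiff(bb$tip.label, tree$tip.label)
  if (length(missing)) stop("backbone tip(s) absent from tree: ",
                            paste(missing, collapse = ", "))
  restr <- restrict_tree(tree, bb$tip.label)
  all(tree_splits(bb) %in% tree_splits(restr))
}

# Predicate objects --------------------------------------------------------
# required / forbidden: lists of list(split = labels, over = labels or NULL).
make_pred <- function(required = list(), forbidden = list()) {
  list(required = required, forbidden = forbidden)
}

pred_from_constraint <- function(constraint, taxa) {
  if (is.null(constraint)) return(make_pred())
  bb <- constraint$backbone
  if (!all(bb$tip.label %in% taxa))
    stop("backbone tips not all present in the analysis taxa")
  keys <- tree_splits(bb)
  req <- lapply(keys, function(k)
    list(split = strsplit(k, "\r", fixed = TRUE)[[1]], over = bb$tip.label))
  make_pred(required = req)
}

# Induced split keys of an etree restricted to `over` (labels). Works on
# partial trees in "full label space" mode, where tip ids index et$tip.label
# but only some tips occur in the edge matrix.
et_split_keys <- function(et, over) {
  below <- tips_below_list(et)
  root <- et_root(et)
  labs <- et$tip.label
  n_over <- length(over)
  keys <- character(0)
  for (nd in unique(et$edge[, 1])) {
    side <- intersect(labs[below[[nd]]], over)
    if (length(side) >= 2L && n_over - length(side) >= 2L)
      keys <- c(keys, split_key(side, over))
  }
  unique(keys)
}

pred_ok_et <- function(et, present, pred) {
  cache <- list()
  keys_for <- function(over) {
    sig <- paste(sort(over), collapse = "\r")
    if (is.null(cache[[sig]])) cache[[sig]] <<- et_split_keys(et, over)
    cache[[sig]]
  }
  check <- function(item, want) {
    over <- intersect(item$over %||% present, present)
    s <- intersect(item$split, over)
    if (length(s) < 2L || length(over) - length(s) < 2L) return(TRUE)  # vacuous
    present_split <- split_key(s, over) %in% keys_for(over)
    if (want) present_split else !present_split
  }
  for (r in pred$required) if (!check(r, TRUE)) return(FALSE)
  for (f in pred$forbidden) if (!check(f, FALSE)) return(FALSE)
  TRUE
}

pred_is_empty <- function(pred) {
  !length(pred$required) && !length(pred$forbidden)
}

# Full-label-space construction helpers ------------------------------------

# etree over all `taxa` containing only the three given tip ids
start_partial_et <- function(taxa, t1, t2, t3) {
  N <- length(taxa)
  root <- N + 1L; a <- N + 2L
  etree(matrix(c(root, t1, root, a, a, t2, a, t3), ncol = 2, byrow = TRUE),
        N, taxa)
}

et_from_phylo_sub <- function(ph, taxa) {
  nb <- length(ph$tip.label)
  if (ph$Nnode < nb - 1L) ph <- ape::multi2di(ph)
  nb <- length(ph$tip.label)
  tipid <- match(ph$tip.label, taxa)
  if (anyNA(tipid)) stop("tree tips absent from taxa")
  edge <- ph$edge
  is_tip <- edge <= nb
  edge[is_tip] <- tipid[edge[is_tip]]
  edge[!is_tip] <- ph$edge[!is_tip] - nb + length(taxa)
  storage.mode(edge) <- "integer"
  etree(edge, length(taxa), taxa)
}

present_tips_et <- function(et) {
  ids <- et$edge[et$edge[, 2] <= et$n_tip, 2]
  et$tip.label[ids]
}

# drop unused tip labels so the etree can become a valid phylo
et_drop_absent <- function(et) {
  ids <- sort(unique(et$edge[et$edge[, 2] <= et$n_tip, 2]))
  if (length(ids) == et$n_tip) return(et)
  map <- setNames(seq_along(ids), ids)
  edge <- et$edge
  is_tip <- edge <= et$n_tip
  # internal ids must stay above the new tip count; shift them up
  edge[!is_tip] <- edge[!is_tip] + et$n_tip
  edge[is_tip] <- map[as.character(edge[is_tip])]
  etree(edge, length(ids), et$tip.label[ids])
}

# Core search -------------------------------------------------------------

# One random-addition + SPR-hill-climb replicate. Returns list(et, score) or
# NULL when the predicate made every insertion position inadmissible.
addition_replicate <- function(taxa, objective_et, pred, start_et = NULL) {
  N <- length(taxa)
  if (is.null(start_et)) {
    ord <- sample.int(N)
    et <- start_partial_et(taxa, ord[1], ord[2], ord[3])
    todo <- ord[-(1:3)]
  } else {
    et <- start_et
    todo <- sample(setdiff(seq_len(N), match(present_tips_et(start_et), taxa)))
  }
  for (t in todo) {
    rows <- insertion_rows(et)
    cands <- lapply(rows, function(r) attach_tip_et(et, r, t))
    if (!pred_is_empty(pred)) {
      present <- c(present_tips_et(et), taxa[t])
      ok <- vapply(cands, pred_ok_et, TRUE, present = present, pred = pred)
      cands <- cands[ok]
      if (!length(cands)) return(NULL)
    }
    scores <- vapply(cands, objective_et, numeric(1))
    best <- which(scores <= min(scores) + SCORE_TOL)
    et <- cands[[if (length(best) > 1L) sample(best, 1L) else best]]
  }
  et
}

spr_hill_climb <- function(et, objective_et, pred) {
  score <- objective_et(et)
  check <- function(cand) pred_is_empty(pred) ||
    pred_ok_et(cand, cand$tip.label, pred)
  repeat {
    improved <- FALSE
    nbrs <- spr_neighbors(et)
    scores <- vapply(nbrs, objective_et, numeric(1))
    for (i in order(scores)) {
      if (scores[i] >= score - SCORE_TOL) break
      if (check(nbrs[[i]])) {
        et <- nbrs[[i]]; score <- scores[i]; improved <- TRUE; break
      }
    }
    if (improved) next
    # local optimum under this rooting: try rerooted sweeps (covers the SPR
    # orientations a fixed rooting misses)
    for (tip in sample.int(et$n_tip)) {
      et2 <- reanchor_et(et, tip)
      nbrs <- spr_neighbors(et2)
      scores <- vapply(nbrs, objective_et, numeric(1))
      for (i in order(scores)) {
        if (scores[i] >= score - SCORE_TOL) break
        if (check(nbrs[[i]])) {
          et <- nbrs[[i]]; score <- scores[i]; improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved) return(list(et = et, score = score))
  }
}

# Expand the optimal set across equal-score SPR neighbours (plateau walk).
collect_plateau <- function(opt_list, objective_et, pred, best_score, max_trees) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  queue <- list()
  push <- function(et) {
    sig <- topology_signature(et_to_phylo(et))
    if (!is.null(get0(sig, envir = seen))) return(FALSE)
    assign(sig, TRUE, envir = seen)
    queue[[length(queue) + 1L]] <<- et
    TRUE
  }
  for (et in opt_list) push(et)
  out <- list(); i <- 0L
  capped <- FALSE
  while (i < length(queue)) {
    i <- i + 1L
    et <- queue[[i]]
    out[[length(out) + 1L]] <- et
    if (length(out) >= max_trees) { capped <- TRUE; break }
    nbrs <- spr_neighbors(et)
    scores <- vapply(nbrs, objective_et, numeric(1))
    for (j in which(abs(scores - best_score) <= SCORE_TOL)) {
      cand <- nbrs[[j]]
      if (pred_is_empty(pred) || pred_ok_et(cand, cand$tip.label, pred)) push(cand)
    }
  }
  if (capped) warning("optimal tree set truncated at ", max_trees, " trees")
  out
}

search_core <- function(m, weights, taxa, pred, n_replicates, seed, max_trees,
                        start_et = NULL, plateau = TRUE) {
  objective <- parsimony_objective(m, weights)
  objective_et <- function(et) objective(et)
  with_seed(seed, {
    best_score <- Inf
    opts <- list()
    opt_scores <- numeric(0)
    hits <- 0L
    for (rep_i in seq_len(n_replicates)) {
      et <- NULL
      for (try_i in 1:20) {
        et <- addition_replicate(taxa, objective_et, pred, start_et)
        if (!is.null(et)) break
      }
      if (is.null(et)) next
      res <- spr_hill_climb(et, objective_et, pred)
      if (res$score < best_score - SCORE_TOL) {
        best_score <- res$score; opts <- list(res$et); hits <- 1L
      } else if (res$score <= best_score + SCORE_TOL) {
        opts <- c(opts, list(res$et)); hits <- hits + 1L
      }
    }
    if (!length(opts)) stop("no constraint-satisfying tree could be constructed")
    if (plateau) opts <- collect_plateau(opts, objective_et, pred, best_score, max_trees)
    trees <- lapply(opts, et_to_phylo)
    sigs <- vapply(trees, topology_signature, "")
    trees <- trees[!duplicated(sigs)]
    structure(list(best_score = best_score, best_trees = trees,
                   replicates_hitting_best = hits, seed = seed),
              class = "search_result")
  })
}

#' Heuristic parsimony tree search
#'
#' Random taxon-addition starting trees improved by SPR hill climbing with
#' rerooted sweeps, optionally under a backbone constraint (non-backbone taxa
#' float). All distinct optimal topologies encountered are returned, expanded
#' across equal-score SPR plateaus; results are deterministic for a given
#' `seed`.
#'
#' @param m a `char_matrix`.
#' @param weights a `weight_scheme`, numeric weight vector, or `NULL` (equal).
#' @param constraint optional [backbone_constraint()].
#' @param n_replicates number of random-addition replicates (>= 1).
#' @param seed integer RNG seed.
#' @param taxa optional subset of matrix taxa to analyse (default all).
#' @param max_trees cap on the stored optimal tree set (default 10000).
#' @return a `search_result`: `best_score`, `best_trees` (list of `phylo`),
#'   `replicates_hitting_best`, `seed`.
#' @export
heuristic_search <- function(m, weights = NULL, constraint = NULL,
                             n_replicates = 10, seed = 1, taxa = NULL,
                             max_trees = 10000) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  taxa <- taxa %||% m$taxa
  pred <- pred_from_constraint(constraint, taxa)
  start_et <- NULL
  if (!is.null(constraint) && length(constraint$backbone$tip.label) >= 3)
    start_et <- et_from_phylo_sub(constraint$backbone, taxa)
  search_core(m, weights, taxa, pred, n_replicates, seed, max_trees,
              start_et = start_et)
}

exhaustive_core <- function(m, weights, taxa, pred, max_trees = 10000) {
  if (length(taxa) > 9)
    stop("exhaustive search is limited to 9 taxa (135,135 topologies)")
  objective <- parsimony_objective(m, weights)
  best_score <- Inf
  opts <- list()
  for_each_topology(taxa, function(et) {
    if (!pred_is_empty(pred) && !pred_ok_et(et, taxa, pred)) return(invisible(NULL))
    sc <- objective(et)
    if (sc < best_score - SCORE_TOL) {
      best_score <<- sc; opts <<- list(et)
    } else if (sc <= best_score + SCORE_TOL && length(opts) < max_trees) {
      opts[[length(opts) + 1L]] <<- et
    }
    invisible(NULL)
  })
  if (!length(opts)) stop("no constraint-satisfying tree exists")
  structure(list(best_score = best_score,
                 best_trees = lapply(opts, et_to_phylo),
                 replicates_hitting_best = NA_integer_, seed = NA_integer_),
            class = "search_result")
}

#' Exhaustive parsimony tree search
#'
#' Enumerates every unrooted binary topology (up to 9 taxa) and returns the
#' exact global optimum set, optionally under a backbone constraint.
#'
#' @inheritParams heuristic_search
#' @return a `search_result`.
#' @export
exhaustive_search <- function(m, weights = NULL, constraint = NULL, taxa = NULL,
                              max_trees = 10000) {
  taxa <- taxa %||% m$taxa
  pred <- pred_from_constraint(constraint, taxa)
  exhaustive_core(m, weights, taxa, pred, max_trees)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: best score %.4f, %d optimal tree(s)",
              x$best_score, length(x$best_trees)))
  if (!is.na(x$replicates_hitting_best))
    cat(sprintf(", %d replicate(s) hit the optimum", x$replicates_hitting_best))
  cat("\n")
  invisible(x)
}
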