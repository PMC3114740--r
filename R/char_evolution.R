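# Ancestral states and homology -------------------------------------------
#
# Most parsimonious reconstructions (MPRs) come from Sankoff backtracking:
# after the down-pass, an assignment is optimal exactly when the root takes a
# minimum-cost state and every node takes a state minimizing its own subtree
# cost plus the transformation cost from its parent's assigned state. ACCTRAN
# and DELTRAN are the greedy tracebacks that resolve each ambiguity toward
# (ACCTRAN) or away from (DELTRAN) a change on the current branch, placing
# transformations as close to or as far from the root as possible. Homology
# versus analogy of a state shared by two tips is decided per MPR by whether
# the state runs unbroken along the path connecting them, then aggregated
# across all MPRs ("H" if always, "A" if never, ambiguous otherwise).

char_dp <- function(tree, column, spec) {
  tree <- as_phylo_tree(tree)
  et <- phylo_to_et(tree)
  cp <- compact_postorder(et)
  masks <- column_masks(column, spec, et$tip.label)
  S <- length(spec$state_space)
  tc <- tip_cost_matrix(masks, S)
  cm <- cost_matrix_for(spec)
  node_cost <- sankoff_node_costs_cpp(cp$edge, cp$n_tip, cp$n_node, tc, cm,
                                      seq_len(cp$n_tip))
  root <- cp$edge[nrow(cp$edge), 1]
  parent <- integer(cp$n_node)
  for (i in seq_len(nrow(cp$edge))) parent[cp$edge[i, 2]] <- cp$edge[i, 1]
  # children in preorder-friendly form
  kids <- split(cp$edge[, 2], factor(cp$edge[, 1], levels = seq_len(cp$n_node)))
  labels <- c(et$tip.label,
              paste0("node", seq_len(cp$n_node - cp$n_tip) + cp$n_tip))
  list(et = et, cp = cp, node_cost = node_cost, cm = cm, S = S, root = root,
       parent = parent, kids = kids, labels = labels, spec = spec)
}

node_options <- function(dp, node, parent_state) {
  v <- dp$node_cost[node, ] + dp$cm[parent_state, ]
  which(v <= min(v) + 1e-9)
}

mpr_length <- function(dp) min(dp$node_cost[dp$root, ])

as_reconstruction <- function(dp, states, flavor) {
  assignment <- setNames(dp$spec$state_space[states], dp$labels)
  edges <- data.frame(parent = dp$labels[dp$cp$edge[, 1]],
                      child = dp$labels[dp$cp$edge[, 2]],
                      from = dp$spec$state_space[states[dp$cp$edge[, 1]]],
                      to = dp$spec$state_space[states[dp$cp$edge[, 2]]],
                      stringsAsFactors = FALSE)
  structure(list(assignment = assignment, length = mpr_length(dp),
                 flavor = flavor, edges = edges),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  changes <- x$edges[x$edges$from != x$edges$to, , drop = FALSE]
  cat(sprintf("reconstruction (%s): length %.4g, %d change(s)\n",
              x$flavor, x$length, nrow(changes)))
  invisible(x)
}

#' Enumerate all most parsimonious reconstructions of a character
#'
#' @param tree a rooted `phylo` tree or Newick string.
#' @param column named state-set list/vector (or named bitmask vector).
#' @param spec a [char_spec()].
#' @param cap maximum number of MPRs to enumerate before raising an error.
#' @return list of `reconstruction` objects, each with a full node-state
#'   `assignment` (tips with uncertain cells are assigned too), the common
#'   `length`, and the per-edge state table.
#' @export
enumerate_mprs <- function(tree, column, spec, cap = 10000) {
  if (cap < 1) stop("cap must be >= 1")
  dp <- char_dp(tree, column, spec)
  L <- mpr_length(dp)
  if (L >= BIG / 2) stop("no admissible state assignment")
  out <- list()
  states <- integer(dp$cp$n_node)
  # preorder node sequence
  preorder <- dp$root
  i <- 1L
  while (i <= length(preorder)) {
    preorder <- c(preorder, dp$kids[[preorder[i]]])
    i <- i + 1L
  }
  assign_from <- function(pos) {
    node <- preorder[pos]
    opts <- if (node == dp$root) {
      which(dp$node_cost[dp$root, ] <= L + 1e-9)
    } else {
      node_options(dp, node, states[dp$parent[node]])
    }
    for (s in opts) {
      states[node] <<- s
      if (pos == length(preorder)) {
        if (length(out) >= cap)
          stop("MPR count exceeds cap (", cap, ")")
        out[[length(out) + 1L]] <<- states
      } else {
        assign_from(pos + 1L)
      }
    }
  }
  assign_from(1L)
  lapply(out, function(st) as_reconstruction(dp, st, "mpr"))
}

greedy_traceback <- function(dp, accelerate) {
  states <- integer(dp$cp$n_node)
  L <- mpr_length(dp)
  root_opts <- which(dp$node_cost[dp$root, ] <= L + 1e-9)
  states[dp$root] <- root_opts[1]
  preorder <- dp$root
  i <- 1L
  while (i <= length(preorder)) {
    preorder <- c(preorder, dp$kids[[preorder[i]]])
    i <- i + 1L
  }
  for (node in preorder[-1]) {
    ps <- states[dp$parent[node]]
    opts <- node_options(dp, node, ps)
    states[node] <- if (accelerate) {
      changed <- setdiff(opts, ps)
      if (length(changed)) changed[1] else ps
    } else {
      if (ps %in% opts) ps else opts[1]
    }
  }
  states
}

#' ACCTRAN reconstruction (accelerated transformation)
#'
#' Resolves every optimization ambiguity by changing as close to the root as
#' possible (changes happen early; subsequent reversals are tolerated).
#'
#' @inheritParams enumerate_mprs
#' @return a `reconstruction`.
#' @export
acctran <- function(tree, column, spec) {
  dp <- char_dp(tree, column, spec)
  as_reconstruction(dp, greedy_traceback(dp, accelerate = TRUE), "acctran")
}

#' DELTRAN reconstruction (delayed transformation)
#'
#' Resolves every optimization ambiguity by keeping the parent's state
#' whenever that is cost-free, pushing changes toward the apical branches
#' (so convergence is preferred over early gain plus reversal).
#'
#' @inheritParams enumerate_mprs
#' @return a `reconstruction`.
#' @export
deltran <- function(tree, column, spec) {
  dp <- char_dp(tree, column, spec)
  as_reconstruction(dp, greedy_traceback(dp, accelerate = FALSE), "deltran")
}

#' Count independent origins of a state on a tree
#'
#' Origins are branches whose child is reconstructed in `state` but whose
#' parent is not; a state already present at the root is not counted as an
#' origin.
#'
#' @inheritParams enumerate_mprs
#' @param state the state symbol whose gains are counted.
#' @param flavor `"acctran"`, `"deltran"`, or `"mpr"` (the minimum over all
#'   MPRs, capped enumeration).
#' @param cap MPR enumeration cap (only for `flavor = "mpr"`).
#' @return integer count of transitions into `state`.
#' @export
count_origins <- function(tree, column, spec, state, flavor = "deltran",
                          cap = 10000) {
  flavor <- match.arg(flavor, c("deltran", "acctran", "mpr"))
  count_one <- function(rec) {
    sum(rec$edges$to == state & rec$edges$from != state)
  }
  if (flavor == "mpr") {
    min(vapply(enumerate_mprs(tree, column, spec, cap), count_one, numeric(1)))
  } else {
    rec <- if (flavor == "acctran") acctran(tree, column, spec)
           else deltran(tree, column, spec)
    count_one(rec)
  }
}

#' Classify a state shared by two tips as homologous or analogous
#'
#' For every MPR, the shared state is *homologous* for the pair if it labels
#' each node on the path from one tip through their most recent common
#' ancestor to the other (continuous inheritance), and *analogous* if the
#' path is interrupted (independent acquisition). The call is `"H"` when all
#' MPRs agree on homology, `"A"` when none is homologous, and `"ambiguous"`
#' otherwise (also when enumeration hits `cap`, with a warning).
#'
#' @inheritParams enumerate_mprs
#' @param tipX,tipY tip labels sharing at least one observed state.
#' @return list with `pair`, `call` (`"H"`, `"A"`, `"ambiguous"`),
#'   `n_mprs`, `n_homologous`.
#' @export
classify_pair_homology <- function(tree, column, spec, tipX, tipY, cap = 10000) {
  tree <- as_phylo_tree(tree)
  masks <- column_masks(column, spec, tree$tip.label)
  mx <- masks[match(tipX, tree$tip.label)]
  my <- masks[match(tipY, tree$tip.label)]
  if (is.na(mx) || is.na(my)) stop("tip not in tree")
  if (bitwAnd(mx, my) == 0L)
    stop("tips share no observed state for this character")
  mprs <- tryCatch(enumerate_mprs(tree, column, spec, cap),
                   error = function(e) {
                     if (grepl("exceeds cap", conditionMessage(e))) NULL else stop(e)
                   })
  if (is.null(mprs)) {
    warning("MPR enumeration capped; homology call is ambiguous")
    return(list(pair = c(tipX, tipY), call = "ambiguous",
                n_mprs = NA_integer_, n_homologous = NA_integer_))
  }
  dp <- char_dp(tree, column, spec)
  ix <- match(tipX, dp$et$tip.label); iy <- match(tipY, dp$et$tip.label)
  path_nodes <- function() {
    up <- function(i) {
      path <- i
      while (path[length(path)] != dp$root)
        path <- c(path, dp$parent[path[length(path)]])
      path
    }
    px <- up(ix); py <- up(iy)
    mrca <- px[min(which(px %in% py))]
    c(px[seq_len(which(px == mrca))], py[seq_len(which(py == mrca) - 1L)])
  }
  path <- path_nodes()
  homologous <- vapply(mprs, function(rec) {
    st <- rec$assignment[dp$labels[path]]
    length(unique(st)) == 1L
  }, TRUE)
  call <- if (all(homologous)) "H" else if (!any(homologous)) "A" else "ambiguous"
  list(pair = c(tipX, tipY), call = call,
       n_mprs = length(mprs), n_homologous = sum(homologous))
}

#' Optimize a binary trait (e.g. habitat) onto a tree
#'
#' @param tree a rooted `phylo` tree or Newick string.
#' @param trait named vector of `0`/`1` (or two-level factor/character)
#'   covering every tip.
#' @param flavor `"deltran"` (default, pushing changes onto apical branches)
#'   or `"acctran"`.
#' @return a `reconstruction` whose `transitions` element lists the branches
#'   carrying each state change.
#' @export
map_binary_trait <- function(tree, trait, flavor = "deltran") {
  flavor <- match.arg(flavor, c("deltran", "acctran"))
  tree <- as_phylo_tree(tree)
  if (!all(tree$tip.label %in% names(trait))) stop("trait must cover every tip")
  vals <- as.character(trait[tree$tip.label])
  lev <- sort(unique(vals))
  if (length(lev) > 2) stop("trait must be binary")
  if (length(lev) == 1) lev <- c(lev, paste0("not_", lev))
  # levels may be arbitrary words; score as 0/1 and translate back
  spec <- char_spec("unordered", c("0", "1"))
  column <- setNames(as.list(as.character(match(vals, lev) - 1L)),
                     tree$tip.label)
  rec <- if (flavor == "acctran") acctran(tree, column, spec)
         else deltran(tree, column, spec)
  relab <- function(x) lev[match(x, c("0", "1"))]
  rec$assignment[] <- relab(rec$assignment)
  rec$edges$from <- relab(rec$edges$from)
  rec$edges$to <- relab(rec$edges$to)
  rec$transitions <- rec$edges[rec$edges$from != rec$edges$to, , drop = FALSE]
  rec
}
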