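# Synthetic data ------------------------------------------------------------
#
# The generator emulates the structure of a combined fossil + molecular
# supermatrix: a birth-death tree whose extinct lineages supply fossil tips
# with true ages, a small morphology block (ordered and unordered characters,
# scored for everyone) alongside a large molecular block (missing for all
# fossils), and first/last appearance dates consistent with the true tree.
# Characters evolve by a continuous-time Markov walk on the true tree, so
# every parsimony length is bounded above by the number of simulated changes.

#' Simulation configuration
#'
#' @param n_extant number of living taxa (>= 2).
#' @param n_fossil number of sampled extinct taxa.
#' @param birth,death speciation and extinction rates per lineage per My.
#' @param n_morph,n_mol numbers of morphological and molecular characters.
#' @param ordered_fraction fraction of morphological characters treated as
#'   ordered.
#' @param max_states maximum number of states of a morphological character
#'   (uniform on 2..max_states); molecular characters always have 4.
#' @param change_rate expected number of state changes per character over the
#'   whole tree.
#' @param morph_missing_fraction extra fraction of fossil morphology cells
#'   blanked to mimic incomplete preservation.
#' @param seed mandatory integer seed; all generators are deterministic in it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_extant = 12, n_fossil = 8, birth = 0.15, death = 0.1,
                       n_morph = 60, n_mol = 400, ordered_fraction = 0.25,
                       max_states = 4, change_rate = 2,
                       morph_missing_fraction = 0.3, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_extant >= 2, n_fossil >= 0, birth > 0, death >= 0,
            n_morph >= 0, n_mol >= 0, ordered_fraction >= 0,
            ordered_fraction <= 1, max_states >= 2, change_rate >= 0,
            morph_missing_fraction >= 0, morph_missing_fraction <= 1)
  structure(list(n_extant = n_extant, n_fossil = n_fossil, birth = birth,
                 death = death, n_morph = n_morph, n_mol = n_mol,
                 ordered_fraction = ordered_fraction, max_states = max_states,
                 change_rate = change_rate,
                 morph_missing_fraction = morph_missing_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One forward birth-death run. Returns NULL on failure, else a list of
# segments (id, start, end, children, died) plus the stop time.
bd_run <- function(birth, death, stop_fun, max_events = 1e5) {
  segs <- list(list(id = 1L, start = 0, end = NA, children = NULL, died = FALSE),
               list(id = 2L, start = 0, end = NA, children = NULL, died = FALSE))
  alive <- c(1L, 2L)
  next_id <- 3L
  t <- 0
  for (ev in seq_len(max_events)) {
    st <- stop_fun(length(alive), sum(vapply(segs, `[[`, TRUE, "died")), t)
    if (!is.na(st)) {
      for (i in alive) segs[[i]]$end <- st
      return(list(segs = segs, present = st))
    }
    if (!length(alive)) {
      # total extinction: a time-conditioned run still has a defined outcome
      st <- stop_fun(0L, sum(vapply(segs, `[[`, TRUE, "died")), Inf)
      if (!is.na(st)) {
        return(list(segs = segs, present = st))
      }
      return(NULL)
    }
    rate <- length(alive) * (birth + death)
    t <- t + stats::rexp(1, rate)
    st <- stop_fun(length(alive), sum(vapply(segs, `[[`, TRUE, "died")), t)
    if (!is.na(st)) {                     # time-conditioned stop mid-wait
      for (i in alive) segs[[i]]$end <- st
      return(list(segs = segs, present = st))
    }
    who <- alive[sample.int(length(alive), 1)]
    if (runif(1) < birth / (birth + death)) {
      segs[[who]]$end <- t
      segs[[who]]$children <- c(next_id, next_id + 1L)
      segs[[next_id]] <- list(id = next_id, start = t, end = NA,
                              children = NULL, died = FALSE)
      segs[[next_id + 1L]] <- list(id = next_id + 1L, start = t, end = NA,
                                   children = NULL, died = FALSE)
      alive <- c(setdiff(alive, who), next_id, next_id + 1L)
      next_id <- next_id + 2L
    } else {
      segs[[who]]$end <- t
      segs[[who]]$died <- TRUE
      alive <- setdiff(alive, who)
    }
  }
  NULL
}

segs_to_phylo <- function(segs, labels) {
  # labels: named by segment id for every terminal segment
  nwk <- function(i) {
    s <- segs[[i]]
    len <- s$end - s$start
    if (is.null(s$children)) {
      paste0(labels[[as.character(s$id)]], ":", format(len, digits = 12))
    } else {
      paste0("(", nwk(s$children[1]), ",", nwk(s$children[2]), "):",
             format(len, digits = 12))
    }
  }
  ape::read.tree(text = paste0("(", nwk(1L), ",", nwk(2L), ");"))
}

#' Simulate a birth-death tree with fossil tips
#'
#' Runs a forward birth-death process from two ancestral lineages. With
#' `condition = "taxa"` (default) the run stops the first time the number of
#' living lineages reaches `n_extant`; `n_fossil` of the extinct lineages
#' are retained as fossil tips (labelled `f*`), the rest are pruned, and
#' runs with too few extinctions are resampled (bounded retries). With
#' `condition = "time"` the process simply runs for `duration` My and keeps
#' everything, which is the mode used to check the generator against the
#' analytic expectation `E[N(t)] = 2 exp((birth - death) t)`.
#'
#' @param config a [sim_config()].
#' @param condition `"taxa"` or `"time"`.
#' @param duration run length in My for `condition = "time"`.
#' @param max_tries retry bound for `condition = "taxa"`.
#' @return a `sim_tree`: list with `tree` (`phylo` with branch lengths in
#'   My), `tip_ages` (Ma before present; 0 for extant), `extant`, `fossils`,
#'   and `root_age`.
#' @export
sim_tree <- function(config, condition = c("taxa", "time"), duration = 25,
                     max_tries = 200) {
  condition <- match.arg(condition)
  with_seed(config$seed, {
    for (try_i in seq_len(max_tries)) {
      if (condition == "taxa") {
        run <- bd_run(config$birth, config$death, function(n_alive, n_dead, t)
          if (n_alive == config$n_extant && t > 0) t else NA_real_)
        if (is.null(run)) next
        n_dead <- sum(vapply(run$segs, `[[`, TRUE, "died"))
        if (n_dead < config$n_fossil) next
      } else {
        run <- bd_run(config$birth, config$death, function(n_alive, n_dead, t)
          if (t >= duration) duration else NA_real_)
        if (is.null(run)) next
      }
      segs <- run$segs
      terminal <- Filter(function(s) is.null(s$children), segs)
      died <- vapply(terminal, `[[`, TRUE, "died")
      ids <- vapply(terminal, `[[`, 1L, "id")
      labels <- character(0)
      extant_ids <- ids[!died]; dead_ids <- ids[died]
      labels[as.character(extant_ids)] <- paste0("t", seq_along(extant_ids))
      labels[as.character(dead_ids)] <- paste0("f", seq_along(dead_ids))
      keep_dead <- if (condition == "taxa")
        sample(as.character(dead_ids), config$n_fossil) else as.character(dead_ids)
      tree <- segs_to_phylo(segs, as.list(labels))
      drop <- setdiff(labels[as.character(dead_ids)], labels[keep_dead])
      if (length(drop)) {
        if (length(tree$tip.label) - length(drop) < 2) next
        tree <- ape::drop.tip(tree, drop)
      }
      ages <- setNames(vapply(terminal, function(s) run$present - s$end, 1),
                       labels[as.character(ids)])
      ages <- ages[tree$tip.label]
      fos <- sort(names(ages)[startsWith(names(ages), "f")])
      # pruning extinct lineages can remove the original root, so date the
      # retained root from any tip's age plus its root-to-tip path length
      depths <- ape::node.depth.edgelength(tree)
      root_age <- unname(ages[1] + depths[1])
      return(structure(list(tree = tree, tip_ages = ages,
                            extant = sort(names(ages)[startsWith(names(ages), "t")]),
                            fossils = fos, root_age = root_age),
                       class = "sim_tree"))
    }
    stop("birth-death simulation failed after ", max_tries, " tries ",
         "(all lineages extinct or too few fossils); raise the rates or retries")
  })
}

#' @export
print.sim_tree <- function(x, ...) {
  cat(sprintf("sim_tree: %d extant + %d fossil tips, root age %.2f My\n",
              length(x$extant), length(x$fossils), x$root_age))
  invisible(x)
}

# Simulate one character down the tree. `edge_rates` gives the expected
# number of change events per edge (postorder row order).
simulate_column <- function(tree, k, kind, edge_rates, symbols) {
  # returns list(masks named by tip, changes = number of simulated changes)
  et <- phylo_to_et(tree)
  cp <- compact_postorder(et)
  edge <- cp$edge
  state <- integer(cp$n_node)
  root <- edge[nrow(edge), 1]
  state[root] <- sample.int(k, 1)
  changes <- 0L
  for (i in rev(seq_len(nrow(edge)))) {       # preorder: parents before children
    p <- edge[i, 1]; ch <- edge[i, 2]
    s <- state[p]
    n_ev <- rpois(1, edge_rates[i])
    if (n_ev > 0) for (j in seq_len(n_ev)) {
      if (kind == "unordered") {
        s <- sample(setdiff(seq_len(k), s), 1)
        changes <- changes + 1L
      } else {
        step <- if (s == 1L) 1L else if (s == k) -1L else sample(c(-1L, 1L), 1)
        s <- s + step
        changes <- changes + 1L
      }
    }
    state[ch] <- s
  }
  masks <- bitwShiftL(1L, state[seq_len(cp$n_tip)] - 1L)
  list(masks = setNames(masks, et$tip.label), changes = changes)
}

#' Simulate a character matrix on a tree
#'
#' Characters evolve independently by a Markov walk along the true tree:
#' unordered characters jump uniformly among their other states, ordered
#' characters step to a neighbouring state (reflecting at the ends), and
#' `change_rate` is the expected number of changes per character over the
#' whole tree. Change events are placed under two regimes. Morphological
#' characters use a speciational model — the expected change count is spread
#' evenly over branches regardless of their duration, reflecting the
#' punctuated tempo and the ascertainment of discrete morphological
#' characters — so short internal branches are as likely to be recorded as
#' long ones. Molecular characters are clock-like: events fall on branches in
#' proportion to their duration in My. The morphology block mixes ordered and
#' unordered characters with 2 to `max_states` states; the molecular block is
#' unordered with 4 states. All characters share the global symbol list
#' `0,1,...`.
#'
#' @param simtree a [sim_tree()] result (or a `phylo` with branch lengths).
#' @param config a [sim_config()].
#' @return a `char_matrix` with attributes `morph_cols`, `mol_cols` (column
#'   indices) and `true_changes` (simulated change counts per character).
#' @export
sim_matrix <- function(simtree, config) {
  tree <- if (inherits(simtree, "sim_tree")) simtree$tree else simtree
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  total_len <- sum(tree$edge.length)
  et0 <- phylo_to_et(tree)
  po <- postorder_rows(et0$edge, et_root(et0))
  n_edge <- length(po)
  # expected events per edge under each placement regime (postorder order)
  rates_clock <- if (total_len > 0)
    config$change_rate * tree$edge.length[po] / total_len else rep(0, n_edge)
  rates_spec <- rep(config$change_rate / n_edge, n_edge)
  S <- max(config$max_states, if (config$n_mol > 0) 4L else 2L)
  symbols <- as.character(0:(S - 1))
  n_total <- config$n_morph + config$n_mol
  masks <- vector("list", n_total)
  specs <- vector("list", n_total)
  changes <- integer(n_total)
  with_seed(config$seed + 1L, {
    for (c_i in seq_len(n_total)) {
      molecular <- c_i > config$n_morph
      k <- if (molecular) 4L else sample(2:config$max_states, 1)
      kind <- if (!molecular && runif(1) < config$ordered_fraction)
        "ordered" else "unordered"
      col <- simulate_column(tree, k, kind,
                             if (molecular) rates_clock else rates_spec,
                             symbols)
      masks[[c_i]] <- unname(col$masks[match(tree$tip.label, names(col$masks))])
      specs[[c_i]] <- char_spec(kind, symbols)
      changes[c_i] <- col$changes
    }
  })
  m <- new_char_matrix(tree$tip.label, masks, specs)
  attr(m, "morph_cols") <- seq_len(config$n_morph)
  attr(m, "mol_cols") <- if (config$n_mol > 0)
    config$n_morph + seq_len(config$n_mol) else integer(0)
  attr(m, "true_changes") <- changes
  m
}

#' Blank fossil cells the way real supermatrices are incomplete
#'
#' Every molecular cell of a fossil taxon becomes missing (fossils yield no
#' sequence data), plus a random fraction of their morphology cells.
#'
#' @param m a `char_matrix`.
#' @param fossil_taxa fossil taxon labels.
#' @param molecular_columns column indices of the molecular block.
#' @param morph_missing_fraction fraction of fossil morphology cells
#'   additionally set to missing.
#' @param seed integer seed for the random blanking.
#' @return the modified `char_matrix`.
#' @export
apply_fossil_missingness <- function(m, fossil_taxa, molecular_columns,
                                     morph_missing_fraction = 0, seed = 1) {
  if (!all(fossil_taxa %in% m$taxa)) stop("unknown fossil taxa")
  molecular_columns <- as.integer(molecular_columns)
  if (length(molecular_columns) &&
      (min(molecular_columns) < 1 || max(molecular_columns) > n_char(m)))
    stop("molecular column indices out of range")
  rows <- match(fossil_taxa, m$taxa)
  for (c_i in molecular_columns) {
    S <- length(m$specs[[c_i]]$state_space)
    m$masks[[c_i]][rows] <- full_mask(S)
  }
  morph_cols <- setdiff(seq_len(n_char(m)), molecular_columns)
  if (morph_missing_fraction > 0 && length(morph_cols) && length(rows)) {
    with_seed(seed, {
      cells <- expand.grid(row = rows, col = morph_cols)
      n_blank <- round(morph_missing_fraction * nrow(cells))
      if (n_blank > 0) {
        pick <- cells[sample.int(nrow(cells), n_blank), ]
        for (i in seq_len(nrow(pick))) {
          S <- length(m$specs[[pick$col[i]]]$state_space)
          m$masks[[pick$col[i]]][pick$row[i]] <- full_mask(S)
        }
      }
    })
  }
  m
}

#' Simulate first/last appearance dates consistent with a true tree
#'
#' Fossil tips appear at their true (extinction) age when preservation is
#' perfect; lower `preservation_rate` pushes the FAD back toward the
#' lineage's origin by a uniform fraction of its pendant branch, blurring the
#' record. Extant tips are dated to the present (FAD = LAD = 0). LADs sit a
#' small uniform interval below the FAD for I/O realism.
#'
#' @param simtree a [sim_tree()] result.
#' @param preservation_rate in (0, 1]; 1 = FAD equals the true tip age.
#' @param seed integer seed.
#' @return an [age_table()] covering every tip.
#' @export
sim_ages <- function(simtree, preservation_rate = 1, seed = 1) {
  stopifnot(inherits(simtree, "sim_tree"),
            preservation_rate > 0, preservation_rate <= 1)
  tree <- simtree$tree
  pend <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                          tree$edge[, 2])], tree$tip.label)
  with_seed(seed, {
    fad <- lad <- numeric(length(tree$tip.label))
    names(fad) <- names(lad) <- tree$tip.label
    for (tx in tree$tip.label) {
      a <- simtree$tip_ages[[tx]]
      if (tx %in% simtree$extant) { fad[tx] <- 0; lad[tx] <- 0; next }
      fad[tx] <- a + (1 - preservation_rate) * runif(1) * pend[[tx]]
      lad[tx] <- max(0, fad[tx] - runif(1, 0, min(2, fad[tx])))
    }
    age_table(tree$tip.label, fad, lad, extant = tree$tip.label %in% simtree$extant)
  })
}

#' Generate a full synthetic combined-evidence dataset
#'
#' Convenience wrapper: birth-death tree, character matrix, fossil-style
#' missingness and a matching age table, all deterministic in
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `simtree`, `matrix` (missingness applied), `ages`,
#'   `extant`, `fossils`, `mol_cols`, `morph_cols`.
#' @export
sim_dataset <- function(config) {
  st <- sim_tree(config)
  m <- sim_matrix(st, config)
  mol <- attr(m, "mol_cols")
  m2 <- apply_fossil_missingness(m, st$fossils, mol,
                                 config$morph_missing_fraction,
                                 seed = config$seed + 2L)
  attributes(m2)[c("morph_cols", "mol_cols", "true_changes")] <-
    attributes(m)[c("morph_cols", "mol_cols", "true_changes")]
  ages <- sim_ages(st, seed = config$seed + 3L)
  list(simtree = st, matrix = m2, ages = ages, extant = st$extant,
       fossils = st$fossils, mol_cols = mol,
       morph_cols = attr(m, "morph_cols"))
}
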