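# Pipeline orchestration ---------------------------------------------------
#
# A single structured config (YAML file or equivalent list) drives the whole
# analysis: load or simulate inputs, choose the weighting mode, search
# (optionally backbone-constrained), consensus, branch support, stratigraphic
# fit, topology tests. Stages run in dependency order, stop downstream on
# failure, write standard formats (Newick, CSV) into an output directory and
# are summarized in a manifest that is reproducible given identical inputs,
# config and seeds.

config_schema <- list(
  inputs = c("matrix", "trees", "ages", "constraint", "floating", "simulate"),
  weighting = c("mode", "k"),
  search = c("enabled", "method", "n_replicates", "max_trees"),
  consensus = c("enabled", "threshold"),
  score = c("enabled", "trees"),
  support = c("enabled", "clades", "mode", "extant_backbone", "fossils",
              "n_replicates"),
  stratfit = c("enabled", "tree", "n_perm"),
  toptest = c("enabled", "treeA", "treeB"),
  seed = NULL,
  out_dir = NULL
)

validate_config <- function(config) {
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (sec in intersect(names(config), names(config_schema))) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    if (!is.list(config[[sec]])) stop("config section '", sec, "' must be a mapping")
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) stop("unknown config key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) stop("config error: 'seed' is required")
  invisible(TRUE)
}

file_digest <- function(path) unname(tools::md5sum(path))

object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  file_digest(f)
}

#' Cross-check the taxon bookkeeping of an input bundle
#'
#' Reports (never fails on) mismatches between the matrix, trees, age table
#' and constraint: tree tips absent from the matrix, unaged tips,
#' backbone/floating overlap, extant taxa that nevertheless lack molecular
#' data, and similar inconsistencies.
#'
#' @param m a `char_matrix` (or `NULL`).
#' @param trees list of `phylo` trees (or `NULL`).
#' @param ages an [age_table()] (or `NULL`).
#' @param constraint a [backbone_constraint()] (or `NULL`).
#' @return data.frame with columns `level` (`"error"`/`"warning"`), `item`,
#'   `message`; zero rows when the bundle is consistent.
#' @export
validate_inputs <- function(m = NULL, trees = NULL, ages = NULL,
                            constraint = NULL) {
  rows <- list()
  note <- function(level, item, msg)
    rows[[length(rows) + 1L]] <<- data.frame(level = level, item = item,
                                             message = msg)
  if (!is.null(trees)) {
    if (inherits(trees, "phylo")) trees <- list(trees)
    for (i in seq_along(trees)) {
      if (!is.null(m)) {
        extra <- setdiff(trees[[i]]$tip.label, m$taxa)
        for (tx in extra) note("error", tx,
                               sprintf("tree %d tip absent from matrix", i))
      }
      if (!is.null(ages)) {
        unaged <- setdiff(trees[[i]]$tip.label, ages$taxon)
        for (tx in unaged) note("error", tx,
                                sprintf("tree %d tip missing from age table", i))
      }
    }
  }
  if (!is.null(constraint)) {
    bb <- constraint$backbone$tip.label
    if (!is.null(m)) {
      for (tx in setdiff(c(bb, constraint$floating), m$taxa))
        note("error", tx, "constraint taxon absent from matrix")
    }
    for (tx in intersect(bb, constraint$floating))
      note("error", tx, "taxon both in backbone and floating set")
    if (!is.null(ages)) {
      fossil_aged <- ages$taxon[!ages$extant]
      for (tx in intersect(bb, fossil_aged))
        note("warning", tx, "backbone (extant) taxon has a fossil age record")
    }
  }
  if (!is.null(ages) && !is.null(m)) {
    for (tx in setdiff(m$taxa, ages$taxon))
      note("warning", tx, "matrix taxon not in age table")
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(0), item = character(0),
               message = character(0))
}

load_pipeline_inputs <- function(config) {
  inp <- config$inputs %||% list()
  out <- list()
  if (!is.null(inp$simulate)) {
    sc <- do.call(sim_config, c(inp$simulate,
                                if (is.null(inp$simulate$seed))
                                  list(seed = config$seed)))
    ds <- sim_dataset(sc)
    out$matrix <- ds$matrix
    out$ages <- ds$ages
    out$trees <- list(ds$simtree$tree)
    out$sim <- ds
  }
  if (!is.null(inp$matrix)) {
    if (!file.exists(inp$matrix)) stop("missing input file: ", inp$matrix)
    out$matrix <- read_nexus(inp$matrix)
  }
  if (!is.null(inp$trees)) {
    if (!file.exists(inp$trees)) stop("missing input file: ", inp$trees)
    tr <- read_newick(inp$trees)
    out$trees <- if (inherits(tr, "phylo")) list(tr) else unclass(tr)
  }
  if (!is.null(inp$ages)) {
    if (!file.exists(inp$ages)) stop("missing input file: ", inp$ages)
    out$ages <- read_age_table(inp$ages)
  }
  if (!is.null(inp$constraint)) {
    if (!file.exists(inp$constraint)) stop("missing input file: ", inp$constraint)
    floating <- if (!is.null(inp$floating)) as.character(unlist(inp$floating))
                else character(0)
    out$constraint <- backbone_constraint(read_newick(inp$constraint), floating)
  }
  out
}

#' Run the combined-evidence pipeline from a config
#'
#' Stages (each enabled in the config): load/simulate inputs, build the
#' weighting scheme, `search` for minimum-length trees (optionally under a
#' backbone constraint), `consensus`, `score` given trees, `support`
#' (BS/ddBS per requested clade), `stratfit`, and `toptest`. Outputs are
#' written to `out_dir` and a manifest (config digest, input digests, seeds,
#' per-stage scores) is returned and saved as YAML.
#'
#' @param config path to a YAML config file, or an equivalent nested list.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return the manifest, invisibly a list of class `run_manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% tempfile("stratpars_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  inputs <- load_pipeline_inputs(config)
  report <- validate_inputs(inputs$matrix, inputs$trees, inputs$ages,
                            inputs$constraint)
  if (nrow(report)) {
    write.table(report, file.path(out_dir, "input_report.csv"), sep = ",",
                row.names = FALSE)
    if (any(report$level == "error"))
      stop("input validation failed; see ", file.path(out_dir, "input_report.csv"))
  }

  manifest <- list(
    tool_version = as.character(utils::packageVersion("stratpars")),
    seed = seed,
    config_digest = object_digest(config),
    input_digests = lapply(Filter(function(x) is.character(x) && file.exists(x),
                                  config$inputs %||% list()), file_digest),
    stages = list()
  )
  m <- inputs$matrix
  if (is.null(m)) stop("config error: no matrix (inputs$matrix or inputs$simulate)")

  wcfg <- config$weighting %||% list()
  weights <- weight_scheme(wcfg$mode %||% "equal", m, k = wcfg$k %||% 3)
  manifest$stages$weighting <- list(mode = weights$mode, k = weights$k)

  trees <- inputs$trees
  scfg <- config$search %||% list()
  if (isTRUE(scfg$enabled)) {
    method <- scfg$method %||% "heuristic"
    res <- if (method == "exhaustive") {
      exhaustive_search(m, weights, constraint = inputs$constraint)
    } else {
      heuristic_search(m, weights, constraint = inputs$constraint,
                       n_replicates = scfg$n_replicates %||% 10, seed = seed,
                       max_trees = scfg$max_trees %||% 10000)
    }
    write_newick(res$best_trees, file.path(out_dir, "best_trees.nwk"))
    manifest$stages$search <- list(best_score = res$best_score,
                                   n_trees = length(res$best_trees),
                                   replicates_hitting_best =
                                     res$replicates_hitting_best)
    trees <- res$best_trees
  }

  ccfg <- config$consensus %||% list()
  if (isTRUE(ccfg$enabled)) {
    if (is.null(trees) || length(trees) < 1) stop("consensus: no trees available")
    cons <- if (is.null(ccfg$threshold)) strict_consensus(trees)
            else majority_consensus(trees, ccfg$threshold)
    write_newick(cons, file.path(out_dir, "consensus.nwk"))
    manifest$stages$consensus <- list(n_input_trees = length(trees),
                                      resolved_clades = cons$Nnode)
  }

  sccfg <- config$score %||% list()
  if (isTRUE(sccfg$enabled)) {
    if (is.null(trees)) stop("score: no trees available")
    scores <- vapply(trees, function(t) tree_length(t, m, weights)$total, 1)
    write.table(data.frame(tree = seq_along(scores), length = scores),
                file.path(out_dir, "tree_lengths.csv"), sep = ",",
                row.names = FALSE)
    manifest$stages$score <- list(lengths = scores)
  }

  supcfg <- config$support %||% list()
  if (isTRUE(supcfg$enabled)) {
    if (is.null(trees)) stop("support: no trees available")
    best <- tree_length(trees[[1]], m, weights)$total
    rows <- list()
    for (i in seq_along(supcfg$clades)) {
      clade <- as.character(unlist(supcfg$clades[[i]]))
      if (identical(supcfg$mode, "ddbs")) {
        bb <- read_newick(supcfg$extant_backbone)
        r <- double_decay_support(m, weights, bb, clade,
                                  fossils = as.character(unlist(supcfg$fossils)),
                                  best_score = best, seed = seed + i,
                                  n_replicates = supcfg$n_replicates %||% 10)
        rows[[i]] <- data.frame(clade = paste(clade, collapse = "+"),
                                support = r$ddbs, mode = "ddbs")
      } else {
        r <- bremer_support(m, weights, clade, best_score = best,
                            seed = seed + i,
                            n_replicates = supcfg$n_replicates %||% 10)
        rows[[i]] <- data.frame(clade = paste(clade, collapse = "+"),
                                support = r$bs, mode = "bs")
      }
    }
    tab <- do.call(rbind, rows)
    write.table(tab, file.path(out_dir, "support.csv"), sep = ",",
                row.names = FALSE)
    manifest$stages$support <- list(table = tab)
  }

  stcfg <- config$stratfit %||% list()
  if (isTRUE(stcfg$enabled)) {
    if (is.null(inputs$ages)) stop("stratfit: no age table available")
    tr <- if (!is.null(stcfg$tree)) read_newick(stcfg$tree) else trees[[1]]
    fit <- strat_fit(tr, inputs$ages, n_perm = stcfg$n_perm %||% 999,
                     seed = seed)
    write.table(fit$per_branch_ghost, file.path(out_dir, "ghost_lineages.csv"),
                sep = ",", row.names = FALSE)
    manifest$stages$stratfit <- fit[c("mig", "g_min", "g_max", "msm_star",
                                      "ger", "p_value")]
  }

  ttcfg <- config$toptest %||% list()
  if (isTRUE(ttcfg$enabled)) {
    ta <- if (!is.null(ttcfg$treeA)) read_newick(ttcfg$treeA) else trees[[1]]
    tb <- read_newick(ttcfg$treeB)
    tt <- topology_test(m, weights, ta, tb)
    manifest$stages$toptest <- tt[c("delta_total", "n_nonzero", "p_templeton",
                                    "p_winning_sites")]
  }

  class(manifest) <- "run_manifest"
  yaml::write_yaml(unclass_manifest(manifest), file.path(out_dir, "manifest.yaml"))
  manifest$out_dir <- out_dir
  invisible(manifest)
}

unclass_manifest <- function(x) {
  x <- unclass(x)
  rapply(x, function(v) if (is.data.frame(v)) as.list(v) else v,
         classes = "data.frame", how = "replace")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
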