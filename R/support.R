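# Branch support ----------------------------------------------------------
#
# Bremer support (BS) is the extra weighted length needed before a clade
# disappears from the optimal set: a converse-constraint search for the
# shortest tree in which the clade is *not* monophyletic. Double-decay branch
# support (ddBS) asks the same question about a relationship among extant
# taxa only: the extant backbone minus the tested split is enforced, the
# split itself is forbidden in the extant restriction, and extinct taxa float
# freely, so only the differential cost of contrasting extant relationships
# is measured. Crown-exclusion analyses instead force one focal fossil inside
# a crown clade and report the step cost of that placement.

support_method <- function(method, n_taxa) {
  method <- match.arg(method, c("auto", "exhaustive", "heuristic"))
  if (method == "auto") if (n_taxa <= 8) "exhaustive" else "heuristic" else method
}

run_support_search <- function(m, weights, taxa, pred, method, n_replicates, seed) {
  if (method == "exhaustive") exhaustive_core(m, weights, taxa, pred)
  else search_core(m, weights, taxa, pred, n_replicates, seed,
                   max_trees = 1000, plateau = FALSE)
}

best_score_of <- function(m, weights, taxa, method, n_replicates, seed) {
  run_support_search(m, weights, taxa, make_pred(), method, n_replicates, seed)$best_score
}

new_support_result <- function(clade, bs, ddbs = NA_real_, suboptimal_tree,
                               best_score, alt_score) {
  structure(list(clade = clade, bs = bs, ddbs = ddbs,
                 suboptimal_tree = suboptimal_tree,
                 best_score = best_score, alt_score = alt_score),
            class = "support_result")
}

#' @export
print.support_result <- function(x, ...) {
  cat(sprintf("support_result for {%s}: bs = %s, ddbs = %s\n",
              paste(x$clade, collapse = ", "),
              format(x$bs, digits = 4), format(x$ddbs, digits = 4)))
  invisible(x)
}

#' Bremer (branch) support of a clade
#'
#' Searches for the shortest tree in which `clade` is not monophyletic and
#' reports the weighted step difference from the optimum.
#'
#' @param m a `char_matrix`.
#' @param weights a `weight_scheme`, numeric vector, or `NULL`.
#' @param clade tip labels of the tested group (a proper subset, >= 2 tips,
#'   with at least two taxa outside it — otherwise no tree can break it).
#' @param best_score optimal score, if already known (recomputed otherwise).
#' @param taxa optional taxon subset to analyse.
#' @param method `"auto"` (exhaustive up to 8 taxa, else heuristic),
#'   `"exhaustive"`, or `"heuristic"`.
#' @param n_replicates,seed heuristic-search settings.
#' @return a `support_result` with fields `clade`, `bs`, `suboptimal_tree`
#'   (a shortest clade-violating tree), `best_score`, `alt_score`.
#' @export
bremer_support <- function(m, weights = NULL, clade, best_score = NULL,
                           taxa = NULL, method = "auto",
                           n_replicates = 10, seed = 1) {
  taxa <- taxa %||% m$taxa
  clade <- unique(as.character(clade))
  if (!all(clade %in% taxa)) stop("clade contains taxa outside the analysis")
  if (length(clade) < 2) stop("clade needs at least two members")
  if (length(taxa) - length(clade) < 2)
    stop("clade is trivially unbreakable (fewer than two taxa outside it)")
  method <- support_method(method, length(taxa))
  if (is.null(best_score))
    best_score <- best_score_of(m, weights, taxa, method, n_replicates, seed)
  alt <- run_support_search(m, weights, taxa,
                            make_pred(forbidden = list(list(split = clade, over = NULL))),
                            method, n_replicates, seed + 1L)
  new_support_result(clade, bs = alt$best_score - best_score,
                     suboptimal_tree = alt$best_trees[[1]],
                     best_score = best_score, alt_score = alt$best_score)
}

#' Double-decay branch support with floating fossils
#'
#' Support for a relationship among extant taxa, measured against the
#' complete matrix: the extant backbone (minus the tested split) is enforced,
#' trees whose extant restriction still shows the split are rejected, and all
#' fossil taxa float. The reported `ddbs` is the weighted step difference
#' between the best such tree and the unconstrained optimum. With no fossils
#' present this reduces exactly to Bremer support.
#'
#' @inheritParams bremer_support
#' @param extant_backbone `phylo` tree on the extant taxa whose relationships
#'   are being protected (minus the tested one).
#' @param target_clade extant tip labels of the tested relationship.
#' @param fossils fossil taxon labels (free to attach anywhere; fossil
#'   placements never count toward the monophyly predicate).
#' @return a `support_result` with `ddbs` filled in (and `bs = NA`).
#' @export
double_decay_support <- function(m, weights = NULL, extant_backbone,
                                 target_clade, fossils = character(0),
                                 best_score = NULL, taxa = NULL,
                                 method = "auto", n_replicates = 10, seed = 1) {
  taxa <- taxa %||% m$taxa
  extant_backbone <- as_phylo_tree(extant_backbone)
  extant <- extant_backbone$tip.label
  target_clade <- unique(as.character(target_clade))
  if (!all(target_clade %in% extant)) stop("target clade must be extant taxa")
  if (length(target_clade) < 2) stop("target clade needs at least two members")
  if (length(extant) - length(target_clade) < 2)
    stop("target clade is trivially unbreakable among the extant taxa")
  if (length(intersect(fossils, extant))) stop("fossils overlap the backbone")
  method <- support_method(method, length(taxa))
  if (is.null(best_score))
    best_score <- best_score_of(m, weights, taxa, method, n_replicates, seed)
  target_key <- split_key(target_clade, extant)
  req <- Filter(function(r) split_key(r$split, extant) != target_key,
                pred_from_constraint(backbone_constraint(extant_backbone, fossils),
                                     taxa)$required)
  pred <- make_pred(required = req,
                    forbidden = list(list(split = target_clade, over = extant)))
  alt <- run_support_search(m, weights, taxa, pred, method, n_replicates, seed + 1L)
  res <- new_support_result(target_clade, bs = NA_real_,
                            ddbs = alt$best_score - best_score,
                            suboptimal_tree = alt$best_trees[[1]],
                            best_score = best_score, alt_score = alt$best_score)
  res
}

#' Cost of forcing a fossil into a crown clade
#'
#' Sequential crown-exclusion analysis: the extant backbone is enforced, one
#' focal fossil is additionally constrained to lie inside the crown clade
#' (its extant members plus the focal fossil must form a group in the
#' restriction to extant taxa plus the fossil), all other fossils float, and
#' the weighted step difference from the unconstrained optimum is returned.
#'
#' @inheritParams double_decay_support
#' @param crown_clade extant tip labels of the crown group.
#' @param focal_fossil the fossil forced inside the crown.
#' @param other_fossils remaining fossil taxa (must not contain the focal).
#' @return a `support_result` whose `ddbs` is the crown-placement step cost.
#' @export
crown_exclusion_ddbs <- function(m, weights = NULL, extant_backbone,
                                 crown_clade, focal_fossil,
                                 other_fossils = character(0),
                                 best_score = NULL, taxa = NULL,
                                 method = "auto", n_replicates = 10, seed = 1) {
  taxa <- taxa %||% m$taxa
  extant_backbone <- as_phylo_tree(extant_backbone)
  extant <- extant_backbone$tip.label
  if (focal_fossil %in% other_fossils) stop("focal fossil listed among other fossils")
  if (focal_fossil %in% extant) stop("focal fossil cannot be an extant backbone taxon")
  if (!all(crown_clade %in% extant)) stop("crown clade must be extant taxa")
  method <- support_method(method, length(taxa))
  if (is.null(best_score))
    best_score <- best_score_of(m, weights, taxa, method, n_replicates, seed)
  pred <- pred_from_constraint(backbone_constraint(extant_backbone,
                                                   c(focal_fossil, other_fossils)),
                               taxa)
  pred$required <- c(pred$required,
                     list(list(split = c(crown_clade, focal_fossil),
                               over = c(extant, focal_fossil))))
  alt <- run_support_search(m, weights, taxa, pred, method, n_replicates, seed + 1L)
  new_support_result(c(crown_clade, focal_fossil), bs = NA_real_,
                     ddbs = alt$best_score - best_score,
                     suboptimal_tree = alt$best_trees[[1]],
                     best_score = best_score, alt_score = alt$best_score)
}

#' Format support values with the conventional reporting rounding
#'
#' Branch support is reported rounded up to the nearest tenth of a step and
#' double-decay support up to the nearest whole step.
#'
#' @param bs numeric vector of Bremer support values.
#' @param ddbs numeric vector of double-decay support values.
#' @return data.frame with raw and rounded columns.
#' @export
format_support <- function(bs, ddbs = NULL) {
  out <- data.frame(bs = bs, bs_reported = ceiling(bs * 10) / 10)
  if (!is.null(ddbs)) {
    out$ddbs <- ddbs
    out$ddbs_reported <- ceiling(ddbs)
  }
  out
}
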