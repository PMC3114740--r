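#!/usr/bin/env Rscript
# Branch support for the synthetic supermatrix optimum: Bremer support over
# all taxa, and double-decay support for the same extant relationships with
# the fossils floating. Reported with the conventional rounding (BS up to a
# tenth of a step, ddBS up to a whole step).

library(stratpars)

m <- read_nexus("results/data/supermatrix.nex")
fossils <- readLines("results/data/fossils.txt")
weights <- weight_scheme("scaled", m)
best_trees <- read_newick("results/best_trees.nwk")
if (inherits(best_trees, "phylo")) best_trees <- list(best_trees)
best <- best_trees[[1]]
best_score <- tree_length(best, m, weights)$total

extant <- setdiff(m$taxa, fossils)
bb <- restrict_tree(best, extant)
clades <- Filter(function(cl) length(cl) >= 2 && length(cl) <= length(extant) - 2,
                 lapply(tree_splits(bb), function(k)
                   strsplit(k, "\r", fixed = TRUE)[[1]]))
clades <- clades[seq_len(min(6, length(clades)))]

rows <- list()
for (i in seq_along(clades)) {
  cl <- clades[[i]]
  b <- bremer_support(m, weights, cl, best_score = best_score,
                      method = "heuristic", n_replicates = 3, seed = 100 + i)
  d <- double_decay_support(m, weights, bb, cl, fossils = fossils,
                            best_score = best_score, method = "heuristic",
                            n_replicates = 3, seed = 200 + i)
  rows[[i]] <- data.frame(clade = paste(sort(cl), collapse = "+"),
                          bs = b$bs, ddbs = d$ddbs)
}
tab <- do.call(rbind, rows)
tab <- cbind(tab, format_support(tab$bs, tab$ddbs)[c("bs_reported", "ddbs_reported")])
write.csv(tab, "results/support.csv", row.names = FALSE)
print(tab, digits = 3)
cat(sprintf("\nddBS >= BS for %d/%d extant clades; median ddBS/BS ratio %.1f\n",
            sum(tab$ddbs >= tab$bs - 1e-6), nrow(tab),
            median((tab$ddbs + 0.01) / (tab$bs + 0.01))))
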