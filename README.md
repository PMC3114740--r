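# stratpars

Combined-evidence parsimony for clades with rich fossil records: weighted
tree search with floating fossils, Bremer and double-decay branch support,
stratigraphic congruence, and ancestral-state homology analysis — in one R
package.

## The problem

Supermatrix studies of groups like whales combine a morphological block
(scored for living and extinct taxa) with a large molecular block that no
fossil can have. Analysing such a matrix raises questions that standard
phylogenetics packages answer only piecemeal:

* How should ordered multistate morphological characters be weighted so a
  ten-state character cannot dominate? (*Between-character scaling*: an
  ordered character with observed span *s* gets weight 1/*s*, so every
  variable character's best case is one step. Homoplastic characters can be
  further down-weighted with *implied weighting*, the concave objective
  `sum_c h_c / (h_c + k)` with concavity constant `k = 3` by default.)
* How are minimum-length trees found when extant relationships are fixed by
  molecular data but fossils must be free to attach anywhere? (*Backbone
  constraints* with floating taxa.)
* How stable is a relationship among living species given the fossils?
  (*Bremer support* `BS = L(best tree without the clade) − L(best tree)`,
  and *double-decay support* ddBS, the same quantity with only the extant
  relationship tested while every fossil floats; and *crown-exclusion*
  costs, the extra steps needed to force a fossil inside a crown clade.)
* Does a topology fit the fossil record? (Ghost lineages; `MIG`, their sum;
  `MSM* = G_min / MIG`, a consistency index of an irreversible
  stratigraphic character; `GER = (G_max − MIG)/(G_max − G_min)`, its
  retention-index analogue; permutation p-values after Siddall.)
* Can a suboptimal fossil placement be rejected? (Templeton
  Wilcoxon-signed-rank and winning-sites sign tests on per-character length
  differences, exact for small samples.)
* Is a state shared by two living species inherited or convergent? (Full
  MPR enumeration with ACCTRAN/DELTRAN, and per-pair homology ("H") versus
  analogy ("A") calls aggregated over all most parsimonious
  reconstructions.)

All parsimony lengths come from one generalized Sankoff dynamic programme
(compiled via Rcpp) handling unordered, ordered and irreversible characters,
polymorphic cells and missing data; every operation is validated against
brute-force enumeration in the test suite. A birth–death simulator generates
matched trees, matrices, fossil-style missingness and stratigraphic ages so
the whole pipeline is testable without any downloads.

## Worked example

```r
library(stratpars)

# a synthetic combined-evidence dataset: 12 extant + 8 fossil taxa,
# 60 morphology + 400 molecular characters (fossils blanked for molecules)
ds  <- sim_dataset(sim_config(seed = 20260101))
w   <- weight_scheme("scaled", ds$matrix)

res <- heuristic_search(ds$matrix, w, n_replicates = 5, seed = 42)
res
#> search_result: best score 540.5000, 34 optimal tree(s), 5 replicate(s) hit the optimum

best <- res$best_trees[[1]]
bb   <- restrict_tree(best, ds$extant)        # extant backbone of the optimum
cl   <- c("t5", "t6")                          # an extant cherry of the optimum
bremer_support(ds$matrix, w, cl, best_score = res$best_score,
               method = "heuristic", n_replicates = 3, seed = 1)
#> support_result for {t5, t6}: bs = 2.333, ddbs = NA
double_decay_support(ds$matrix, w, bb, cl, fossils = ds$fossils,
                     best_score = res$best_score, method = "heuristic",
                     n_replicates = 3, seed = 1)
#> support_result for {t5, t6}: bs = NA, ddbs = 2.333

strat_fit(best, ds$ages, n_perm = 999, seed = 7)
#> strat_fit: MIG 100.00 Ma (G_min 25.88, G_max 434.46), MSM* 0.259, GER 0.819, p = 0.007
```

Read: the minimum-length trees are 540.5 weighted steps long, and there are
34 of them — the incompletely scored fossils float among many equally
parsimonious attachments, exactly the instability double-decay support is
designed to see through. Breaking the (t5,t6) cherry costs 2.33 extra
weighted steps (a fractional value, because ordered multistate characters
carry scaled weights); for this clade no fossil sits inside its stem, so
ddBS equals BS. The tree implies 100 My of summed ghost lineage, much
closer to the best case (25.9 My) than the worst (434 My); only 6 of 999
age permutations fit the record as well (p = 0.007).

The numbered scripts under `analysis/` run the full desk-scale study —
simulate, search (free and backbone-constrained), support, stratigraphic
fit, crown-exclusion topology tests, character-evolution maps — writing
tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

On the bundled study these report, among other things, that double-decay
support meets or exceeds Bremer support for all six tested extant clades
(median ddBS/BS ratio 2.5, e.g. clade t11+t12 with BS 5.5 but ddBS 21.5),
that the true tree fits its own fossil record with GER 0.92 at the
permutation floor p = 0.001, and that forcing the one stem fossil into the
crown clade costs 2.5 steps — too few for the Templeton test to reject
(p = 0.25).

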