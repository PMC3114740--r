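---
title: "Combined-evidence parsimony with fossils: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined-evidence parsimony with fossils: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratpars)
```

# The analysis this package implements

Supermatrix analyses of clades with rich fossil records combine a
morphological character block, scored for living and extinct taxa alike, with
a molecular block that is necessarily missing for every fossil. stratpars
implements the parsimony side of such an analysis end to end:

1. **Weighted parsimony scoring.** Every length in the package comes from one
   generalized Sankoff dynamic programme. Unordered characters use unit
   costs (Fitch counting); ordered characters cost the number of intervening
   states; irreversible characters use an explicit asymmetric cost table.
   Polymorphic cells enter as state sets at zero internal cost and missing
   cells as the full set, so an unscorable fossil cell never adds steps —
   under set-based parsimony, "uncertain" and "polymorphic" score
   identically, which is why the package does not distinguish them.
2. **Between-character scaling.** An ordered character with observed state
   span *s* receives weight 1/*s*, so its best case costs one step, the same
   as a binary character; unordered multistate characters keep weight 1.
   Without this, a ten-state ordered character would dominate the objective.
3. **Implied weighting.** The concave objective sum(h/(h+k)) down-weights
   homoplastic characters dynamically; *h* is computed on scaled steps so
   that the concavity constant *k* (default 3, the value conventionally used
   with this objective) means the same thing for ordered and binary
   characters. The implied-weighting optimum can genuinely differ from the
   equal-weights optimum; the test suite carries a six-taxon instance, found
   by exhaustive screening, where it does.
4. **Tree search.** Exhaustive enumeration is exact up to 9 taxa (135,135
   topologies). The heuristic search uses random taxon-addition starting
   trees followed by subtree-prune-regraft (SPR) hill climbing; because a
   fixed rooting only exposes part of the unrooted SPR neighbourhood, the
   climb re-roots the tree at local optima and sweeps again, which covers
   nearest-neighbour interchanges and the bisection-reconnection-style
   moves a practitioner would expect. Equal-score plateaus are walked
   breadth-first (capped, default 10,000 trees) so that multiple
   minimum-length trees are collected, and ties during taxon addition are
   broken by the seeded RNG — searches are bit-reproducible given
   `(matrix, seed, n_replicates)`.
5. **Backbone constraints.** A molecular scaffold is enforced as split
   compatibility: the candidate tree restricted to the backbone taxa must
   display every backbone bipartition, while all other taxa — fossils —
   float freely. Constraint checks run on partial trees during stepwise
   addition, so constraint-violating insertions are never scored.
6. **Branch support.** Bremer support is a converse-constraint search: the
   shortest tree in which the clade is *not* monophyletic, implemented as a
   filter on candidate trees rather than a penalty, which keeps small
   instances exact. Double-decay support (ddBS) protects the extant backbone
   minus the tested split, forbids that split in the extant restriction and
   lets fossils float; with no fossils it reduces to Bremer support exactly,
   and because its search space is nested inside the Bremer one, ddBS >= BS
   holds for the same clade. Whether the original analyses enforced the full
   extant backbone or only the converse split is not decidable from the
   published description; the package enforces backbone + converse split,
   and the ddBS functions accept any backbone so the other reading is one
   call away. Crown-exclusion analyses constrain one focal fossil inside a
   crown clade and report the step cost of that placement.
7. **Stratigraphic congruence.** Internal nodes are dated at the oldest
   first-appearance datum (FAD) among their descendants; the summed
   parent-minus-child age differences give the minimum implied gap (MIG).
   MSM* = G_min/MIG and GER = (G_max − MIG)/(G_max − G_min), where G_min is
   the FAD range and G_max the sum of distances from the oldest FAD. Both
   use FADs only — last appearances are carried for reporting, not fit —
   and extant tips participate at age 0. The same quantity is reachable as
   the Sankoff length of an irreversible "stratigraphic character" (one
   state per distinct FAD, reversals forbidden), and the identity
   Sankoff = MIG is asserted exactly in the tests. Significance comes from
   permuting the FAD multiset across tips: p = (1 + #{MSM*_perm >=
   MSM*_obs})/(n_perm + 1), so 999 permutations bottom out at p = 0.001.
   The number of character states is always derived from the supplied age
   table (one per distinct FAD) rather than fixed, since published state
   counts and code tables for such characters do not always agree.
8. **Topology tests.** Suboptimal placements are compared with the optimum
   character by character. Zero-difference characters are excluded, as is
   standard for sign-based tests. The Templeton test is the two-tailed
   Wilcoxon signed-rank on the nonzero weighted differences with midranks
   for ties; for 20 or fewer nonzero differences the exact null is built by
   convolution over sign assignments (the reference behaviour), otherwise a
   tie-corrected normal approximation with continuity correction is used and
   labelled as such. The winning-sites test is the exact two-tailed binomial
   sign test.
9. **Ancestral states.** All most parsimonious reconstructions are
   enumerated by Sankoff backtracking (an assignment is optimal iff the root
   takes a minimum-cost state and every node minimizes its subtree cost plus
   the transformation from its parent), with a cap (default 10,000) beyond
   which homology calls degrade to "ambiguous" with a warning. ACCTRAN and
   DELTRAN are greedy tracebacks preferring, respectively, a change on the
   current branch or retention of the parent state; both provably remain
   MPRs. A state shared by two tips is homologous in an MPR when it runs
   unbroken along the path between them, and the calls aggregate to H
   (always), A (never) or ambiguous across MPRs. Note that "DELTRAN pushes
   changes tipward" holds as a statement about total root-to-change depth,
   not about the count of pendant-branch changes — an ACCTRAN reversal can
   itself land on a pendant branch.

# The synthetic data generator

Because the real supermatrix lives in an external repository, every claim
the package makes about itself is validated on synthetic data whose
structure mirrors the combined-evidence setting:

* **Trees** come from a forward birth-death simulation (default 0.15
  speciation, 0.10 extinction per lineage per My — a net diversification in
  the range estimated for crown cetaceans) stopped the first time the
  number of living lineages reaches `n_extant`; `n_fossil` of the extinct
  lineages are kept as fossil tips and the rest pruned. The default shape,
  12 extant + 8 fossils with 60 morphological and 400 molecular characters,
  is the study's structure at desk scale.
* **Characters** evolve by a Markov walk. Morphological changes are placed
  *speciationally* — the expected number of changes per character
  (`change_rate`, default 2) is spread evenly across branches — while
  molecular changes are clock-like, falling on branches in proportion to
  their duration. The speciational choice is deliberate: discrete
  morphological characters are ascertained for variation and evolve with a
  punctuated tempo, and under a strictly clock-like placement short internal
  branches are frequently recorded by no character at all, making the true
  topology unrecoverable in principle rather than in implementation. The
  default `change_rate = 2` leaves most characters variable with moderate
  homoplasy, comparable to the consistency indices of published morphology
  matrices.
* **Missingness** blanks every molecular cell of every fossil, plus a
  configurable fraction (default 0.3) of their morphology cells.
* **Ages**: with perfect preservation a fossil's FAD equals its true
  extinction age; lower `preservation_rate` shifts the FAD along the pendant
  branch by a uniform fraction. LADs sit a small uniform interval below the
  FAD, for I/O realism only — fits use FADs.

What passing the recovery tests does **not** show: the generator has no
among-character rate variation, no correlated characters, no directional or
ordered-biased evolution, no gappy stratigraphic ranges, and its molecular
block is a generic 4-state unordered process rather than a nucleotide
substitution model. Results on real matrices therefore inherit none of those
guarantees; the tests establish that the *implementations* are exact (every
operation is checked against brute-force enumeration on small instances),
not that parsimony is statistically consistent on any particular dataset.

# Numerical choices

* Score ties use a tolerance of 1e-6 weighted steps; totals are sums of
  doubles, and the length-report invariant (total = sum of per-character
  lengths) is exact to 1e-9.
* Forbidden transformations (irreversible reversals, disallowed tip states)
  are encoded as a large finite cost (1e12); any total above half that
  signals an impossible assignment and raises an error rather than a number.
* State spaces are matrix-global (the NEXUS SYMBOLS convention): every
  character's declared space is the full symbol list, so `?` always means
  the full set and round-trips are exact. Unused states are harmless to the
  dynamic programme.
* Degenerate inputs are rejected loudly: GER is undefined (error) when all
  FADs coincide; MSM* is defined as 1 when MIG = 0; Bremer support of a
  clade with fewer than two taxa outside it is an error ("trivially
  unbreakable"); an all-missing character contributes zero everywhere.
* Reported support follows the conventional rounding — BS up to the nearest
  tenth of a step (fractional values arise from scaled ordered characters),
  ddBS up to the nearest step — via `format_support()`, while raw values
  stay full-precision.

# Problem sizes used in validation

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen so the whole suite replays in minutes: oracle-equivalence
checks on 100 random instances of 6-7 taxa (where every topology can be
enumerated and scored independently in R), recovery experiments on 100 seeds
of 12-taxon matrices with 200 morphological characters, and one full
12 + 8-taxon, 460-character pipeline run. The same code paths scale to the
published matrix sizes (dozens of taxa, tens of thousands of characters);
search cost is dominated by SPR sweeps, each of which scores O(n^2)
neighbours at O(n · characters) per tree.

# Known limitations

* The heuristic search targets equal optima, not identical search traces, of
  the "new technology" searches in dedicated programs; on large matrices
  the replicate count is the lever, and the exhaustive oracle is only
  available to 9 taxa.
* TNT-dialect NEXUS extensions, user-defined step matrices in ASSUMPTIONS
  blocks, and irreversible characters have no NEXUS serialization here; the
  stratigraphic character is built in code from the age table instead.
* Partitioned Bremer support, bootstrap/jackknife resampling and
  likelihood-based topology tests are out of scope.
* The pipeline's constrained-analysis score is reported on the package's own
  scale (sum of weighted steps, or sum of h/(h+k) under implied weighting);
  score scales printed by other programs for the same analysis are not
  always directly comparable.
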