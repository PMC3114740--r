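spec01 <- char_spec("unordered", c("0", "1"))

test_that("character lengths match hand-worked cases for every cost regime", {
  tr <- read_newick("((A,B),(C,D));")
  all0 <- setNames(list("0", "0", "0", "0"), LETTERS[1:4])
  expect_equal(character_length(tr, all0, spec01), 0)
  alt <- setNames(list("0", "1", "0", "1"), LETTERS[1:4])
  expect_equal(character_length(tr, alt, spec01), 2)
  spec3o <- char_spec("ordered", c("0", "1", "2"))
  wide <- setNames(list("0", "2", "0", "2"), LETTERS[1:4])
  expect_equal(character_length(tr, wide, spec3o), 4)
  expect_equal(character_length(tr, wide, char_spec("unordered", c("0", "1", "2"))), 2)
  expect_error(character_length(tr, setNames(list("0", "1", "0", "3"), LETTERS[1:4]),
                                spec01), "state")
})

test_that("character_length equals the recursive reference on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n); tr$edge.length <- NULL
    S <- sample(2:4, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    spec <- char_spec(kind, as.character(0:(S - 1)))
    masks <- setNames(sample(seq_len(2^S - 1), n, replace = TRUE), tr$tip.label)
    got <- character_length(tr, masks, spec)
    want <- ref_sankoff(tr, as.list(masks), S, ref_cost_matrix(kind, S))
    expect_equal(got, want)
  }
})

test_that("irreversible cost tables are honoured", {
  # 0 -> 1 costs 1; reversal forbidden
  spec <- char_spec("irreversible", c("0", "1"),
                    cost = matrix(c(0, Inf, 1, 0), 2, 2))
  tr <- read_newick("((A,B),(C,D));")
  col <- setNames(list("1", "0", "1", "0"), LETTERS[1:4])
  # two independent gains (root must stay 0; losses are impossible)
  expect_equal(character_length(tr, col, spec), 2)
  col2 <- setNames(list("1", "1", "1", "1"), LETTERS[1:4])
  expect_equal(character_length(tr, col2, spec), 0)
})

test_that("tree length is invariant under rerooting for reversible costs", {
  set.seed(42)
  tr <- ape::rtree(8); tr$edge.length <- NULL
  m <- random_small_matrix(tr$tip.label, 10)
  base <- tree_length(tr, m)$total
  for (tip in sample(tr$tip.label, 4)) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_length(rr, m)$total, base)
  }
})

test_that("minimum conceivable lengths follow the observed fixed states", {
  expect_equal(min_length(setNames(c(1L, 2L), c("A", "B")), spec01), 1)
  spec5 <- char_spec("ordered", as.character(0:4))
  col <- setNames(as.integer(c(1, 2, 4, 8, 16)), paste0("t", 1:5))
  expect_equal(min_length(col, spec5), 4)
  spec6o <- char_spec("ordered", as.character(0:5))
  spec6u <- char_spec("unordered", as.character(0:5))
  col3 <- setNames(as.integer(c(1, 4, 32)), c("A", "B", "C"))
  expect_equal(min_length(col3, spec6o), 5)
  expect_equal(min_length(col3, spec6u), 2)
  # brute force: the minimum over all trees of 5 informative taxa equals it
  set.seed(7)
  taxa <- paste0("t", 1:5)
  for (i in 1:10) {
    S <- sample(2:4, 1)
    kind <- sample(c("unordered", "ordered"), 1)
    spec <- char_spec(kind, as.character(0:(S - 1)))
    masks <- setNames(bitwShiftL(1L, sample(0:(S - 1), 5, replace = TRUE)), taxa)
    best <- min(vapply(ref_all_topologies(taxa), function(tr)
      ref_sankoff(tr, as.list(masks), S, ref_cost_matrix(kind, S)), numeric(1)))
    expect_equal(min_length(masks, spec), best)
  }
})

test_that("between-character scaling gives every variable character a unit minimum", {
  taxa <- paste0("t", 1:4)
  m <- char_matrix(taxa,
                   list(setNames(as.list(c("0", "4", "2", "0")), taxa),
                        setNames(as.list(c("0", "1", "2", "0")), taxa),
                        setNames(as.list(c("0", "1", "1", "0")), taxa)),
                   list(char_spec("ordered", as.character(0:4)),
                        char_spec("unordered", as.character(0:2)),
                        char_spec("unordered", c("0", "1"))))
  ws <- scaling_weights(m)
  expect_equal(ws$per_char, c(0.25, 1, 1))
  cfg <- sim_config(n_extant = 7, n_fossil = 0, n_morph = 30, n_mol = 0,
                    ordered_fraction = 0.5, max_states = 5, seed = 17)
  ds <- sim_dataset(cfg)
  ws2 <- scaling_weights(ds$matrix)
  mins <- stratpars:::min_lengths_of(ds$matrix)
  variable <- mins > 0
  expect_true(all(abs(ws2$per_char[variable] * mins[variable] - 1) < 1e-9 |
                    vapply(ds$matrix$specs[variable], `[[`, "", "kind") == "unordered"))
  # unordered multistate characters keep weight one
  expect_true(all(ws2$per_char[vapply(ds$matrix$specs, `[[`, "", "kind") == "unordered"] == 1))
})

test_that("tree_length sums weighted per-character lengths and homoplasy", {
  taxa <- LETTERS[1:4]
  tr <- read_newick("((A,B),(C,D));")
  m <- char_matrix(taxa,
                   list(setNames(as.list(c("0", "0", "1", "1")), taxa),
                        setNames(as.list(c("0", "1", "0", "1")), taxa)),
                   list(spec01, spec01))
  rep1 <- tree_length(tr, m, c(1, 0.5))
  expect_equal(rep1$per_char_length, c(1, 1))
  expect_equal(rep1$total, 2)
  expect_equal(rep1$per_char_h, c(0, 1))
  expect_equal(sum(rep1$per_char_length), rep1$total)
  # random 7-taxon matrices agree with the reference total
  set.seed(33)
  for (i in 1:10) {
    taxa7 <- paste0("t", 1:7)
    tr7 <- ape::rtree(7); tr7$edge.length <- NULL; tr7$tip.label <- taxa7
    mm <- random_small_matrix(taxa7, 6)
    w <- runif(6, 0.25, 2)
    expect_equal(tree_length(tr7, mm, w)$total, ref_matrix_length(tr7, mm, w))
  }
})

test_that("implied weighting is bounded, concave-consistent and monotone in k", {
  tr <- read_newick("((A,B),(C,D));")
  taxa <- LETTERS[1:4]
  clean <- char_matrix(taxa, list(setNames(as.list(c("0", "0", "1", "1")), taxa)),
                       list(spec01))
  expect_equal(implied_weight_score(tr, clean, 3), 0)
  noisy <- char_matrix(taxa, list(setNames(as.list(c("0", "1", "0", "1")), taxa)),
                       list(spec01))
  expect_equal(implied_weight_score(tr, noisy, 1), 0.5)   # h = 1, k = 1
  set.seed(12)
  m <- random_small_matrix(paste0("t", 1:6), 8)
  tr6 <- ape::rtree(6); tr6$edge.length <- NULL; tr6$tip.label <- paste0("t", 1:6)
  ks <- c(1, 2, 3, 5, 10)
  scores <- vapply(ks, function(k) implied_weight_score(tr6, m, k), numeric(1))
  expect_true(all(diff(scores) <= 1e-12))
  expect_true(all(scores >= 0 & scores < n_char(m)))
})

test_that("implied and equal weighting can prefer different topologies", {
  # a 6-taxon instance (found by exhaustive screening) where the concave
  # objective tolerates homoplasy concentrated in the 4-state character that
  # equal weighting spreads across the binary ones
  taxa <- paste0("t", 1:6)
  specs <- c(list(char_spec("unordered", as.character(0:3))),
             rep(list(spec01), 3))
  masks <- list(as.integer(c(1, 4, 1, 4, 2, 2)),
                as.integer(c(1, 2, 2, 1, 1, 2)),
                as.integer(c(2, 1, 2, 1, 2, 2)),
                as.integer(c(1, 2, 2, 2, 2, 1)))
  m <- stratpars:::new_char_matrix(taxa, masks, specs)
  eq <- exhaustive_search(m, weight_scheme("equal", m))
  iw <- exhaustive_search(m, weight_scheme("implied", m, k = 0.5))
  sig_eq <- vapply(eq$best_trees, sig_of, "")
  sig_iw <- vapply(iw$best_trees, sig_of, "")
  # verified exhaustively: the two objectives rank topologies differently
  expect_false(setequal(sig_eq, sig_iw))
})
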