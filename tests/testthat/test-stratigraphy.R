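ages3 <- age_table(c("A", "B", "C"), c(10, 5, 0),
                   extant = c(FALSE, FALSE, TRUE))

test_that("node ages propagate the oldest descendant first appearance", {
  na <- node_min_ages("(A,(B,C));", ages3)
  expect_equal(unname(na[c("A", "B", "C")]), c(10, 5, 0))
  expect_equal(unname(na["node5"]), 5)    # (B,C) ancestor
  expect_equal(unname(na["node4"]), 10)   # root
  extant <- age_table(c("A", "B", "C"), c(0, 0, 0), extant = TRUE)
  expect_true(all(node_min_ages("(A,(B,C));", extant) == 0))
  poly <- age_table(c("A", "B", "C"), c(3, 2, 1), extant = FALSE)
  expect_equal(max(node_min_ages("(A,B,C);", poly)), 3)
  expect_error(node_min_ages("(A,(B,D));", ages3), "missing")
})

test_that("MIG sums per-branch ghost durations", {
  expect_equal(mig("(A,(B,C));", ages3), 10)   # 0 + 5 + 0 + 5
  expect_equal(mig("((A,C),B);", ages3), 15)
  same <- age_table(c("A", "B", "C"), c(7, 7, 7), extant = FALSE)
  expect_equal(mig("(A,(B,C));", same), 0)
  gh <- per_branch_ghosts("(A,(B,C));", ages3)
  expect_equal(sum(gh$ghost), 10)
  expect_true(all(gh$ghost >= 0))
})

test_that("GER and MSM* hit their closed-form extremes", {
  expect_equal(ger("(A,(B,C));", ages3), 1)
  expect_equal(msm_star("(A,(B,C));", ages3), 1)
  expect_equal(ger("((A,C),B);", ages3), 0)
  expect_equal(msm_star("((A,C),B);", ages3), 10 / 15)
  same <- age_table(c("A", "B", "C"), c(7, 7, 7), extant = FALSE)
  expect_error(ger("(A,(B,C));", same), "equal")
  expect_equal(msm_star("(A,(B,C));", same), 1)
  # age-ordered pectinate trees of any size are perfect
  n <- 8
  labs <- paste0("t", 1:n)
  nwk <- paste0(paste0("(", labs[-n], ",", collapse = ""), labs[n],
                paste(rep(")", n - 1), collapse = ""), ";")
  at <- age_table(labs, seq(n - 1, 0), extant = c(rep(FALSE, n - 1), TRUE))
  expect_equal(ger(nwk, at), 1)
  expect_equal(msm_star(nwk, at), 1)
})

test_that("GER and MSM* stay within bounds on random trees", {
  set.seed(404)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n); tr$edge.length <- NULL
    fads <- sample(0:40, n, replace = TRUE)
    if (length(unique(fads)) < 2) next
    at <- age_table(tr$tip.label, fads, extant = fads == 0)
    g <- ger(tr, at); ms <- msm_star(tr, at)
    expect_gte(g, 0); expect_lte(g, 1)
    expect_gt(ms, 0); expect_lte(ms, 1)
    fit <- strat_fit(tr, at)
    expect_gte(fit$mig, fit$g_min - 1e-9)
    expect_lte(fit$mig, fit$g_max + 1e-9)
    expect_equal(fit$msm_star, fit$g_min / fit$mig)
  }
})

test_that("the irreversible stratigraphic character reproduces MIG exactly", {
  at <- age_table(c("A", "B", "C"), c(10, 5, 0),
                  extant = c(FALSE, FALSE, TRUE))
  sc <- stratigraphic_character(at)
  expect_equal(length(sc$spec$state_space), 3L)
  expect_equal(unname(sc$state_ages), c(10, 5, 0))
  cm <- sc$spec$cost
  expect_equal(cm[1, 2], 5)            # old -> young costs the age difference
  expect_true(!is.finite(cm[2, 1]))    # reversals forbidden
  expect_equal(diag(cm), rep(0, 3))
  # state symbols continue into letters beyond ten distinct ages
  many <- age_table(paste0("x", 1:12), seq(22, 0, by = -2), extant = FALSE)
  expect_equal(stratigraphic_character(many)$tip_states[["x1"]], "0")
  expect_equal(length(unique(stratigraphic_character(many)$tip_states)), 12L)
  # Sankoff length of the character equals MIG on random trees
  set.seed(88)
  for (i in 1:40) {
    n <- sample(4:9, 1)
    tr <- ape::rtree(n); tr$edge.length <- NULL
    fads <- sample(c(0, 0, 5, 8, 13, 21, 30), n, replace = TRUE)
    if (length(unique(fads)) < 2) next
    at_i <- age_table(tr$tip.label, fads, extant = fads == 0)
    sc_i <- stratigraphic_character(at_i)
    col <- setNames(as.list(sc_i$tip_states[tr$tip.label]), tr$tip.label)
    expect_equal(character_length(tr, col, sc_i$spec), mig(tr, at_i))
  }
})

test_that("permutation significance behaves at both extremes", {
  same <- age_table(c("A", "B", "C", "D"), rep(3, 4), extant = FALSE)
  expect_equal(strat_permutation_test("((A,B),(C,D));", same, 99, seed = 1)$p_value, 1)
  # perfectly age-ordered pectinate tree with many distinct ages
  n <- 10
  labs <- paste0("t", 1:n)
  nwk <- paste0(paste0("(", labs[-n], ",", collapse = ""), labs[n],
                paste(rep(")", n - 1), collapse = ""), ";")
  at <- age_table(labs, seq(n - 1, 0), extant = c(rep(FALSE, n - 1), TRUE))
  res <- strat_permutation_test(nwk, at, n_perm = 999, seed = 2)
  expect_lte(res$p_value, 0.01)
  expect_equal(res$observed, 1)
  # floor of the p value: (1 + 0) / (n_perm + 1)
  expect_gte(res$p_value, 1 / 1000)
})

test_that("true trees fit their own fossil record better than random ones", {
  set.seed(909)
  wins <- 0; trials <- 40
  for (i in 1:trials) {
    cfg <- sim_config(n_extant = 5, n_fossil = 5, n_morph = 0, n_mol = 0,
                      seed = 4000 + i)
    st <- sim_tree(cfg)
    at <- sim_ages(st, preservation_rate = 1, seed = i)
    rnd <- ape::rtree(length(st$tree$tip.label))
    rnd$tip.label <- sample(st$tree$tip.label)
    if (ger(st$tree, at) >= ger(rnd, at) - 1e-9) wins <- wins + 1
  }
  expect_gte(wins / trials, 0.9)
})
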