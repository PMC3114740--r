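spec01 <- char_spec("unordered", c("0", "1"))
mk_col <- function(v, taxa) setNames(as.list(as.character(v)), taxa)

test_that("Bremer support counts the steps needed to break a clade", {
  taxa <- c("A", "B", "C", "D", "E")
  cells <- list(mk_col(c(1, 1, 0, 0, 0), taxa),
                mk_col(c(1, 1, 0, 0, 0), taxa),
                mk_col(c(0, 0, 1, 1, 0), taxa))
  m <- char_matrix(taxa, cells, rep(list(spec01), 3))
  r <- bremer_support(m, clade = c("A", "B"))
  expect_equal(r$bs, 2)
  expect_false(ref_is_clade(r$suboptimal_tree, c("A", "B")))
  # a clade with no character support has zero Bremer support
  r0 <- bremer_support(m, clade = c("A", "C"))
  expect_equal(r0$bs, 0)
  expect_error(bremer_support(m, clade = c("A", "B", "C", "D")), "unbreakable")
  expect_error(bremer_support(m, clade = "A"), "two members")
})

test_that("ordered characters contribute fractional support after scaling", {
  # one ordered character of range 2 (scaled weight 0.5) uniquely separates
  # (A,B): breaking the clade costs half a step
  taxa <- c("A", "B", "C", "D", "E")
  cells <- list(mk_col(c(2, 2, 0, 0, 0), taxa),
                mk_col(c(0, 0, 1, 1, 0), taxa))
  m <- char_matrix(taxa, cells,
                   list(char_spec("ordered", c("0", "1", "2")), spec01))
  ws <- scaling_weights(m)
  r <- bremer_support(m, ws, clade = c("A", "B"))
  expect_equal(r$bs, 1)        # two scaled half-steps: 2 -> 1 -> 0 twice vs once
  expect_equal(r$bs %% 0.5, 0) # supports print conventions like 0.13 -> tenths
  ft <- format_support(c(0.125, 6.85), c(163.2, 12.01))
  expect_equal(ft$bs_reported, c(0.2, 6.9))
  expect_equal(ft$ddbs_reported, c(164, 13))
})

test_that("Bremer support matches the exhaustive converse-constraint oracle", {
  set.seed(301)
  for (i in 1:8) {
    taxa <- paste0("t", 1:6)
    m <- random_small_matrix(taxa, 6)
    opt <- exhaustive_search(m)
    clade <- sample(taxa, 2)
    r <- bremer_support(m, clade = clade, best_score = opt$best_score)
    all_trees <- ref_all_topologies(taxa)
    scores <- vapply(all_trees, ref_matrix_length, numeric(1), m = m)
    lacks <- !vapply(all_trees, ref_is_clade, TRUE, clade = clade)
    expect_equal(r$bs, min(scores[lacks]) - min(scores))
  }
})

test_that("double decay equals Bremer support when no fossils float", {
  taxa <- c("A", "B", "C", "D", "E")
  cells <- list(mk_col(c(1, 1, 0, 0, 0), taxa),
                mk_col(c(1, 1, 1, 0, 0), taxa),
                mk_col(c(0, 0, 1, 1, 0), taxa))
  m <- char_matrix(taxa, cells, rep(list(spec01), 3))
  bb <- exhaustive_search(m)$best_trees[[1]]
  for (clade in list(c("A", "B"), c("D", "E"))) {
    bs <- bremer_support(m, clade = clade)$bs
    dd <- double_decay_support(m, extant_backbone = bb, target_clade = clade)$ddbs
    expect_equal(dd, bs)
  }
})

test_that("floating fossils that subdivide a branch raise ddBS above BS", {
  # extant signal: two characters for (t1,t2); fossil F sits inside the
  # (t1,t2) stem and shares only one of them, so breaking the *extant*
  # relationship with F floating costs more than breaking (t1,t2,F) jointly
  taxa <- c("t1", "t2", "t3", "t4", "t5", "F")
  cells <- list(mk_col(c(1, 1, 0, 0, 0, 1), taxa),
                mk_col(c(1, 1, 0, 0, 0, 1), taxa),
                mk_col(c(1, 1, 0, 0, 0, 0), taxa),
                mk_col(c(0, 0, 1, 1, 0, 0), taxa))
  m <- char_matrix(taxa, cells, rep(list(spec01), 4))
  best <- exhaustive_search(m)$best_score
  bs <- bremer_support(m, clade = c("t1", "t2"), best_score = best)$bs
  bb <- read_newick("((t1,t2),(t3,t4),t5);")
  dd <- double_decay_support(m, extant_backbone = bb,
                             target_clade = c("t1", "t2"), fossils = "F",
                             best_score = best)$ddbs
  expect_gte(dd, bs)
  # oracle: shortest tree whose extant restriction lacks (t1,t2), F anywhere
  all_trees <- ref_all_topologies(taxa)
  scores <- vapply(all_trees, ref_matrix_length, numeric(1), m = m)
  extant <- setdiff(taxa, "F")
  ok <- vapply(all_trees, function(tr) {
    r <- ape::keep.tip(tr, extant)
    !ref_is_clade(r, c("t1", "t2")) &&
      all(c(ref_is_clade(r, c("t3", "t4"))))
  }, TRUE)
  expect_equal(dd, min(scores[ok]) - best)
})

test_that("crown-exclusion cost matches the exhaustive oracle", {
  set.seed(55)
  # a stem fossil with plesiomorphies is costly to force into the crown
  taxa <- c("t1", "t2", "t3", "t4", "F")
  crown <- c("t1", "t2")
  cells <- list(mk_col(c(1, 1, 0, 0, 0), taxa),
                mk_col(c(1, 1, 0, 0, 0), taxa),
                mk_col(c(1, 1, 1, 0, 0), taxa),
                mk_col(c(0, 0, 0, 1, 1), taxa),   # F shares outgroup states
                mk_col(c(0, 0, 0, 1, 1), taxa),
                mk_col(c(0, 0, 0, 1, 1), taxa))
  m <- char_matrix(taxa, cells, rep(list(spec01), 6))
  bb <- read_newick("((t1,t2),t3,t4);")
  best <- exhaustive_search(m)$best_score
  r <- crown_exclusion_ddbs(m, NULL, bb, crown, focal_fossil = "F",
                            best_score = best)
  all_trees <- ref_all_topologies(taxa)
  scores <- vapply(all_trees, ref_matrix_length, numeric(1), m = m)
  ok <- vapply(all_trees, function(tr) {
    ref_is_clade(tr, c(crown, "F")) &&
      ref_is_clade(ape::keep.tip(tr, c("t1", "t2", "t3", "t4")), crown)
  }, TRUE)
  expect_equal(r$ddbs, min(scores[ok]) - best)
  expect_gt(r$ddbs, 0)
  # a fossil matching the crown exactly costs nothing
  cells2 <- cells
  cells2[[4]] <- mk_col(c(1, 1, 0, 0, 1), taxa)
  cells2[[5]] <- mk_col(c(0, 0, 0, 1, 0), taxa)
  cells2[[6]] <- mk_col(c(0, 0, 0, 1, 0), taxa)
  m2 <- char_matrix(taxa, cells2, rep(list(spec01), 6))
  r2 <- crown_exclusion_ddbs(m2, NULL, bb, crown, focal_fossil = "F",
                             best_score = exhaustive_search(m2)$best_score)
  expect_equal(r2$ddbs, 0)
})
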