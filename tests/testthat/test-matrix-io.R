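test_that("minimal NEXUS files parse into state sets", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=3;",
               'FORMAT SYMBOLS="01" MISSING=? GAP=-;',
               "MATRIX",
               "tax_a 0{01}?",
               "tax_b 11-",
               ";", "END;"), f)
  m <- read_nexus(f)
  expect_equal(m$taxa, c("tax_a", "tax_b"))
  expect_equal(cell_states(m, "tax_a", 1), "0")
  expect_equal(cell_states(m, "tax_b", 1), "1")
  expect_equal(cell_states(m, "tax_a", 2), c("0", "1"))   # polymorphism
  expect_equal(cell_states(m, "tax_a", 3), c("0", "1"))   # ? = full set
  expect_equal(cell_states(m, "tax_b", 3), c("0", "1"))   # gap = full set
})

test_that("ASSUMPTIONS typesets and weights are applied and malformed files fail", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=4;",
               'FORMAT SYMBOLS="012";',
               "MATRIX", "a 0120", "b 2101", ";", "END;",
               "BEGIN ASSUMPTIONS;",
               "TYPESET * kinds = ord: 2 4, unord: 1 3;",
               "WTSET * w = 0.25: 2, 1: 1 3-4;",
               "END;"), f)
  m <- read_nexus(f)
  expect_equal(vapply(m$specs, `[[`, "", "kind"),
               c("unordered", "ordered", "unordered", "ordered"))
  expect_equal(vapply(m$specs, `[[`, 1, "weight"), c(1, 0.25, 1, 1))

  bad <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;", "DIMENSIONS NTAX=3 NCHAR=2;",
               "MATRIX", "a 01", "b 10", ";", "END;"), bad)
  expect_error(read_nexus(bad), "dimension")
})

test_that("NEXUS round-trip reproduces cells, kinds and weights", {
  set.seed(11)
  cfg <- sim_config(n_extant = 6, n_fossil = 2, n_morph = 14, n_mol = 6,
                    seed = 31)
  ds <- sim_dataset(cfg)
  m <- ds$matrix
  m$specs[[3]]$weight <- 0.25
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus(m, f)
  m2 <- read_nexus(f)
  expect_equal(m2$taxa, m$taxa)
  expect_equal(lapply(m2$masks, unname), lapply(m$masks, unname))
  expect_equal(vapply(m2$specs, `[[`, "", "kind"),
               vapply(m$specs, `[[`, "", "kind"))
  expect_equal(vapply(m2$specs, `[[`, 1, "weight"),
               vapply(m$specs, `[[`, 1, "weight"))

  # degenerate: zero characters still round-trips
  m0 <- stratpars:::new_char_matrix(c("a", "b"), list(), list())
  write_nexus(m0, f)
  expect_equal(n_char(read_nexus(f)), 0L)
})

test_that("Newick round-trip preserves bipartition sets", {
  expect_equal(length(read_newick("(A,B);")$tip.label), 2L)
  t4 <- read_newick("((A,B),(C,D));")
  expect_equal(length(t4$tip.label), 4L)
  expect_equal(t4$Nnode, 3L)
  set.seed(5)
  for (i in 1:50) {
    tr <- ape::rtree(sample(4:10, 1))
    tr$edge.length <- NULL
    back <- read_newick(write_newick(tr))
    expect_true(trees_identical_unrooted(tr, back))
  }
  expect_error(read_newick("((A,B);"))
})

test_that("age tables validate and force extant taxa to the present", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,FAD,LAD,extant",
               "Zygorhiza,38,35,false",
               "Physeter,,,true"), f)
  at <- read_age_table(f)
  expect_equal(at$fad[at$taxon == "Zygorhiza"], 38)
  expect_equal(at$lad[at$taxon == "Zygorhiza"], 35)
  expect_equal(at$fad[at$taxon == "Physeter"], 0)   # extant = present day
  expect_error(age_table("X", fad = 5, lad = 7), "X")
  expect_error(age_table("Y", fad = -1), "Y")
  # tab-delimited sniffing
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tFAD\tLAD\textant", "A\t10\t9\tfalse"), f2)
  expect_equal(read_age_table(f2)$fad, 10)
})

test_that("interval midpoints average the stratigraphic bounds", {
  expect_equal(interval_midpoint_age(32.3, 30.5), 31.4)
  expect_equal(interval_midpoint_age(5, 5), 5)
  expect_equal(interval_midpoint_age(52, 47), 49.5)
  expect_error(interval_midpoint_age(3, 5), "oldest")
})

test_that("simple gap coding scores exact, containing and absent gaps", {
  expect_equal(n_char(simple_gap_code(c(a = "ACGT", b = "ACGT"))), 0L)

  gc1 <- simple_gap_code(c(s1 = "AC-T", s2 = "AC-T", s3 = "ACGT"))
  expect_equal(n_char(gc1), 1L)
  expect_equal(cell_states(gc1, "s1", 1), "1")
  expect_equal(cell_states(gc1, "s3", 1), "0")

  gc2 <- simple_gap_code(c(q1 = "A--T", q2 = "A--T", q3 = "A---", q4 = "AGGT"))
  expect_equal(n_char(gc2), 2L)
  expect_equal(cell_states(gc2, "q1", 1), "1")
  expect_equal(cell_states(gc2, "q3", 1), c("0", "1"))  # strictly contained -> ?
  expect_equal(cell_states(gc2, "q4", 1), "0")
  expect_equal(cell_states(gc2, "q3", 2), "1")
  expect_equal(cell_states(gc2, "q1", 2), "0")

  expect_error(simple_gap_code(c(a = "AC-T", b = "ACT")), "ragged")
  # invariant: state 1 only for the exact span
  set.seed(9)
  for (i in 1:20) {
    seqs <- vapply(1:5, function(j)
      paste(sample(c("A", "C", "-"), 12, replace = TRUE, prob = c(2, 2, 1)),
            collapse = ""), "")
    names(seqs) <- paste0("x", 1:5)
    gc <- simple_gap_code(seqs)
    if (n_char(gc) == 0) next
    runs <- lapply(seqs, function(s) stratpars:::gap_runs(strsplit(s, "")[[1]]))
    spans <- unique(do.call(rbind, runs))
    spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
    for (c_i in seq_len(n_char(gc))) {
      for (tx in names(seqs)) {
        if (identical(cell_states(gc, tx, c_i), "1")) {
          rn <- runs[[tx]]
          expect_true(any(rn[, 1] == spans[c_i, 1] & rn[, 2] == spans[c_i, 2]))
        }
      }
    }
  }
})
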