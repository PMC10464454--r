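test_that("built-in aligner handles the worked examples deterministically", {
  og <- orthogroup("og", seq_records(c("a@1", "b@1"), c("MK", "MK"),
                                     c("a", "b")))
  a <- align_orthogroup(og)
  expect_equal(unname(a$rows), c("MK", "MK"))
  expect_equal(a$width, 2L)

  # pairwise optimum puts one gap in the shorter row (frozen from the
  # exhaustive affine-gap DP under BLOSUM62)
  og <- orthogroup("og", seq_records(c("a@1", "b@1"), c("MKV", "MV"),
                                     c("a", "b")))
  expect_equal(unname(align_orthogroup(og)$rows), c("MKV", "M-V"))

  og1 <- orthogroup("og", seq_records("a@1", "MKT", "a"))
  expect_equal(unname(align_orthogroup(og1)$rows), "MKT")
  expect_equal(align_orthogroup(og1)$width, 3L)

  # determinism
  og <- orthogroup("og", seq_records(
    c("a@1", "b@1", "c@1"), c("MKVLLAQ", "MVLLAQ", "MKVLAQ"),
    c("a", "b", "c")))
  expect_identical(align_orthogroup(og)$rows, align_orthogroup(og)$rows)
})

test_that("ungapping aligned rows recovers the members exactly", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    seqs <- vapply(seq_len(k), function(j)
      paste(sample(AA, sample(8:40, 1), replace = TRUE), collapse = ""), "")
    og <- orthogroup("og", seq_records(paste0("s", 1:k, "@g"), seqs,
                                       paste0("s", 1:k)))
    rows <- align_orthogroup(og)$rows
    expect_equal(length(unique(nchar(rows))), 1L)
    expect_equal(unname(gsub("-", "", rows[paste0("s", 1:k)])), seqs)
  }
})

test_that("an external aligner command template is honoured", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  og <- orthogroup("og", seq_records(
    c("a@1", "b@1", "c@1"), c("MKVLLAQWERTY", "MVLLAQWERTY", "MKVLAQWERTY"),
    c("a", "b", "c")))
  a <- align_orthogroup(og, external = "mafft --auto {in} > {out}")
  expect_setequal(names(a$rows), c("a", "b", "c"))
  expect_equal(sort(unname(gsub("-", "", a$rows))),
               sort(og$members$seq))
  expect_error(align_orthogroup(og, external = "no_such_tool_xyz {in} {out}"),
               "external aligner failed")
})

test_that("concatenation gap-fills missing taxa and tiles partitions", {
  a1 <- structure(list(og_id = "og1",
                       rows = c(A = strrep("M", 10), B = strrep("K", 10),
                                C = strrep("L", 10)), width = 10L),
                  class = "og_alignment")
  a2 <- structure(list(og_id = "og2",
                       rows = c(A = strrep("R", 7), B = strrep("S", 7)),
                       width = 7L), class = "og_alignment")
  sm <- concatenate(list(a1, a2), taxa = c("A", "B", "C"))
  expect_equal(nchar(unname(sm$matrix)), rep(17L, 3))
  expect_equal(substring(sm$matrix[["C"]], 11, 17), strrep("-", 7))
  expect_equal(sm$partitions$start, c(0L, 10L))
  expect_equal(sm$partitions$end, c(10L, 17L))
  expect_equal(sm_partition_rows(sm, "og2")[[1]], strrep("R", 7))

  # single alignment: supermatrix equals it
  sm1 <- concatenate(list(a1))
  expect_equal(unname(sm1$matrix), unname(a1$rows[sm1$taxa]))

  # zero taxon overlap: every row half gap
  b1 <- structure(list(og_id = "x", rows = c(P = "MMMM"), width = 4L),
                  class = "og_alignment")
  b2 <- structure(list(og_id = "y", rows = c(Q = "KKKK"), width = 4L),
                  class = "og_alignment")
  smx <- concatenate(list(b1, b2))
  expect_equal(unname(smx$matrix), c("MMMM----", "----KKKK"))

  # case-variant collision is an error
  bad <- structure(list(og_id = "z", rows = c(p = "MM"), width = 2L),
                   class = "og_alignment")
  expect_error(concatenate(list(b1, bad)), "case")
})

test_that("NJ recovers tree-additive distances for all 4- and 5-taxon shapes", {
  skip_if_not_installed("phangorn")
  for (n in 4:5) {
    shapes <- phangorn::allTrees(n, rooted = FALSE,
                                 tip.label = paste0("t", seq_len(n)))
    set.seed(n)
    for (si in seq_along(shapes)) {
      tr <- shapes[[si]]  # [[ restores the shared multiPhylo tip labels
      tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
      d <- ape::cophenetic.phylo(tr)
      got <- nj_tree(d)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                             ape::unroot(got))), 0)
    }
  }
  # brute force for the 4-taxon case: the generating split is the one whose
  # paired distances are smallest (four-point condition)
  set.seed(9)
  for (i in 1:20) {
    tr <- ape::rtree(4, tip.label = c("A", "B", "C", "D"))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
    d <- ape::cophenetic.phylo(tr)[c("A", "B", "C", "D"), c("A", "B", "C", "D")]
    sums <- c(AB.CD = d["A", "B"] + d["C", "D"],
              AC.BD = d["A", "C"] + d["B", "D"],
              AD.BC = d["A", "D"] + d["B", "C"])
    truth_split <- names(which.min(sums))
    got <- nj_tree(d)
    pair <- strsplit(sub("\\..*", "", truth_split), "")[[1]]
    rooted <- ape::root(got, outgroup = setdiff(c("A", "B", "C", "D"), pair))
    clade <- ape::extract.clade(rooted, ape::getMRCA(rooted, pair))$tip.label
    expect_setequal(clade, pair)
  }
})

test_that("NJ edge cases behave as specified", {
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  # two identical rows become sisters with zero-length pendant edges
  a <- structure(list(og_id = "og", rows = c(
    A = "MKMKMKMKMK", B = "MKMKMKMKMK", C = "LLLLLQQQQQ", D = "LLLLLRRRRR"),
    width = 10L), class = "og_alignment")
  sm <- concatenate(list(a))
  tr <- nj_tree(sm)
  tip_edge <- match(match(c("A", "B"), tr$tip.label), tr$edge[, 2])
  expect_equal(tr$edge.length[tip_edge], c(0, 0))
  expect_true(all(tr$edge.length >= 0))
  # an all-gap pair is an error
  bad <- structure(list(og_id = "og", rows = c(
    A = "MK--", B = "--MK", C = "MKMK"), width = 4L),
    class = "og_alignment")
  expect_error(p_distance_matrix(concatenate(list(bad))), "comparable")
})

test_that("bootstrap supports are deterministic and bounded", {
  sim <- simulate_proteomes(sim_spec(seed = 31, n_genes = 6,
                                     paralog_rate = 0, loss_rate = 0,
                                     outlier_rate = 0))
  aln <- lapply(lapply(sim$ogs, dedupe_paralogs), align_orthogroup)
  sm <- concatenate(aln)
  t1 <- bootstrap_support(sm, n_replicates = 25, seed = 5)
  t2 <- bootstrap_support(sm, n_replicates = 25, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # a single replicate can only give 0 or 100
  t3 <- bootstrap_support(sm, n_replicates = 1, seed = 2)
  sup3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(sup3[!is.na(sup3)] %in% c(0, 100)))
})

test_that("ML export writes relaxed PHYLIP, NEXUS partitions and the command", {
  a1 <- structure(list(og_id = "og1",
                       rows = c(A = strrep("M", 10), B = strrep("K", 10),
                                C = strrep("L", 10)), width = 10L),
                  class = "og_alignment")
  a2 <- structure(list(og_id = "og2",
                       rows = c(A = strrep("R", 7), B = strrep("S", 7)),
                       width = 7L), class = "og_alignment")
  sm <- concatenate(list(a1, a2), taxa = c("A", "B", "C"))
  dir <- withr::local_tempdir()
  files <- export_ml_inputs(sm, dir)
  phy <- readLines(files$phylip)
  expect_equal(phy[1], "3 17")
  expect_equal(length(phy), 4L)
  nex <- readLines(files$nexus)
  expect_true(any(grepl("charset og1 = 1-10;", nex)))
  expect_true(any(grepl("charset og2 = 11-17;", nex)))
  # round trip the 1-based inclusive ranges back to the partition table
  rng <- regmatches(nex, regexpr("[0-9]+-[0-9]+", nex))
  starts <- as.integer(sub("-.*", "", rng)); ends <- as.integer(sub(".*-", "", rng))
  expect_equal(starts - 1L, sm$partitions$start)
  expect_equal(ends, sm$partitions$end)
  expect_match(files$command, "-bb 1000", fixed = TRUE)
  expect_match(files$command, "-nt AUTO", fixed = TRUE)
  expect_match(files$command, "-seed 291752", fixed = TRUE)
})
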