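test_that("pretrim applies the three rules and reports counts", {
  cfg <- run_config(min_peptide_len = 10L)
  recs <- seq_records(
    id = c("A@dup1", "A@dup2", "B@dup1", "A@star", "A@short9", "A@len10"),
    seq = c("MKTAYIAKQR", "MKTAYIAKQR", "MKTAYIAKQR", "MKT*LLKQRR",
            "MKTAYIAKQ", "MKTAYIAKQW"),
    species = c("A", "A", "B", "A", "A", "A"))
  kept <- pretrim(recs, cfg)
  # identical pair within A collapsed to lexicographically-first id;
  # same sequence in B is untouched (collapse is within-species)
  expect_true("A@dup1" %in% kept$id)
  expect_false("A@dup2" %in% kept$id)
  expect_true("B@dup1" %in% kept$id)
  expect_false("A@star" %in% kept$id)   # contains '*'
  expect_false("A@short9" %in% kept$id) # 9 aa < 10
  expect_true("A@len10" %in% kept$id)   # exactly 10 aa kept
  expect_equal(attr(kept, "report"),
               c(exact_duplicate = 1L, asterisk = 1L, too_short = 1L))
  # input order preserved; empty input is legal
  expect_equal(kept$id, c("A@dup1", "B@dup1", "A@len10"))
  expect_equal(nrow(pretrim(recs[0, ], cfg)), 0L)
})

test_that("branch outlier flagging matches the worked quartile example", {
  tr <- "((A@1:0.1,B@1:0.1):0.01,(C@1:0.1,D@1:1.0):0.01);"
  fl <- flag_branch_outliers(tr)
  expect_equal(unclass(fl)[1], "D@1")
  # Q1 = 0.1, Q3 = 0.325, fence = 0.325 + 1.5 * 0.225 = 0.6625
  expect_equal(attr(fl, "fence"), 0.6625)

  # all equal: IQR = 0, nothing flagged
  expect_length(
    flag_branch_outliers("((A@1:0.2,B@1:0.2):0.1,(C@1:0.2,D@1:0.2):0.1);"), 0)

  # the long leaf in the outgroup: excluded from statistics and flagging,
  # and with only 3 usable leaves flagging is skipped entirely
  fl <- flag_branch_outliers(tr, outgroup = "D")
  expect_length(fl, 0)
  expect_true(is.na(attr(fl, "fence")))

  # outgroup exclusion with enough remaining leaves
  tr5 <- "((A@1:0.1,B@1:0.1):0.01,((C@1:0.1,E@1:0.1):0.01,D@1:1.0):0.01);"
  fl <- flag_branch_outliers(tr5, outgroup = "D")
  expect_length(fl, 0)
  expect_false(is.na(attr(fl, "fence")))

  # a leaf without a branch length is an error naming the leaf
  expect_error(
    flag_branch_outliers(ape::read.tree(text = "((A@1,B@1),(C@1,D@1));")),
    "branch length")
})

test_that("flagging agrees with a brute-force quartile/fence oracle", {
  set.seed(11)
  for (i in 1:500) {
    k <- sample(4:12, 1)
    pend <- setNames(round(runif(k, 0, 1), 3), paste0("t", seq_len(k), "@m"))
    tr <- tree_with_pendants(pend)
    got <- sort(as.character(flag_branch_outliers(tr)))
    expect_identical(got, sort(fence_flag_oracle(pend)))
  }
})

test_that("raising iqr_factor never flags more leaves", {
  set.seed(12)
  for (i in 1:60) {
    k <- sample(4:10, 1)
    pend <- setNames(runif(k, 0, 2), paste0("t", seq_len(k), "@m"))
    tr <- tree_with_pendants(pend)
    flagged <- lapply(c(0.5, 1.0, 1.5, 3.0), function(f)
      as.character(flag_branch_outliers(tr, iqr_factor = f)))
    for (j in seq_len(length(flagged) - 1))
      expect_true(all(flagged[[j + 1]] %in% flagged[[j]]))
  }
})

test_that("linked-presence filter keeps all-or-none groups", {
  linked <- list(c("Csub", "Cdem"))
  mk <- function(sp) orthogroup("og", seq_records(
    paste0(sp, "@g"), rep(strrep("M", 20), length(sp)), sp))
  expect_true(filter_linked_presence(mk(c("Csub", "Cdem", "X")), linked))
  expect_false(filter_linked_presence(mk(c("Csub", "X")), linked))
  expect_true(filter_linked_presence(mk(c("X", "Y")), linked))
  expect_true(filter_linked_presence(mk("X"), list()))  # no-op without groups
})

test_that("min-species filter exempts outgroup-only orthogroups", {
  outgroup <- c("O1", "O2", "O3")
  mk <- function(sp) orthogroup("og", seq_records(
    paste0(sp, "@g"), rep(strrep("M", 20), length(sp)), sp))
  expect_false(filter_min_species(mk(c("A", "B")), outgroup))     # 2 < 3
  expect_true(filter_min_species(mk(c("O1", "O2")), outgroup))    # exempt
  expect_true(filter_min_species(mk(c("A", "B", "O1")), outgroup))
  # single outgroup taxon: nothing can be discarded
  expect_true(filter_min_species(mk("A"), "O1"))
  expect_error(filter_min_species(mk("A"), character(0)), "non-empty")
})

test_that("paralog pruning keeps the longest member, ties by smallest id", {
  og <- orthogroup("og", seq_records(
    id = c("X@a", "X@b", "Y@only", "Z@x2", "Z@x1"),
    seq = c(strrep("M", 100), strrep("M", 120), strrep("K", 50),
            strrep("A", 100), strrep("A", 100)),
    species = c("X", "X", "Y", "Z", "Z")))
  out <- dedupe_paralogs(og)
  expect_setequal(out$members$id, c("X@b", "Y@only", "Z@x1"))
  expect_true(all(table(out$members$species) <= 1))
  # single member per species: unchanged
  og1 <- orthogroup("og", seq_records("X@a", "MKTAYIAKQR", "X"))
  expect_equal(dedupe_paralogs(og1)$members, og1$members)
})

test_that("postprocessing applies the four steps in order with a report", {
  ogs <- fixture_ten_ogs()
  cfg <- fixture_cfg()
  res <- run_postprocessing(ogs, cfg)
  rep <- res$report
  expect_equal(rep$discarded_at[rep$og_id == "OG09"], "step2_linked")
  expect_true(is.na(rep$discarded_at[rep$og_id == "OG10"]))  # exempt
  expect_equal(sum(!is.na(rep$discarded_at)), 1L)
  expect_equal(length(res$ogs), 9L)
  for (og in res$ogs)
    expect_true(all(table(og$members$species) <= 1))
  # paralogs in OG02/OG04 were removed at step 4 and attributed there
  expect_equal(rep$paralogs_removed[rep$og_id == "OG02"], 1L)
  expect_equal(rep$paralogs_removed[rep$og_id == "OG04"], 2L)
  # filters never invent members
  in_ids <- unlist(lapply(ogs, function(o) o$members$id))
  out_ids <- unlist(lapply(res$ogs, function(o) o$members$id))
  expect_true(all(out_ids %in% in_ids))
  # degenerate inputs
  expect_equal(length(run_postprocessing(list(), cfg)$ogs), 0L)
})

test_that("a paralog that is also an outlier is removed and attributed at step 1", {
  seqs <- seq_records(
    id = c("A@a", "B@b", "C@c", "X@x1", "X@x2"),
    seq = c(strrep("M", 20), strrep("K", 20), strrep("L", 20),
            strrep("A", 20), strrep("A", 30)),
    species = c("A", "B", "C", "X", "X"))
  tree <- "((A@a:0.1,B@b:0.1):0.05,(C@c:0.1,(X@x1:0.1,X@x2:2.0):0.05):0.05);"
  og <- orthogroup("og", seqs, tree)
  cfg <- run_config(outgroup = "Zout")
  # outgroup species absent from this group: step 3 must not discard it
  res <- run_postprocessing(list(og), cfg)
  rep <- res$report
  expect_equal(rep$outliers_removed, 1L)
  expect_equal(rep$paralogs_removed, 0L)  # nothing left for step 4 to do
  expect_false("X@x2" %in% res$ogs[[1]]$members$id)
  expect_true("X@x1" %in% res$ogs[[1]]$members$id)
})

test_that("run configs round-trip through the key-value file format", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# roles",
               "species_of_interest = Csub",
               "linked_groups = Csub+Cdem",
               "outgroup = O1, O2",
               "min_peptide_len = 12",
               "iqr_factor = 2.0"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$species_of_interest, "Csub")
  expect_equal(cfg$linked_groups, list(c("Csub", "Cdem")))
  expect_equal(cfg$outgroup, c("O1", "O2"))
  expect_equal(cfg$min_peptide_len, 12L)
  expect_equal(cfg$iqr_factor, 2.0)
})

test_that("orthogroup directories round-trip", {
  sim <- simulate_proteomes(sim_spec(seed = 3, n_genes = 4), build_trees = TRUE)
  dir <- withr::local_tempdir()
  write_orthogroups(sim$ogs, dir)
  back <- read_orthogroups(file.path(dir, "orthogroups.tsv"))
  expect_equal(length(back), length(sim$ogs))
  for (o in sim$ogs) {
    b <- back[[o$og_id]]
    expect_setequal(b$members$id, o$members$id)
    expect_equal(b$members$seq[order(b$members$id)],
                 o$members$seq[order(o$members$id)])
    if (!is.null(o$tree)) expect_setequal(b$tree$tip.label, o$tree$tip.label)
  }
})
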