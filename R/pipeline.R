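#' Run the plastome phylogenomics pipeline on orthogroup input
#'
#' Orchestrates: pre-orthology trimming of all member peptides, the four
#' post-orthology cleaning steps, per-orthogroup alignment, supermatrix
#' concatenation, and a bootstrapped neighbor-joining tree. Gene trees
#' missing from the input are rebuilt by NJ on the members
#' ([og_gene_tree()]). Deterministic under a fixed seed with the built-in
#' aligner.
#'
#' @param ogs list of [orthogroup()] objects (from [read_orthogroups()] or
#'   [simulate_proteomes()]).
#' @param cfg a [run_config()]; species of interest and outgroup taxa must
#'   occur in the input (checked before any compute).
#' @param bootstrap_n bootstrap replicates for the final tree (0 = none).
#' @param seed seed for bootstrap resampling.
#' @param aligner optional external aligner command template passed to
#'   [align_orthogroup()].
#' @param taxa optional taxon output order (defaults to species of
#'   interest, then the rest sorted).
#' @return list of class `pipeline_result` with `supermatrix`, `tree`,
#'   `ogs` (cleaned) and `report` (a `pipeline_report`).
#' @export
run_pipeline <- function(ogs, cfg, bootstrap_n = 100L, seed = 1L,
                         aligner = NULL, taxa = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  all_species <- unique(unlist(lapply(ogs, og_species)))
  missing_roles <- setdiff(c(cfg$species_of_interest, cfg$outgroup,
                             unlist(cfg$linked_groups)), all_species)
  if (length(missing_roles))
    stop("config error: species not present in input: ",
         paste(missing_roles, collapse = ", "))

  records_in <- sum(vapply(ogs, function(o) nrow(o$members), 0L))

  # pre-orthology trimming, applied to the pooled members
  pool <- do.call(rbind, lapply(ogs, function(o) o$members))
  kept <- pretrim(pool, cfg)
  pretrim_report <- attr(kept, "report")
  ogs2 <- list()
  pretrim_empty <- 0L
  for (o in ogs) {
    o2 <- drop_members(o, setdiff(o$members$id, kept$id))
    if (!nrow(o2$members)) { pretrim_empty <- pretrim_empty + 1L; next }
    if (is.null(o2$tree) && nrow(o2$members) >= 3L)
      o2$tree <- og_gene_tree(o2)
    ogs2[[length(ogs2) + 1L]] <- o2
  }

  post <- run_postprocessing(ogs2, cfg)
  if (!length(post$ogs))
    stop("empty supermatrix: no orthogroups survived filtering")

  alignments <- lapply(post$ogs, align_orthogroup, external = aligner)
  if (is.null(taxa))
    taxa <- c(cfg$species_of_interest,
              sort(setdiff(all_species, cfg$species_of_interest)))
  sm <- concatenate(alignments, taxa = taxa)
  if (length(sm$taxa) < 3L)
    stop("empty supermatrix: fewer than 3 taxa survived filtering")
  tree <- if (bootstrap_n > 0L) bootstrap_support(sm, bootstrap_n, seed)
          else nj_tree(sm)

  members_out <- sum(vapply(post$ogs, function(o) nrow(o$members), 0L))
  report <- structure(list(
    records_in = records_in,
    pretrim = pretrim_report,
    records_after_pretrim = nrow(kept),
    ogs_in = length(ogs),
    ogs_empty_after_pretrim = pretrim_empty,
    ogs_into_postprocessing = length(ogs2),
    postprocessing = post$report,
    ogs_out = length(post$ogs),
    members_out = members_out,
    supermatrix_columns = nchar(sm$matrix[[1L]]),
    taxa = sm$taxa,
    bootstrap_n = bootstrap_n,
    seed = seed), class = "pipeline_report")

  structure(list(supermatrix = sm, tree = tree, ogs = post$ogs,
                 report = report), class = "pipeline_result")
}

#' Check that a pipeline report's counts reconcile across stages
#'
#' Records out of one stage must equal records into the next; removals and
#' survivors must sum to the inputs.
#'
#' @param report a `pipeline_report`.
#' @return TRUE invisibly; an error describes any mismatch.
#' @export
reconcile_report <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  if (report$records_in - sum(report$pretrim) != report$records_after_pretrim)
    stop("pretrim counts do not reconcile")
  if (report$ogs_in - report$ogs_empty_after_pretrim !=
      report$ogs_into_postprocessing)
    stop("orthogroup counts into postprocessing do not reconcile")
  pp <- report$postprocessing
  if (sum(!is.na(pp$discarded_at)) + report$ogs_out != nrow(pp))
    stop("postprocessing discard counts do not reconcile")
  kept <- is.na(pp$discarded_at)
  ok <- pp$members_in[kept] - pp$outliers_removed[kept] -
    pp$paralogs_removed[kept] == pp$members_out[kept]
  if (!all(ok)) stop("per-orthogroup member counts do not reconcile")
  if (sum(pp$members_out[kept]) != report$members_out)
    stop("total member counts do not reconcile")
  invisible(TRUE)
}

#' @param x a `pipeline_report`.
#' @param ... unused.
#' @rdname run_pipeline
#' @export
print.pipeline_report <- function(x, ...) {
  cat("plastophylo pipeline report\n")
  cat(sprintf("  peptides in: %d; removed by pretrim: %d duplicate, %d with '*', %d short; out: %d\n",
              x$records_in, x$pretrim[["exact_duplicate"]],
              x$pretrim[["asterisk"]], x$pretrim[["too_short"]],
              x$records_after_pretrim))
  pp <- x$postprocessing
  cat(sprintf("  orthogroups in: %d (%d emptied by pretrim)\n",
              x$ogs_in, x$ogs_empty_after_pretrim))
  cat(sprintf("  step 1 outliers removed: %d; discarded: %d at step 2, %d at step 3\n",
              sum(pp$outliers_removed),
              sum(pp$discarded_at == "step2_linked", na.rm = TRUE),
              sum(pp$discarded_at == "step3_min_species", na.rm = TRUE)))
  cat(sprintf("  step 4 paralogs removed: %d\n", sum(pp$paralogs_removed)))
  cat(sprintf("  orthogroups out: %d; members: %d; supermatrix: %d taxa x %d columns\n",
              x$ogs_out, x$members_out, length(x$taxa),
              x$supermatrix_columns))
  cat(sprintf("  bootstrap: %d replicates, seed %d\n", x$bootstrap_n, x$seed))
  invisible(x)
}

#' Is the species of interest sister to its reference?
#'
#' Roots the tree on the outgroup and tests whether the two taxa form a
#' two-leaf clade; also returns that clade's bootstrap support when node
#' labels are present.
#'
#' @param tree a `phylo` with the taxa as tips.
#' @param interest,reference,outgroup taxon labels.
#' @return list with `sister` (logical) and `support` (numeric or NA).
#' @export
sister_check <- function(tree, interest, reference, outgroup) {
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  pair <- c(interest, reference)
  mrca <- ape::getMRCA(rooted, pair)
  tips <- ape::extract.clade(rooted, mrca)$tip.label
  sister <- setequal(tips, pair)
  support <- NA_real_
  if (!is.null(tree$node.label)) {
    m2 <- ape::getMRCA(tree, pair)
    lab <- tree$node.label[m2 - length(tree$tip.label)]
    if (!is.na(lab) && nzchar(lab)) support <- as.numeric(lab)
  }
  list(sister = sister, support = support)
}
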