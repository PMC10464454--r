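#' Run configuration for orthogroup cleaning
#'
#' @param species_of_interest character vector of focal species tags.
#' @param linked_groups list of character vectors; each set is treated
#'   all-or-none during filtering (typically an interest species paired with
#'   its close reference).
#' @param outgroup character vector of outgroup species tags.
#' @param min_peptide_len minimum peptide length in aa kept by [pretrim()]
#'   (default 10).
#' @param iqr_factor fence multiplier for branch-length outliers
#'   (default 1.5).
#' @param two_sided flag also unusually short branches (default FALSE: only
#'   long branches are suspect).
#' @return object of class `run_config`.
#' @export
run_config <- function(species_of_interest = character(0),
                       linked_groups = list(),
                       outgroup = character(0),
                       min_peptide_len = 10L,
                       iqr_factor = 1.5,
                       two_sided = FALSE) {
  if (min_peptide_len < 1L) stop("min_peptide_len must be >= 1")
  if (iqr_factor <= 0) stop("iqr_factor must be > 0")
  stopifnot(is.list(linked_groups))
  structure(list(species_of_interest = species_of_interest,
                 linked_groups = linked_groups,
                 outgroup = outgroup,
                 min_peptide_len = as.integer(min_peptide_len),
                 iqr_factor = iqr_factor,
                 two_sided = isTRUE(two_sided)),
            class = "run_config")
}

#' Read a key-value run configuration file
#'
#' INI-style `key = value` lines; `#` comments. Lists are comma-separated;
#' `linked_groups` entries are `+`-joined within a group and comma-separated
#' between groups (e.g. `linked_groups = Csub+Cdem, X+Y`).
#'
#' @param path config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- lapply(strsplit(lines, "=", fixed = TRUE), function(p)
    c(trimws(p[1L]), trimws(paste(p[-1L], collapse = "="))))
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  split_list <- function(x) if (is.na(x) || !nzchar(x)) character(0)
                            else trimws(strsplit(x, ",")[[1L]])
  lg <- lapply(split_list(vals["linked_groups"]), function(g)
    trimws(strsplit(g, "+", fixed = TRUE)[[1L]]))
  run_config(
    species_of_interest = split_list(vals["species_of_interest"]),
    linked_groups = lg,
    outgroup = split_list(vals["outgroup"]),
    min_peptide_len = as.integer(vals["min_peptide_len"] %|na|% 10L),
    iqr_factor = as.numeric(vals["iqr_factor"] %|na|% 1.5))
}

`%|na|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Orthogroup container
#'
#' @param og_id orthogroup name.
#' @param members record data frame of amino-acid members (see
#'   [seq_records()]); every member needs a species tag.
#' @param tree optional gene tree (`ape::phylo` or a newick string) whose
#'   leaf labels are member ids.
#' @return object of class `orthogroup` with fields `og_id`, `members`,
#'   `tree`.
#' @export
orthogroup <- function(og_id, members, tree = NULL) {
  stopifnot(is.character(og_id), nzchar(og_id))
  if (nrow(members) && any(is.na(members$species)))
    stop("orthogroup '", og_id, "': all members need species tags")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!is.null(tree)) {
    if (!setequal(tree$tip.label, members$id))
      stop("orthogroup '", og_id, "': tree leaves do not match member ids")
    if (is.null(tree$edge.length))
      stop("orthogroup '", og_id, "': gene tree has no branch lengths")
  }
  structure(list(og_id = og_id, members = members, tree = tree),
            class = "orthogroup")
}

#' @param og an orthogroup.
#' @rdname orthogroup
#' @return `og_species`: the set of species tags present.
#' @export
og_species <- function(og) unique(og$members$species)

#' Pre-orthology trimming of peptide sets
#'
#' Applied before orthology inference: (a) within each species, byte-identical
#' sequences are collapsed to one representative (the lexicographically
#' smallest id) since they are uninformative exact-duplicate paralogs;
#' (b) sequences containing `*` (internal stops from flawed annotations) are
#' removed; (c) sequences shorter than `cfg$min_peptide_len` amino acids are
#' removed.
#'
#' @param records record data frame of peptides with species tags.
#' @param cfg a [run_config()].
#' @return the kept records, with attribute `report` counting removals per
#'   rule (`exact_duplicate`, `asterisk`, `too_short`).
#' @export
pretrim <- function(records, cfg = run_config()) {
  report <- c(exact_duplicate = 0L, asterisk = 0L, too_short = 0L)
  if (nrow(records)) {
    ord <- order(records$species, records$seq, records$id)
    r <- records[ord, , drop = FALSE]
    dup <- duplicated(r[, c("species", "seq")])
    report["exact_duplicate"] <- sum(dup)
    r <- r[!dup, , drop = FALSE]
    ast <- grepl("*", r$seq, fixed = TRUE)
    report["asterisk"] <- sum(ast)
    r <- r[!ast, , drop = FALSE]
    short <- nchar(r$seq) < cfg$min_peptide_len
    report["too_short"] <- sum(short)
    r <- r[!short, , drop = FALSE]
    records <- r[order(match(r$id, records$id)), , drop = FALSE]
    rownames(records) <- NULL
  }
  attr(records, "report") <- report
  records
}

#' Quartiles by linear interpolation
#'
#' Q1/Q3 via linear interpolation between order statistics (R's default
#' definition, type 7), factored out so tests can target it directly.
#'
#' @param x numeric vector.
#' @return named vector `c(q1, q3, iqr)`.
#' @export
iqr_quartiles <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.75), type = 7, names = FALSE))
  c(q1 = q[1L], q3 = q[2L], iqr = q[2L] - q[1L])
}

#' Flag terminal branch-length outliers in a gene tree
#'
#' The terminal (pendant) branch length of every non-outgroup leaf is
#' collected; leaves whose length exceeds `Q3 + iqr_factor * IQR` (quartiles
#' by linear interpolation) are flagged as outliers. Outgroup leaves are
#' excluded from both the statistics and the flagging. With fewer than four
#' usable leaves the quartiles are still computed but flagging is skipped
#' (quartiles on so few points are unstable).
#'
#' @param tree `ape::phylo` or newick string with branch lengths; leaf labels
#'   are member ids carrying the species tag.
#' @param outgroup character vector of outgroup species tags.
#' @param iqr_factor fence multiplier (default 1.5).
#' @param two_sided also flag leaves below `Q1 - iqr_factor * IQR`.
#' @param species_regex regex extracting the species tag from a leaf label
#'   (first capture group); labels that do not match are their own tag.
#' @return character vector of flagged leaf labels (member ids), with
#'   attribute `fence` (the upper fence, `NA` when flagging was skipped).
#' @export
flag_branch_outliers <- function(tree, outgroup = character(0),
                                 iqr_factor = 1.5, two_sided = FALSE,
                                 species_regex = "^([^@]+)@") {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  tip_edge <- match(seq_len(ntip), tree$edge[, 2L])
  if (anyNA(tip_edge) || anyNA(tree$edge.length[tip_edge])) {
    bad <- tree$tip.label[which(is.na(tip_edge) |
                                is.na(tree$edge.length[tip_edge]))[1L]]
    stop("leaf '", bad, "' has no branch length")
  }
  pend <- setNames(tree$edge.length[tip_edge], tree$tip.label)
  sp <- ifelse(grepl(species_regex, names(pend)),
               sub(paste0(species_regex, ".*$"), "\\1", names(pend)),
               names(pend))
  usable <- pend[!(sp %in% outgroup)]
  if (length(usable) < 4L) {
    out <- character(0)
    attr(out, "fence") <- NA_real_
    return(out)
  }
  q <- iqr_quartiles(usable)
  hi <- q[["q3"]] + iqr_factor * q[["iqr"]]
  flagged <- names(usable)[usable > hi]
  if (isTRUE(two_sided)) {
    lo <- q[["q1"]] - iqr_factor * q[["iqr"]]
    flagged <- union(flagged, names(usable)[usable < lo])
  }
  attr(flagged, "fence") <- hi
  flagged
}

#' Orthogroup presence filters
#'
#' `filter_linked_presence()`: for every linked species set, the orthogroup
#' must contain all of it or none of it ("all either present or absent"),
#' else it is discarded. `filter_min_species()`: orthogroups with fewer
#' species than there are outgroup taxa are discarded, except groups
#' consisting solely of outgroup species, which are exempt.
#'
#' @param og an [orthogroup()].
#' @param linked_groups list of character vectors of species tags.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_linked_presence <- function(og, linked_groups) {
  sp <- og_species(og)
  for (g in linked_groups) {
    n <- sum(g %in% sp)
    if (n != 0L && n != length(g)) return(FALSE)
  }
  TRUE
}

#' @param outgroup character vector of outgroup species tags (non-empty).
#' @rdname filter_linked_presence
#' @export
filter_min_species <- function(og, outgroup) {
  if (!length(outgroup)) stop("outgroup must be non-empty")
  sp <- og_species(og)
  if (all(sp %in% outgroup)) return(TRUE)  # outgroup-only groups are exempt
  length(sp) >= length(outgroup)
}

#' Keep only the longest sequence per species
#'
#' Among remaining within-species paralogs only the longest sequence is
#' kept; ties are broken by the lexicographically smallest id.
#'
#' @param og an [orthogroup()].
#' @return the orthogroup with at most one member per species (the gene tree
#'   is dropped when members were removed, as its leaves no longer match).
#' @export
dedupe_paralogs <- function(og) {
  m <- og$members
  if (!nrow(m)) return(og)
  ord <- order(m$species, -nchar(m$seq), m$id)
  m <- m[ord, , drop = FALSE]
  keep <- !duplicated(m$species)
  removed <- sum(!keep)
  m <- m[keep, , drop = FALSE]
  m <- m[order(match(m$id, og$members$id)), , drop = FALSE]
  rownames(m) <- NULL
  orthogroup(og$og_id, m, if (removed == 0L) og$tree else NULL)
}

drop_members <- function(og, ids) {
  m <- og$members[!og$members$id %in% ids, , drop = FALSE]
  rownames(m) <- NULL
  tree <- og$tree
  if (!is.null(tree) && length(ids)) {
    if (nrow(m) >= 2L) {
      tree <- ape::drop.tip(tree, intersect(tree$tip.label, ids))
    } else tree <- NULL
  }
  orthogroup(og$og_id, m, tree)
}

#' Four-step post-orthology cleaning
#'
#' Applies, in order: (1) removal of terminal branch-length outliers per
#' gene tree ([flag_branch_outliers()]); (2) discarding orthogroups where a
#' linked species set is only partially present; (3) discarding orthogroups
#' with fewer species than outgroup taxa (outgroup-only groups exempt);
#' (4) within-species paralog pruning to the longest sequence. Orthogroups
#' left without members after step 1 are discarded there.
#'
#' @param ogs list of [orthogroup()] objects; each needs a gene tree for
#'   step 1 (groups with < 4 usable leaves are passed through unflagged).
#' @param cfg a [run_config()].
#' @return list with `ogs` (the cleaned orthogroups) and `report`, a data
#'   frame with one row per input orthogroup recording members removed in
#'   steps 1 and 4 and the step (if any) at which the group was discarded.
#' @export
run_postprocessing <- function(ogs, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!length(ogs)) {
    return(list(ogs = list(), report = data.frame(
      og_id = character(0), members_in = integer(0),
      outliers_removed = integer(0), discarded_at = character(0),
      paralogs_removed = integer(0), members_out = integer(0))))
  }
  report <- data.frame(og_id = vapply(ogs, function(o) o$og_id, ""),
                       members_in = vapply(ogs, function(o) nrow(o$members), 0L),
                       outliers_removed = 0L, discarded_at = NA_character_,
                       paralogs_removed = 0L, members_out = 0L)
  out <- list()
  for (i in seq_along(ogs)) {
    og <- ogs[[i]]
    # step 1: branch-length outliers
    if (!is.null(og$tree)) {
      flagged <- flag_branch_outliers(og$tree, cfg$outgroup,
                                      iqr_factor = cfg$iqr_factor,
                                      two_sided = cfg$two_sided)
      report$outliers_removed[i] <- length(flagged)
      og <- drop_members(og, flagged)
      if (!nrow(og$members)) { report$discarded_at[i] <- "step1_empty"; next }
    }
    # step 2: linked presence
    if (!filter_linked_presence(og, cfg$linked_groups)) {
      report$discarded_at[i] <- "step2_linked"; next
    }
    # step 3: outgroup count
    if (length(cfg$outgroup) && !filter_min_species(og, cfg$outgroup)) {
      report$discarded_at[i] <- "step3_min_species"; next
    }
    # step 4: paralog pruning
    before <- nrow(og$members)
    og <- dedupe_paralogs(og)
    report$paralogs_removed[i] <- before - nrow(og$members)
    report$members_out[i] <- nrow(og$members)
    out[[length(out) + 1L]] <- og
  }
  list(ogs = out, report = report)
}

# ---- orthogroup I/O ---------------------------------------------------------

#' Read and write orthogroup directories
#'
#' Layout mirroring common orthology-tool output: a membership TSV with
#' columns `og_id`, `species`, `member_id`, per-orthogroup FASTA files
#' `<og_id>.fa` (headers are member ids) and optional newick gene trees
#' `<og_id>.nwk` in `dir`.
#'
#' @param tsv_path membership table path.
#' @param dir directory holding `<og_id>.fa` / `<og_id>.nwk`.
#' @return `read_orthogroups`: list of [orthogroup()] objects.
#' @export
read_orthogroups <- function(tsv_path, dir = dirname(tsv_path)) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  stopifnot(all(c("og_id", "species", "member_id") %in% names(tab)))
  lapply(split(tab, tab$og_id), function(g) {
    recs <- read_fasta(file.path(dir, paste0(g$og_id[1L], ".fa")))
    recs <- recs[match(g$member_id, recs$id), , drop = FALSE]
    recs$species <- g$species
    nwk <- file.path(dir, paste0(g$og_id[1L], ".nwk"))
    tree <- if (file.exists(nwk)) ape::read.tree(nwk) else NULL
    orthogroup(g$og_id[1L], recs, tree)
  })
}

#' @param ogs list of orthogroups.
#' @rdname read_orthogroups
#' @export
write_orthogroups <- function(ogs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(ogs, function(o)
    data.frame(og_id = o$og_id, species = o$members$species,
               member_id = o$members$id)))
  write.table(tab, file.path(dir, "orthogroups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (o in ogs) {
    write_fasta(o$members, file.path(dir, paste0(o$og_id, ".fa")))
    if (!is.null(o$tree))
      ape::write.tree(o$tree, file.path(dir, paste0(o$og_id, ".nwk")))
  }
  invisible(file.path(dir, "orthogroups.tsv"))
}
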