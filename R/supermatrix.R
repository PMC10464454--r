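#' Align an orthogroup
#'
#' Multiple alignment of an orthogroup's members. By default a built-in
#' center-star progressive aligner is used: all pairwise global alignments
#' are computed under BLOSUM62 with affine gaps (open 10, extend 1), the
#' member with the highest summed pairwise score is the center, and the
#' remaining members are merged against it ("once a gap, always a gap").
#' Deterministic for fixed input. Alternatively `external` is a command
#' template with `{in}`/`{out}` placeholders (e.g.
#' `"mafft --maxiterate 1000 --localpair {in} > {out}"`) run on an unaligned
#' FASTA of the members.
#'
#' @param og an [orthogroup()] with at least one member.
#' @param external optional external aligner command template.
#' @return object of class `og_alignment`: list with `og_id`, `rows` (named
#'   character vector of equal-length gapped sequences, names = species) and
#'   `width`.
#' @export
align_orthogroup <- function(og, external = NULL) {
  m <- og$members
  if (!nrow(m)) stop("orthogroup '", og$og_id, "' has no members")
  if (anyDuplicated(m$species))
    stop("orthogroup '", og$og_id,
         "' still has within-species paralogs; run dedupe_paralogs() first")
  if (!is.null(external)) {
    rows <- run_external_aligner(m, external)
  } else if (nrow(m) == 1L) {
    rows <- setNames(m$seq, m$species)
  } else {
    rows <- center_star_align(setNames(m$seq, m$species))
  }
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("aligner returned rows of unequal length")
  structure(list(og_id = og$og_id, rows = rows, width = w),
            class = "og_alignment")
}

run_external_aligner <- function(members, template) {
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  tmp <- members; tmp$id <- tmp$species
  write_fasta(tmp, fin)
  cmd <- gsub("{in}", shQuote(fin), gsub("{out}", shQuote(fout),
              template, fixed = TRUE), fixed = TRUE)
  err <- tempfile()
  status <- suppressWarnings(system(paste(cmd, "2>", shQuote(err))))
  if (status != 0L || !file.size(fout))
    stop("external aligner failed (exit ", status, "): ",
         paste(readLines(err, warn = FALSE), collapse = " "))
  aln <- read_fasta(fout, moltype = "aa")
  setNames(toupper(aln$seq), aln$id)
}

# pairwise global alignment, affine gaps, BLOSUM62; returns the two gapped rows
pairwise_align <- function(a, b, gap_open = 10, gap_ext = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_ext, type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# center-star progressive alignment over a named vector of sequences
center_star_align <- function(seqs) {
  k <- length(seqs)
  if (k == 1L) return(seqs)
  pair <- rep(list(vector("list", k)), k)
  total <- numeric(k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pa <- pairwise_align(seqs[[i]], seqs[[j]])
    pair[[i]][[j]] <- pa
    total[i] <- total[i] + pa$score
    total[j] <- total[j] + pa$score
  }
  c0 <- which.max(total)  # ties: first index, deterministic
  center <- seqs[[c0]]
  n <- nchar(center)
  # gaps[i] = columns inserted before center residue i (i = n+1: after last)
  gaps <- integer(n + 1L)
  split <- vector("list", k)
  others <- setdiff(seq_len(k), c0)
  for (j in others) {
    pa <- if (j > c0) pair[[c0]][[j]] else {
      p <- pair[[j]][[c0]]; list(a = p$b, b = p$a)
    }
    s <- split_by_center(pa$a, pa$b)  # pa$a = center row, pa$b = other row
    split[[j]] <- s
    gaps <- pmax(gaps, nchar(s$inserts))
  }
  rows <- setNames(character(k), names(seqs))
  cres <- strsplit(center, "", fixed = TRUE)[[1L]]
  rows[c0] <- paste0(paste(mapply(function(g, r) paste0(strrep("-", g), r),
                                  gaps[seq_len(n)], cres), collapse = ""),
                     strrep("-", gaps[n + 1L]))
  for (j in others) {
    s <- split[[j]]
    body <- paste(mapply(function(ins, g, r)
      paste0(strrep("-", g - nchar(ins)), ins, r),
      s$inserts[seq_len(n)], gaps[seq_len(n)], s$opposite), collapse = "")
    tail_ins <- s$inserts[n + 1L]
    rows[j] <- paste0(body, tail_ins,
                      strrep("-", gaps[n + 1L] - nchar(tail_ins)))
  }
  rows
}

# decompose the "other" row of a pairwise alignment relative to the center:
# inserts[i] = other-row characters falling before center residue i (inserts
# [n+1]: after the last); opposite[i] = the character aligned to residue i.
split_by_center <- function(center_row, other_row) {
  cc <- strsplit(center_row, "", fixed = TRUE)[[1L]]
  oc <- strsplit(other_row, "", fixed = TRUE)[[1L]]
  n <- sum(cc != "-")
  inserts <- character(n + 1L); inserts[] <- ""
  opposite <- character(n)
  i <- 0L
  for (p in seq_along(cc)) {
    if (cc[p] == "-") {
      inserts[i + 1L] <- paste0(inserts[i + 1L], oc[p])
    } else {
      i <- i + 1L
      opposite[i] <- oc[p]
    }
  }
  list(inserts = inserts, opposite = opposite)
}

#' Concatenate orthogroup alignments into a supermatrix
#'
#' Alignments are laid side by side; species absent from an orthogroup are
#' filled with gaps across that partition. Partition coordinates are kept
#' 0-based half-open internally and tile the matrix exactly.
#'
#' @param alignments list of `og_alignment` objects.
#' @param taxa optional taxon ordering; defaults to the sorted union of row
#'   names. Species names differing only by case are rejected.
#' @return object of class `supermatrix`: `taxa`, `matrix` (named character
#'   vector of concatenated rows) and `partitions` (data frame `og_id`,
#'   `start`, `end`).
#' @export
concatenate <- function(alignments, taxa = NULL) {
  if (!length(alignments)) stop("no alignments to concatenate")
  all_sp <- unique(unlist(lapply(alignments, function(a) names(a$rows))))
  if (anyDuplicated(tolower(all_sp)))
    stop("species names colliding across case variants: ",
         paste(all_sp[duplicated(tolower(all_sp))], collapse = ", "))
  if (is.null(taxa)) taxa <- sort(all_sp)
  else {
    taxa <- c(taxa[taxa %in% all_sp], sort(setdiff(all_sp, taxa)))
  }
  rows <- setNames(rep("", length(taxa)), taxa)
  parts <- data.frame(og_id = character(0), start = integer(0),
                      end = integer(0))
  pos <- 0L
  for (a in alignments) {
    w <- a$width
    filler <- strrep("-", w)
    add <- vapply(taxa, function(t)
      if (t %in% names(a$rows)) a$rows[[t]] else filler, "")
    rows <- paste0(rows, add)
    names(rows) <- taxa
    parts <- rbind(parts, data.frame(og_id = a$og_id, start = pos,
                                     end = pos + w))
    pos <- pos + w
  }
  structure(list(taxa = taxa, matrix = rows, partitions = parts),
            class = "supermatrix")
}

#' @param sm a supermatrix.
#' @param og_id a partition name.
#' @rdname concatenate
#' @return `sm_partition_rows`: the (still gapped) rows of one partition.
#' @export
sm_partition_rows <- function(sm, og_id) {
  p <- sm$partitions[sm$partitions$og_id == og_id, ]
  if (nrow(p) != 1L) stop("no such partition: ", og_id)
  substring(sm$matrix, p$start + 1L, p$end)
}

sm_char_matrix <- function(sm) {
  do.call(rbind, strsplit(unname(sm$matrix), "", fixed = TRUE))
}

# p-distance with pairwise gap deletion over a character matrix (rows = taxa)
pdist_from_chars <- function(ch, taxa) {
  n <- nrow(ch)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  ok <- ch != "-" & ch != "?"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- ok[i, ] & ok[j, ]
    m <- sum(comp)
    if (m == 0L)
      stop("taxa '", taxa[i], "' and '", taxa[j],
           "' share no comparable (ungapped) columns")
    d[i, j] <- d[j, i] <- sum(ch[i, comp] != ch[j, comp]) / m
  }
  d
}

#' Pairwise p-distances of a supermatrix
#'
#' Proportion of differing residues over columns where both rows are
#' ungapped. A pair with zero comparable columns is an error.
#'
#' @param sm a [concatenate()] supermatrix.
#' @return symmetric numeric matrix of p-distances.
#' @export
p_distance_matrix <- function(sm) {
  pdist_from_chars(sm_char_matrix(sm), sm$taxa)
}

#' Neighbor-joining tree of a supermatrix
#'
#' NJ (via `ape::nj`) on p-distances with pairwise gap deletion. Negative
#' estimated edge lengths are clamped to zero. Deterministic for fixed
#' input.
#'
#' @param sm a supermatrix with at least three taxa, or a distance matrix.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(sm) {
  d <- if (inherits(sm, "supermatrix")) p_distance_matrix(sm) else as.matrix(sm)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the supermatrix NJ tree
#'
#' Columns are resampled with replacement `n_replicates` times; each
#' replicate gets its own p-distance NJ tree, and the support of each
#' internal edge of the point-estimate tree is the percentage of replicate
#' trees containing the same bipartition. Supports are stored in
#' `node.label`; the root of the unrooted representation carries no support.
#'
#' @param sm a supermatrix (>= 3 taxa).
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed, recorded on the result.
#' @return the point-estimate `phylo` with `node.label` percentages and
#'   attribute `seed`.
#' @export
bootstrap_support <- function(sm, n_replicates = 100L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  ch <- sm_char_matrix(sm)
  point <- nj_tree(structure(pdist_from_chars(ch, sm$taxa), class = "matrix"))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(ncol(ch), ncol(ch), replace = TRUE)
    boots[[r]] <- nj_tree(pdist_from_chars(ch[, idx, drop = FALSE], sm$taxa))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- round(100 * counts / n_replicates)
  supp[1L] <- NA  # root of the unrooted representation: trivial bipartition
  point$node.label <- ifelse(is.na(supp), "", as.character(supp))
  attr(point, "seed") <- seed
  point
}

#' Export supermatrix inputs for an external ML tree builder
#'
#' Writes a relaxed PHYLIP alignment, a NEXUS `sets` block with 1-based
#' inclusive charset ranges, and a shell command file invoking IQ-TREE with
#' `-nt AUTO -bb 1000` and the pipeline's fixed seed 291752.
#'
#' @param sm a supermatrix.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the three file paths and the command
#'   string.
#' @export
export_ml_inputs <- function(sm, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  phy <- file.path(outdir, "supermatrix.phy")
  width <- nchar(sm$matrix[[1L]])
  con <- file(phy, "w")
  writeLines(paste(length(sm$taxa), width), con)
  writeLines(paste(sm$taxa, unname(sm$matrix[sm$taxa])), con)
  close(con)
  nex <- file.path(outdir, "partitions.nex")
  cs <- sprintf("  charset %s = %d-%d;", sm$partitions$og_id,
                sm$partitions$start + 1L, sm$partitions$end)
  writeLines(c("#nexus", "begin sets;", cs, "end;"), nex)
  cmd <- sprintf("iqtree -s %s -spp %s -nt AUTO -bb 1000 -seed 291752",
                 basename(phy), basename(nex))
  cmdfile <- file.path(outdir, "run_iqtree.sh")
  writeLines(cmd, cmdfile)
  invisible(list(phylip = phy, nexus = nex, command_file = cmdfile,
                 command = cmd))
}
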