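#' Simulation specification for synthetic proteomes
#'
#' The generator's stated world: peptides evolve down a fixed species tree by
#' i.i.d. residue substitutions at branch-length rates (uniform replacement,
#' no rate matrix — adequate for exercising filters and distance trees, not
#' biologically realistic). Paralogs are within-species duplicates with extra
#' divergence and a truncated tail; losses drop a gene from a species;
#' planted outliers re-evolve a member at `outlier_multiplier` times its
#' pendant branch length.
#'
#' @param seed integer seed; all outputs are byte-identical under a fixed
#'   seed.
#' @param tree newick species tree with branch lengths in expected
#'   substitutions per site. The default is an 8-taxon tree: `Csub` (species
#'   of interest) sister to its reference `Cdem`, five background species
#'   and a distant outgroup `Out`.
#' @param n_genes number of ancestral genes (orthogroups).
#' @param gene_len_range min/max ancestral gene length in aa.
#' @param paralog_rate per (gene, species) probability of a duplicate.
#' @param loss_rate per (gene, species) probability of loss.
#' @param outlier_rate per-gene probability of planting one branch-length
#'   outlier in a random non-outgroup species.
#' @param outlier_multiplier factor applied to the outlier's pendant branch.
#' @param outgroup outgroup species tags (never chosen as outliers).
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     tree = paste0("(((Csub:0.03,Cdem:0.03):0.03,",
                                   "((Sp1:0.04,Sp2:0.04):0.02,Sp3:0.05):0.02)",
                                   ":0.02,(Sp4:0.05,Sp5:0.05):0.03,Out:0.2);"),
                     n_genes = 40L, gene_len_range = c(80L, 250L),
                     paralog_rate = 0.05, loss_rate = 0.05,
                     outlier_rate = 0.05, outlier_multiplier = 10,
                     outgroup = "Out") {
  stopifnot(paralog_rate >= 0, paralog_rate <= 1, loss_rate >= 0,
            loss_rate <= 1, outlier_rate >= 0, outlier_rate <= 1,
            n_genes >= 1L, gene_len_range[1L] <= gene_len_range[2L])
  structure(list(seed = as.integer(seed), tree = tree,
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range),
                 paralog_rate = paralog_rate, loss_rate = loss_rate,
                 outlier_rate = outlier_rate,
                 outlier_multiplier = outlier_multiplier,
                 outgroup = outgroup),
            class = "sim_spec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# substitute each site with probability 1 - exp(-bl), uniform replacement
evolve_seq <- function(chars, bl) {
  p <- -expm1(-bl)
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    repl <- sample(AA20, sum(hit), replace = TRUE)
    same <- repl == chars[hit]
    while (any(same)) {  # uniform over the 19 other residues
      repl[same] <- sample(AA20, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  chars
}

#' Simulate per-species proteomes with known orthogroup truth
#'
#' One orthogroup per ancestral gene. Returns the orthogroups (with gene
#' trees rebuilt by neighbor joining on the simulated members, so outlier
#' flagging sees estimation noise rather than the species tree itself) and
#' truth tables sufficient to score every downstream filter exactly.
#'
#' @param spec a [sim_spec()].
#' @param build_trees attach NJ gene trees to orthogroups (default TRUE).
#' @return list with `ogs` (list of [orthogroup()]), `truth` (data frames
#'   `outliers`, `paralogs`, `losses` keyed by og and member), `species`,
#'   and the `spec`.
#' @export
simulate_proteomes <- function(spec = sim_spec(), build_trees = TRUE) {
  set.seed(spec$seed)
  phy <- ape::read.tree(text = spec$tree)
  species <- phy$tip.label
  ntip <- length(species)
  root <- ntip + 1L
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])

  outliers <- list(); paralogs <- list(); losses <- list()
  ogs <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("OG%04d", g)
    len <- sample(seq(spec$gene_len_range[1L], spec$gene_len_range[2L]), 1L)
    tips <- vector("list", ntip)      # tip char vectors
    parents <- vector("list", ntip)   # parent seq + pendant bl, for outliers
    walk <- function(node, chars) {
      for (ei in children[[as.character(node)]]) {
        child <- phy$edge[ei, 2L]; bl <- phy$edge.length[ei]
        evolved <- evolve_seq(chars, bl)
        if (child <= ntip) {
          tips[[child]] <<- evolved
          parents[[child]] <<- list(chars = chars, bl = bl)
        } else walk(child, evolved)
      }
    }
    walk(root, sample(AA20, len, replace = TRUE))

    # plant at most one outlier per gene, never in the outgroup
    out_tip <- 0L
    if (runif(1L) < spec$outlier_rate) {
      pool <- which(!species %in% spec$outgroup)
      out_tip <- sample(pool, 1L)
      p <- parents[[out_tip]]
      tips[[out_tip]] <- evolve_seq(p$chars, p$bl * spec$outlier_multiplier)
    }

    ids <- character(0); seqs <- character(0); sps <- character(0)
    for (t in seq_len(ntip)) {
      if (runif(1L) < spec$loss_rate) {
        losses[[length(losses) + 1L]] <- data.frame(og_id = gid,
                                                    species = species[t])
        if (t == out_tip) out_tip <- 0L
        next
      }
      mid <- paste0(species[t], "@g", sprintf("%04d", g))
      ids <- c(ids, mid); sps <- c(sps, species[t])
      seqs <- c(seqs, paste(tips[[t]], collapse = ""))
      if (t == out_tip)
        outliers[[length(outliers) + 1L]] <- data.frame(og_id = gid,
                                                        member_id = mid)
      if (runif(1L) < spec$paralog_rate) {
        dup <- evolve_seq(tips[[t]], 0.02)
        dup <- dup[seq_len(max(1L, floor(0.85 * length(dup))))]
        pid <- paste0(mid, ".p2")
        ids <- c(ids, pid); sps <- c(sps, species[t])
        seqs <- c(seqs, paste(dup, collapse = ""))
        paralogs[[length(paralogs) + 1L]] <- data.frame(og_id = gid,
                                                        member_id = pid)
      }
    }
    if (!length(ids)) { ogs[[g]] <- NULL; next }
    og <- orthogroup(gid, seq_records(ids, seqs, sps, "aa"))
    if (build_trees && nrow(og$members) >= 3L)
      og$tree <- og_gene_tree(og)
    ogs[[g]] <- og
  }
  bindf <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(ogs = Filter(Negate(is.null), ogs),
       truth = list(
         outliers = bindf(outliers, data.frame(og_id = character(0),
                                               member_id = character(0))),
         paralogs = bindf(paralogs, data.frame(og_id = character(0),
                                               member_id = character(0))),
         losses = bindf(losses, data.frame(og_id = character(0),
                                           species = character(0)))),
       species = species, spec = spec)
}

#' Neighbor-joining gene tree of an orthogroup's members
#'
#' Leaves are member ids (so paralogs are legal). Members of equal length
#' are compared directly; otherwise they are center-star aligned first.
#'
#' @param og an [orthogroup()] with >= 3 members.
#' @return an `ape::phylo` tree with non-negative branch lengths.
#' @export
og_gene_tree <- function(og) {
  seqs <- setNames(og$members$seq, og$members$id)
  if (length(seqs) < 3L) stop("gene tree needs at least 3 members")
  if (length(unique(nchar(seqs))) > 1L) seqs <- center_star_align(seqs)
  ch <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  nj_tree(pdist_from_chars(ch, names(seqs)))
}

#' Write simulated proteomes as per-species FASTA files
#'
#' @param sim result of [simulate_proteomes()].
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_proteomes <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pool <- do.call(rbind, lapply(sim$ogs, function(o) o$members))
  paths <- vapply(split(pool, pool$species), function(p) {
    f <- file.path(dir, paste0(p$species[1L], ".faa"))
    write_fasta(p, f)
    f
  }, "")
  invisible(paths)
}

# ---- plastome / read simulation --------------------------------------------

#' Simulation specification for plastome reads
#'
#' The stated world for the polisher: a random plastid-sized contig with
#' homopolymer runs of `true_run_len` planted at evenly spaced sites; the
#' draft assembly carries an indel (`offsets`, draft minus truth) at each
#' site; reads sampled uniformly at `depth` carry the true run length with
#' probability `true_fraction` and the draft's erroneous length otherwise,
#' and are otherwise error-free, with CIGARs correct by construction.
#'
#' @param seed integer seed.
#' @param genome_len contig length in bp (default 20000).
#' @param read_len read length in bp.
#' @param depth target fold coverage.
#' @param true_run_len homopolymer length in the true sequence.
#' @param offsets integer vector of planted draft errors (one site each;
#'   negative = draft lost bases, positive = draft gained bases). Length 0
#'   plants nothing.
#' @param true_fraction fraction of reads showing the true run length.
#' @return object of class `sim_read_spec`.
#' @export
sim_read_spec <- function(seed = 1L, genome_len = 20000L, read_len = 1000L,
                          depth = 30, true_run_len = 7L,
                          offsets = c(-1L, -1L, -1L, 1L),
                          true_fraction = 0.6) {
  stopifnot(genome_len > 4L * read_len, depth > 0, true_run_len >= 3L,
            true_fraction >= 0, true_fraction <= 1,
            all(offsets != 0L), all(abs(offsets) < true_run_len))
  structure(list(seed = as.integer(seed), genome_len = as.integer(genome_len),
                 read_len = as.integer(read_len), depth = depth,
                 true_run_len = as.integer(true_run_len),
                 offsets = as.integer(offsets),
                 true_fraction = true_fraction),
            class = "sim_read_spec")
}

#' Simulate a draft plastome with planted homopolymer errors plus reads
#'
#' @param spec a [sim_read_spec()].
#' @param genome optional nucleotide string to use as the true sequence
#'   (sites are still planted into it unless `offsets` is empty).
#' @param dir optional directory; when given, `reference.fa`, `draft.fa` and
#'   `reads.sam` are written there.
#' @return list with `reference` (true contig), `draft` (erroneous contig),
#'   `sam` (alignment data frame in [read_sam()] layout), `truth` (data
#'   frame of planted sites in draft coordinates: 0-based half-open `start`,
#'   `end`, `base`, `draft_len`, `true_len`), `spec`, and `paths` when `dir`
#'   was given.
#' @export
simulate_plastome_reads <- function(spec = sim_read_spec(), genome = NULL,
                                    dir = NULL) {
  set.seed(spec$seed)
  L <- spec$genome_len
  bases <- c("A", "C", "G", "T")
  if (is.null(genome)) {
    g <- sample(bases, L, replace = TRUE)
  } else {
    g <- strsplit(toupper(genome), "", fixed = TRUE)[[1L]]
    L <- length(g)
  }
  nsite <- length(spec$offsets)
  truth <- data.frame(start = integer(0), end = integer(0),
                      base = character(0), draft_len = integer(0),
                      true_len = integer(0))
  if (nsite) {
    # evenly spaced sites, away from the contig ends and read boundaries
    centers <- round(L * seq_len(nsite) / (nsite + 1L))
    run <- spec$true_run_len
    for (i in seq_len(nsite)) {
      s <- centers[i]  # 1-based start of the run in the true sequence
      b <- sample(bases, 1L)
      g[s:(s + run - 1L)] <- b
      flank <- sample(setdiff(bases, b), 2L, replace = TRUE)
      g[s - 1L] <- flank[1L]; g[s + run] <- flank[2L]
    }
    reference <- paste(g, collapse = "")
    # build the draft right-to-left so earlier site coordinates stay valid
    d <- g
    for (i in rev(seq_len(nsite))) {
      s <- centers[i]; off <- spec$offsets[i]; b <- g[s]
      if (off > 0L) d <- append(d, rep(b, off), after = s - 1L)
      else d <- d[-(s:(s + (-off) - 1L))]
    }
    draft <- paste(d, collapse = "")
    shift <- cumsum(c(0L, spec$offsets))[seq_len(nsite)]
    truth <- data.frame(start = centers - 1L + shift,
                        end = centers - 1L + shift + run + spec$offsets,
                        base = g[centers],
                        draft_len = run + spec$offsets,
                        true_len = run)
  } else {
    reference <- paste(g, collapse = "")
    draft <- reference
  }

  dL <- nchar(draft)
  n_reads <- ceiling(spec$depth * dL / spec$read_len)
  starts <- sample.int(dL - spec$read_len + 1L, n_reads, replace = TRUE) - 1L
  qname <- sprintf("read%05d", seq_len(n_reads))
  cigar <- character(n_reads); seqs <- character(n_reads)
  for (r in seq_len(n_reads)) {
    s0 <- starts[r]; e0 <- s0 + spec$read_len  # draft coords, half-open
    inside <- which(truth$start - 1L >= s0 & truth$end + 1L <= e0)
    if (!length(inside)) {
      seqs[r] <- substr(draft, s0 + 1L, e0)
      cigar[r] <- paste0(spec$read_len, "M")
      next
    }
    segs <- character(0); ops <- character(0)
    cur <- s0
    for (i in inside) {
      pre <- substr(draft, cur + 1L, truth$start[i])
      segs <- c(segs, pre); ops <- c(ops, paste0(nchar(pre), "M"))
      obs <- if (runif(1L) < spec$true_fraction) truth$true_len[i]
             else truth$draft_len[i]
      dl <- truth$draft_len[i]
      segs <- c(segs, strrep(truth$base[i], obs))
      ops <- c(ops,
        if (obs == dl) paste0(dl, "M")
        else if (obs > dl) c(paste0(dl, "M"), paste0(obs - dl, "I"))
        else c(if (obs > 0L) paste0(obs, "M"), paste0(dl - obs, "D")))
      cur <- truth$end[i]
    }
    post <- substr(draft, cur + 1L, e0)
    segs <- c(segs, post); ops <- c(ops, paste0(nchar(post), "M"))
    seqs[r] <- paste(segs, collapse = "")
    # merge adjacent M ops for a clean CIGAR
    lens <- as.integer(sub("[MID]$", "", ops)); kind <- sub("^[0-9]+", "", ops)
    keepop <- lens > 0L
    lens <- lens[keepop]; kind <- kind[keepop]
    m <- length(lens); merged_l <- integer(0); merged_k <- character(0)
    for (k in seq_len(m)) {
      if (k > 1L && kind[k] == tail(merged_k, 1L)) {
        merged_l[length(merged_l)] <- merged_l[length(merged_l)] + lens[k]
      } else { merged_l <- c(merged_l, lens[k]); merged_k <- c(merged_k, kind[k]) }
    }
    cigar[r] <- paste0(merged_l, merged_k, collapse = "")
  }
  sam <- data.frame(qname = qname, flag = 0L, rname = "contig",
                    pos = starts + 1L, cigar = cigar, seq = seqs)
  attr(sam, "skipped") <- 0L
  out <- list(reference = reference, draft = draft, sam = sam, truth = truth,
              spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(seq_records("reference", reference, moltype = "nt"),
                file.path(dir, "reference.fa"))
    write_fasta(seq_records("contig", draft, moltype = "nt"),
                file.path(dir, "draft.fa"))
    write_sam(sam, "contig", dL, file.path(dir, "reads.sam"))
    out$paths <- file.path(dir, c("reference.fa", "draft.fa", "reads.sam"))
  }
  out
}

#' Write alignments as a SAM file
#'
#' @param sam data frame in [read_sam()] layout.
#' @param ref_name,ref_len reference name and length for the `@SQ` header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sam, ref_name, ref_len, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len)), con)
  writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                     sam$qname, sam$flag, sam$rname, sam$pos, sam$cigar,
                     sam$seq, strrep("I", nchar(sam$seq))), con)
  invisible(path)
}
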