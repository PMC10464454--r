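#' Six-frame ORF scan
#'
#' Stop-to-stop open reading frames in all six frames, the way sixpack-style
#' scanners report them: every maximal stretch of non-stop codons of at
#' least `min_aa` residues counts as an ORF (no start codon required).
#' Coordinates are reported on the forward strand, 1-based inclusive.
#'
#' @param seq nucleotide string.
#' @param min_aa minimum ORF length in amino acids (default 10).
#' @param codon_table NCBI genetic code id (default `"11"`).
#' @return data frame with columns `frame` (+1..+3, -1..-3), `start`, `end`
#'   (forward-strand, 1-based inclusive, stop codon excluded) and `peptide`.
#' @export
six_frame_orfs <- function(seq, min_aa = 10L, codon_table = "11") {
  seq <- toupper(seq)
  code <- Biostrings::getGeneticCode(codon_table)
  L <- nchar(seq)
  rc <- revcomp(seq)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) seq else rc
    for (off in 0:2) {
      n <- (L - off) %/% 3L
      if (n == 0L) next
      codons <- substring(s, off + 3L * seq_len(n) - 2L, off + 3L * seq_len(n))
      aa <- unname(code[codons]); aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      r <- rle(is_stop)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (b in which(!r$values & r$lengths >= min_aa)) {
        c1 <- starts[b]; c2 <- ends[b]          # codon indices on strand s
        p1 <- off + 3L * (c1 - 1L) + 1L         # 1-based nt on strand s
        p2 <- off + 3L * c2
        if (strand == 1L) { f1 <- p1; f2 <- p2 }
        else { f1 <- L - p2 + 1L; f2 <- L - p1 + 1L }
        out[[length(out) + 1L]] <- data.frame(
          frame = strand * (off + 1L), start = f1, end = f2,
          peptide = paste(aa[c1:c2], collapse = ""))
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), peptide = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$frame), , drop = FALSE]
}

#' Find homopolymer runs in a region
#'
#' All maximal runs of one base with length >= `min_run` inside
#' `[start, end)` of the contig (0-based half-open; defaults to the whole
#' contig). Runs clipped by the region boundary are truncated there and
#' marked non-maximal.
#'
#' @param contig nucleotide string.
#' @param min_run minimum run length (>= 2, default 3).
#' @param start,end 0-based half-open region bounds.
#' @param name contig name used in reports.
#' @return list of `hp_candidate` objects with fields `contig`, `start`,
#'   `end` (0-based half-open), `base`, `run_len`, `maximal`, plus empty
#'   `support` and `coverage = 0`.
#' @export
find_homopolymer_candidates <- function(contig, min_run = 3L, start = 0L,
                                        end = nchar(contig),
                                        name = "contig") {
  if (min_run < 2L) stop("min_run must be >= 2")
  if (start < 0L || end > nchar(contig) || end <= start)
    stop("region out of contig bounds")
  region <- substr(contig, start + 1L, end)
  ch <- strsplit(toupper(region), "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_run & r$values %in% c("A", "C", "G", "T")
  lapply(which(keep), function(b) {
    s0 <- start + starts[b] - 1L; e0 <- start + ends[b]
    maximal <- (s0 == 0L || substr(contig, s0, s0) != r$values[b]) &&
               (e0 == nchar(contig) || substr(contig, e0 + 1L, e0 + 1L) != r$values[b])
    structure(list(contig = name, start = s0, end = e0, base = r$values[b],
                   run_len = r$lengths[b], maximal = maximal,
                   support = integer(0), coverage = 0L),
              class = "hp_candidate")
  })
}

# ---- SAM --------------------------------------------------------------------

#' Read primary alignments from a SAM file
#'
#' Minimal reader over the field subset the polisher needs: QNAME, FLAG,
#' RNAME, POS, CIGAR, SEQ. Unmapped (0x4), secondary (0x100) and
#' supplementary (0x800) records are dropped and tallied.
#'
#' @param path SAM file path.
#' @return data frame `qname`, `flag`, `rname`, `pos` (1-based), `cigar`,
#'   `seq`, with attribute `skipped` (records dropped by FLAG).
#' @export
read_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^@", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, 0L) < 10L
  if (any(bad)) stop("SAM format error: record with fewer than 10 fields")
  flag <- vapply(f, function(x) as.integer(x[2L]), 0L)
  drop <- bitwAnd(flag, 0x904L) != 0L
  out <- data.frame(qname = vapply(f, `[`, "", 1L)[!drop],
                    flag = flag[!drop],
                    rname = vapply(f, `[`, "", 3L)[!drop],
                    pos = vapply(f, function(x) as.integer(x[4L]), 0L)[!drop],
                    cigar = vapply(f, `[`, "", 6L)[!drop],
                    seq = vapply(f, `[`, "", 10L)[!drop])
  attr(out, "skipped") <- sum(drop)
  out
}

parse_cigar <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", ops)),
       op = sub("^[0-9]+", "", ops))
}

# reference span [start, end) (0-based) consumed by an alignment
cigar_ref_span <- function(pos, cig) {
  consumed <- sum(cig$len[cig$op %in% c("M", "D", "N", "=", "X")])
  c(pos - 1L, pos - 1L + consumed)
}

# observed homopolymer run length for one alignment over ref run [s, e):
# counts read bases equal to `base` aligned within the run plus inserted
# bases of `base` at insertion points s..e. Returns NA unless the read
# covers both anchor positions (s-1 and e) with an aligned (M/=/X) base.
observed_run_length <- function(pos, cig, read_seq, s, e, base) {
  ref <- pos - 1L   # current ref position (0-based)
  qry <- 0L         # read bases consumed
  anchored_left <- FALSE; anchored_right <- FALSE
  count <- 0L
  for (k in seq_along(cig$op)) {
    op <- cig$op[k]; n <- cig$len[k]
    if (op %in% c("M", "=", "X")) {
      if (s - 1L >= ref && s - 1L < ref + n) anchored_left <- TRUE
      if (e >= ref && e < ref + n) anchored_right <- TRUE
      lo <- max(ref, s); hi <- min(ref + n, e)
      if (hi > lo) {
        seg <- substr(read_seq, qry + (lo - ref) + 1L, qry + (hi - ref))
        count <- count + nchar(seg) - nchar(gsub(base, "", seg, fixed = TRUE))
      }
      ref <- ref + n; qry <- qry + n
    } else if (op == "I") {
      if (ref >= s && ref <= e) {
        seg <- substr(read_seq, qry + 1L, qry + n)
        count <- count + nchar(seg) - nchar(gsub(base, "", seg, fixed = TRUE))
      }
      qry <- qry + n
    } else if (op %in% c("D", "N")) {
      ref <- ref + n
    } else if (op == "S") {
      qry <- qry + n
    }
    # H and P consume nothing we track
  }
  if (anchored_left && anchored_right) count else NA_integer_
}

#' Count read support for homopolymer run lengths
#'
#' For every primary alignment spanning the candidate run plus one aligned
#' anchor base on each side, the run length observed in the read (matched
#' bases of the run's nucleotide inside the run, plus inserted copies at its
#' edges) increments `support[length]`. `coverage` is the number of spanning
#' reads; reads that end inside the run or are clipped through it are
#' skipped and tallied.
#'
#' @param candidate an `hp_candidate` from [find_homopolymer_candidates()].
#' @param alignments a [read_sam()] data frame, a SAM file path, or a
#'   prebuilt [index_alignments()] object (cheapest when scoring many
#'   candidates against the same mapping).
#' @return the candidate with `support` (named integer vector, names are run
#'   lengths), `coverage`, and attribute `not_spanning` (reads overlapping
#'   the run that do not span it with anchors).
#' @export
count_run_support <- function(candidate, alignments) {
  idx <- index_alignments(alignments)
  hit <- which(idx$aln$rname == candidate$contig &
               idx$start <= candidate$start - 1L &
               idx$end >= candidate$end + 1L)
  overlapping <- sum(idx$aln$rname == candidate$contig &
                     idx$start < candidate$end & idx$end > candidate$start)
  support <- integer(0); coverage <- 0L
  for (i in hit) {
    obs <- observed_run_length(idx$aln$pos[i], idx$cigars[[i]],
                               idx$aln$seq[i], candidate$start,
                               candidate$end, candidate$base)
    if (is.na(obs)) next
    key <- as.character(obs)
    support[key] <- (if (key %in% names(support)) support[[key]] else 0L) + 1L
    coverage <- coverage + 1L
  }
  candidate$support <- support
  candidate$coverage <- coverage
  attr(candidate, "not_spanning") <- overlapping - coverage
  candidate
}

#' Index a read mapping for repeated support counting
#'
#' Parses every CIGAR once and precomputes reference spans so that
#' [count_run_support()] over many candidates only walks the few reads
#' overlapping each run.
#'
#' @param alignments a [read_sam()] data frame or SAM path; an existing
#'   index is passed through.
#' @return object of class `sam_index`.
#' @export
index_alignments <- function(alignments) {
  if (inherits(alignments, "sam_index")) return(alignments)
  if (is.character(alignments)) alignments <- read_sam(alignments)
  cigars <- lapply(alignments$cigar, parse_cigar)
  spans <- mapply(function(p, cg) cigar_ref_span(p, cg), alignments$pos,
                  cigars)
  structure(list(aln = alignments, cigars = cigars,
                 start = spans[1L, ], end = spans[2L, ]),
            class = "sam_index")
}

#' Decide whether to correct a homopolymer run
#'
#' The alternative run length `L*` with the most read support (ties: closest
#' to the assembly run length, then the smaller length) is adopted only if
#' it is supported by at least `min_reads` reads AND by more than
#' `min_fraction` of the spanning reads — the "more than a quarter and a
#' minimum of ten reads" rule. Support exactly at `min_fraction` does not
#' qualify.
#'
#' @param candidate an `hp_candidate` with support filled.
#' @param min_reads minimum supporting reads (default 10).
#' @param min_fraction strict lower bound on the supporting fraction of
#'   spanning reads (default 0.25).
#' @return object of class `correction_decision`: `candidate`, `action`
#'   (`"insert"`, `"delete"` or `"none"`), `n` (bases), `chosen_len`,
#'   `support_count`, `support_fraction`, `reason`.
#' @export
decide_correction <- function(candidate, min_reads = 10L,
                              min_fraction = 0.25) {
  dec <- function(action, n = 0L, len = NA_integer_, cnt = 0L, frac = NA_real_,
                  reason = "") {
    structure(list(candidate = candidate, action = action, n = n,
                   chosen_len = len, support_count = cnt,
                   support_fraction = frac, reason = reason),
              class = "correction_decision")
  }
  if (candidate$coverage == 0L) return(dec("none", reason = "no coverage"))
  lens <- as.integer(names(candidate$support))
  alt <- lens != candidate$run_len
  if (!any(alt)) return(dec("none", reason = "no alternative length observed"))
  lens <- lens[alt]; cnt <- candidate$support[alt]
  ord <- order(-cnt, abs(lens - candidate$run_len), lens)
  Lstar <- lens[ord[1L]]; n_sup <- cnt[[ord[1L]]]
  frac <- n_sup / candidate$coverage
  if (n_sup < min_reads)
    return(dec("none", len = Lstar, cnt = n_sup, frac = frac,
               reason = sprintf("support %d below minimum of %d reads",
                                n_sup, min_reads)))
  if (frac <= min_fraction)
    return(dec("none", len = Lstar, cnt = n_sup, frac = frac,
               reason = sprintf("fraction %.3f not more than %.2f",
                                frac, min_fraction)))
  d <- Lstar - candidate$run_len
  dec(if (d > 0L) "insert" else "delete", n = abs(d), len = Lstar,
      cnt = n_sup, frac = frac, reason = "supported")
}

#' Apply correction decisions to a contig
#'
#' Insertions and deletions are applied right-to-left so earlier coordinates
#' stay valid. Decisions must not overlap. A shift table maps old 1-based
#' positions to their new coordinates past each edit.
#'
#' @param contig nucleotide string.
#' @param decisions list of `correction_decision` objects (actions of
#'   `"none"` are ignored).
#' @return list with `seq` (corrected contig), `shifts` (data frame
#'   `old_pos`, `shift`: positions > `old_pos` move by the cumulative
#'   `shift`), and `summary` (e.g. `"2 of 4 candidates corrected"`).
#' @export
apply_corrections <- function(contig, decisions) {
  act <- Filter(function(d) d$action != "none", decisions)
  total <- length(decisions)
  if (!length(act))
    return(list(seq = contig, shifts = data.frame(old_pos = integer(0),
                                                  shift = integer(0)),
                summary = sprintf("0 of %d candidates corrected", total)))
  starts <- vapply(act, function(d) d$candidate$start, 0L)
  ends <- vapply(act, function(d) d$candidate$end, 0L)
  ord <- order(starts)
  if (any(starts[ord][-1L] < ends[ord][-length(ord)]))
    stop("overlapping correction decisions")
  shifts <- data.frame(old_pos = integer(0), shift = integer(0))
  for (i in rev(ord)) {
    d <- act[[i]]
    e <- d$candidate$end  # 0-based end of the run; edit applied at run end
    if (d$action == "insert") {
      contig <- paste0(substr(contig, 1L, e),
                       strrep(d$candidate$base, d$n),
                       substr(contig, e + 1L, nchar(contig)))
      shifts <- rbind(data.frame(old_pos = e, shift = d$n), shifts)
    } else {
      contig <- paste0(substr(contig, 1L, e - d$n),
                       substr(contig, e + 1L, nchar(contig)))
      shifts <- rbind(data.frame(old_pos = e, shift = -d$n), shifts)
    }
  }
  shifts$shift <- cumsum(shifts$shift)
  list(seq = contig, shifts = shifts,
       summary = sprintf("%d of %d candidates corrected",
                         length(act), total))
}

#' Polish a draft contig from mapped reads
#'
#' End-to-end wrapper: scan the contig (or supplied candidate regions) for
#' homopolymer runs, count spanning-read support from a SAM file, decide
#' corrections under the read-support rule and apply them.
#'
#' @param contig draft nucleotide string.
#' @param sam a SAM path or [read_sam()] data frame.
#' @param min_run minimum homopolymer length scanned (default 3).
#' @param min_reads,min_fraction see [decide_correction()].
#' @param candidates optional precomputed candidate list (e.g. restricted to
#'   CDS regions flagged by [extract_peptides()]).
#' @param name contig name matching the SAM RNAME.
#' @return list with `seq`, `decisions`, `shifts`, `summary` and a `report`
#'   data frame (1-based positions) of every candidate considered.
#' @export
polish_assembly <- function(contig, sam, min_run = 3L, min_reads = 10L,
                            min_fraction = 0.25, candidates = NULL,
                            name = "contig") {
  idx <- index_alignments(sam)
  if (is.null(candidates))
    candidates <- find_homopolymer_candidates(contig, min_run, name = name)
  decisions <- lapply(candidates, function(cand)
    decide_correction(count_run_support(cand, idx), min_reads, min_fraction))
  res <- apply_corrections(contig, decisions)
  report <- do.call(rbind, lapply(decisions, function(d) data.frame(
    contig = d$candidate$contig, pos = d$candidate$start + 1L,
    base = d$candidate$base, run_len = d$candidate$run_len,
    coverage = d$candidate$coverage, action = d$action, n = d$n,
    chosen_len = d$chosen_len, support = d$support_count,
    fraction = d$support_fraction, reason = d$reason)))
  c(res["seq"], list(decisions = decisions), res[c("shifts", "summary")],
    list(report = report))
}
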