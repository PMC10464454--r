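#' Sequence record tables
#'
#' Sequence sets are held as plain data frames with columns `id`, `species`,
#' `seq` and `moltype` (`"nt"` or `"aa"`). `seq_records()` validates and
#' normalises such a table: ids must be non-empty and unique, sequences are
#' upper-cased, and nucleotide sequences may only contain IUPAC codes.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param seq character vector of residue strings.
#' @param species optional species tag per record (`NA` when unknown).
#' @param moltype `"nt"` or `"aa"`.
#' @return a `data.frame` with columns `id`, `species`, `seq`, `moltype`.
#' @export
seq_records <- function(id, seq, species = NA_character_, moltype = "aa") {
  stopifnot(length(id) == length(seq))
  moltype <- match.arg(moltype, c("aa", "nt"))
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (any(!nzchar(id))) stop("sequence record ids must be non-empty")
  if (anyDuplicated(id)) stop("duplicate sequence ids: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (moltype == "nt" && length(seq)) {
    bad <- grepl("[^ACGTUMRWSYKVHDBN-]", seq)
    if (any(bad)) stop("non-IUPAC characters in nucleotide sequence(s): ",
                       paste(head(id[bad], 3L), collapse = ", "))
  }
  data.frame(id = id, species = rep_len(as.character(species), length(id)),
             seq = seq, moltype = rep_len(moltype, length(id)))
}

#' Read and write FASTA files
#'
#' A deliberately small line-based FASTA reader so that malformed input can be
#' reported with the offending line number (zero-length records and
#' sequence data before the first header are format errors). The species tag
#' is parsed from each header with `species_regex`, whose first capture group
#' is the tag; headers that do not match get `NA`. The default matches the
#' `species@gene` convention used throughout the pipeline.
#'
#' @param path file path.
#' @param moltype `"aa"` (default) or `"nt"`.
#' @param species_regex regex with one capture group extracting the species
#'   tag from the header line (without the leading `>`).
#' @return `read_fasta`: a record data frame (see [seq_records()]).
#' @export
read_fasta <- function(path, moltype = "aa", species_regex = "^([^@]+)@") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1L] && any(nzchar(trimws(lines))))
    stop("FASTA format error at line 1: sequence data before first header")
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_seq <- character(0); cur_line <- 0L
  flush <- function() {
    if (is.null(cur_id)) return()
    s <- paste(cur_seq, collapse = "")
    if (!nzchar(s))
      stop("FASTA format error at line ", cur_line,
           ": zero-length sequence for record '", cur_id, "'")
    ids <<- c(ids, cur_id); seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^>", ln)) {
      flush()
      cur_id <- trimws(sub("^>", "", ln))
      if (!nzchar(cur_id))
        stop("FASTA format error at line ", i, ": empty header")
      cur_seq <- character(0); cur_line <- i
    } else {
      cur_seq <- c(cur_seq, gsub("\\s", "", ln))
    }
  }
  flush()
  species <- ifelse(grepl(species_regex, ids),
                    sub(paste0(species_regex, ".*$"), "\\1", ids),
                    NA_character_)
  seq_records(ids, seqs, species, moltype)
}

#' @param records a record data frame.
#' @param width line-wrap width for sequence lines.
#' @rdname read_fasta
#' @return `write_fasta`: `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string (IUPAC codes allowed).
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC content of a nucleotide sequence
#'
#' 100 * (G + C) / (A + C + G + T). Ambiguity codes and gaps are excluded
#' from both numerator and denominator. `at_content()` is the complement.
#'
#' @param seq non-empty nucleotide string.
#' @return percentage in \[0, 100\].
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("gc_content is undefined for an empty sequence")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- sum(ch %in% c("A", "C", "G", "T"))
  if (n == 0L) stop("gc_content is undefined: no unambiguous A/C/G/T bases")
  100 * sum(ch %in% c("G", "C")) / n
}

#' @rdname gc_content
#' @export
at_content <- function(seq) {
  if (!nzchar(seq)) stop("at_content is undefined for an empty sequence")
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- sum(ch %in% c("A", "C", "G", "T"))
  if (n == 0L) stop("at_content is undefined: no unambiguous A/C/G/T bases")
  100 * sum(ch %in% c("A", "T")) / n
}

# ---- annotation records -----------------------------------------------------

#' Annotated plastome record
#'
#' Container for a genome sequence plus its CDS features. Feature intervals
#' are stored 0-based half-open and validated against the sequence bounds;
#' within one feature the intervals must not overlap and all share a strand.
#'
#' @param seq genome nucleotide string.
#' @param features list of features; each is a list with elements `gene`
#'   (name), `intervals` (data frame with 0-based half-open `start`, `end`),
#'   `strand` (`"+"` or `"-"`) and optional `codon_table` (default `"11"`).
#' @return an object of class `annotation_record`.
#' @export
annotation_record <- function(seq, features) {
  seq <- toupper(seq)
  L <- nchar(seq)
  for (f in features) {
    stopifnot(is.character(f$gene), nrow(f$intervals) >= 1L)
    if (!f$strand %in% c("+", "-"))
      stop("feature '", f$gene, "': strand must be '+' or '-'")
    iv <- f$intervals[order(f$intervals$start), , drop = FALSE]
    if (any(iv$start < 0L) || any(iv$end > L) || any(iv$end <= iv$start))
      stop("feature '", f$gene, "': interval out of bounds")
    if (nrow(iv) > 1L && any(iv$start[-1L] < iv$end[-nrow(iv)]))
      stop("feature '", f$gene, "': overlapping intervals")
  }
  structure(list(seq = seq, features = features), class = "annotation_record")
}

#' Translate a coding sequence
#'
#' Codon-by-codon translation under an NCBI genetic code (default table 11,
#' the plastid/bacterial code). Translation stops at the first stop codon;
#' the stop itself is not part of the peptide. Codons containing ambiguity
#' codes translate to `X`.
#'
#' @param cds in-frame coding nucleotide string.
#' @param codon_table NCBI genetic code id as a string (default `"11"`).
#' @return list with `peptide` (string) and `internal_stop` (TRUE when a stop
#'   codon occurred before the final codon).
#' @export
translate_cds <- function(cds, codon_table = "11") {
  code <- Biostrings::getGeneticCode(codon_table)
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(list(peptide = "", internal_stop = FALSE))
  codons <- substring(toupper(cds), 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  internal_stop <- length(stop_at) > 0L && stop_at[1L] < n
  pep <- if (length(stop_at)) aa[seq_len(stop_at[1L] - 1L)] else aa
  list(peptide = paste(pep, collapse = ""), internal_stop = internal_stop)
}

#' Extract peptides from an annotated plastome
#'
#' One peptide per CDS feature: intervals are joined in ascending order,
#' minus-strand features are reverse-complemented after joining (the GenBank
#' `complement(join(...))` convention), and the joined CDS is translated
#' with [translate_cds()]. Features whose joined length is not a multiple of
#' three are skipped with a warning; features with an internal stop codon are
#' translated up to the stop and flagged as frameshift candidates for the
#' polishing module.
#'
#' @param record an [annotation_record()].
#' @param species optional species tag; when given, peptide ids are
#'   `species@gene`, otherwise the gene name.
#' @return record data frame of peptides with attributes `skipped` (gene
#'   names whose CDS length was not divisible by 3) and
#'   `frameshift_candidates` (gene names with an internal stop).
#' @export
extract_peptides <- function(record, species = NULL) {
  stopifnot(inherits(record, "annotation_record"))
  ids <- character(0); peps <- character(0)
  skipped <- character(0); flagged <- character(0)
  seen <- character(0)
  for (f in record$features) {
    iv <- f$intervals[order(f$intervals$start), , drop = FALSE]
    parts <- substring(record$seq, iv$start + 1L, iv$end)
    cds <- paste(parts, collapse = "")
    if (f$strand == "-") cds <- revcomp(cds)
    if (nchar(cds) %% 3L != 0L) {
      warning("CDS '", f$gene, "' length ", nchar(cds),
              " not divisible by 3; feature skipped")
      skipped <- c(skipped, f$gene)
      next
    }
    tr <- translate_cds(cds, f$codon_table %||% "11")
    if (tr$internal_stop) flagged <- c(flagged, f$gene)
    id <- if (is.null(species)) f$gene else paste0(species, "@", f$gene)
    # duplicate gene names (e.g. genes in both inverted repeats) get a suffix
    if (id %in% seen) id <- paste0(id, ".", sum(seen == id) + 1L)
    seen <- c(seen, if (is.null(species)) f$gene else paste0(species, "@", f$gene))
    ids <- c(ids, id); peps <- c(peps, tr$peptide)
  }
  out <- seq_records(ids, peps, species %||% NA_character_, "aa")
  attr(out, "skipped") <- skipped
  attr(out, "frameshift_candidates") <- flagged
  out
}

#' Read a GBSON-style JSON annotation
#'
#' Accepts a minimal JSON dialect: an object with `sequence` (or `seq`) and
#' `features`, each feature an object with `gene`, `type`,
#' `location` (array of `{start, end, strand}` with 1-based inclusive
#' coordinates, strand `"+"`/`"-"` or 1/-1) and optionally `transl_table`.
#' Unknown keys are ignored; only features with `type == "CDS"` are kept.
#'
#' @param path JSON file path.
#' @return an [annotation_record()].
#' @export
read_gbson <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  seq <- j$sequence %||% j$seq
  if (is.null(seq)) stop("GBSON file lacks a 'sequence' field")
  feats <- list()
  for (f in j$features %||% list()) {
    if (!identical(f$type, "CDS")) next
    loc <- do.call(rbind, lapply(f$location, function(l) {
      strand <- l$strand
      if (is.numeric(strand)) strand <- if (strand < 0) "-" else "+"
      data.frame(start = as.integer(l$start) - 1L, end = as.integer(l$end),
                 strand = strand)
    }))
    feats[[length(feats) + 1L]] <- list(
      gene = f$gene %||% paste0("cds", length(feats) + 1L),
      intervals = loc[, c("start", "end")],
      strand = loc$strand[1L],
      codon_table = as.character(f$transl_table %||% "11"))
  }
  annotation_record(seq, feats)
}

#' Read CDS features from a GenBank flat file
#'
#' Minimal reader for the subset the pipeline needs: the `ORIGIN` sequence
#' block and `CDS` features with `join()`/`complement()` locations plus
#' `/gene` and `/transl_table` qualifiers. Everything else is ignored.
#'
#' @param path GenBank flat-file path.
#' @return an [annotation_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  o <- which(grepl("^ORIGIN", lines))
  if (!length(o)) stop("GenBank file has no ORIGIN block")
  seq_lines <- lines[(o[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  fstart <- which(grepl("^FEATURES", lines))
  if (!length(fstart)) return(annotation_record(seq, list()))
  flines <- lines[(fstart[1L] + 1L):(o[1L] - 1L)]
  # fold continuation lines (21 leading spaces, not starting a qualifier
  # or a new key) into the feature location
  feats <- list(); i <- 1L
  while (i <= length(flines)) {
    m <- regmatches(flines[i], regexec("^     (\\S+)\\s+(\\S.*)$", flines[i]))[[1L]]
    if (length(m) && m[2L] == "CDS") {
      loc <- m[3L]; j <- i + 1L
      while (j <= length(flines) && grepl("^\\s{10,}[^/]", flines[j])) {
        loc <- paste0(loc, trimws(flines[j])); j <- j + 1L
      }
      gene <- NA_character_; table <- "11"
      while (j <= length(flines) && !grepl("^     \\S", flines[j])) {
        q <- trimws(flines[j])
        if (grepl("^/gene=", q)) gene <- gsub('^/gene="?|"$', "", q)
        if (grepl("^/transl_table=", q)) table <- sub("^/transl_table=", "", q)
        j <- j + 1L
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      pieces <- regmatches(loc, gregexpr("[0-9]+\\.\\.[0-9]+", loc))[[1L]]
      if (length(pieces)) {
        iv <- do.call(rbind, lapply(strsplit(pieces, "\\.\\."), function(p)
          data.frame(start = as.integer(p[1L]) - 1L, end = as.integer(p[2L]))))
        feats[[length(feats) + 1L]] <- list(
          gene = if (is.na(gene)) paste0("cds", length(feats) + 1L) else gene,
          intervals = iv, strand = strand, codon_table = table)
      }
      i <- j
    } else i <- i + 1L
  }
  annotation_record(seq, feats)
}

# ---- FASTQ ------------------------------------------------------------------

#' Read a 4-line FASTQ file
#'
#' @param path FASTQ file path.
#' @return data frame with columns `id` (without the leading `@`, first
#'   whitespace-delimited token), `desc` (full header line), `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ format error: truncated record near line ",
         4L * (length(lines) %/% 4L) + 1L)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), desc = character(0),
                      seq = character(0), qual = character(0)))
  h <- lines[4L * seq_len(n) - 3L]
  s <- lines[4L * seq_len(n) - 2L]
  p <- lines[4L * seq_len(n) - 1L]
  q <- lines[4L * seq_len(n)]
  bad <- which(!grepl("^@", h) | !grepl("^\\+", p))[1L]
  if (!is.na(bad))
    stop("FASTQ format error at line ", 4L * bad - 3L,
         ": expected '@' header / '+' separator")
  bad_len <- which(nchar(s) != nchar(q))[1L]
  if (!is.na(bad_len))
    stop("FASTQ format error at line ", 4L * bad_len - 2L,
         ": sequence and quality lengths differ")
  data.frame(id = sub("\\s.*$", "", sub("^@", "", h)),
             desc = sub("^@", "", h), seq = s, qual = q)
}

#' Subset a FASTQ file by read id
#'
#' Writes exactly the reads whose ids appear in `ids`, in input-file order,
#' each read once even when `ids` contains duplicates. Sequence and quality
#' lines are passed through byte-identically. Ids with no matching read are
#' non-fatal and reported.
#'
#' @param reads_path input FASTQ.
#' @param ids non-empty character vector of read ids.
#' @param out_path output FASTQ path.
#' @return invisibly, a list with `written` (reads emitted) and `missing`
#'   (ids not found). A warning summarises misses.
#' @export
subset_fastq <- function(reads_path, ids, out_path) {
  if (!length(ids)) stop("id list must be non-empty")
  ids <- unique(ids)
  fq <- read_fastq(reads_path)
  keep <- fq$id %in% ids
  con <- file(out_path, "w"); on.exit(close(con))
  for (i in which(keep))
    writeLines(c(paste0("@", fq$desc[i]), fq$seq[i], "+", fq$qual[i]), con)
  missing <- setdiff(ids, fq$id)
  if (length(missing))
    warning(length(missing), " id(s) not found in ", reads_path)
  invisible(list(written = sum(keep), missing = missing))
}

#' FASTQ summary statistics
#'
#' @param path FASTQ file path.
#' @return object of class `fastq_stats` with fields `read_count`,
#'   `total_bases` and `mean_length` (`NA` for an empty file; use
#'   [mean_length()] to access it with an error on empty input).
#' @export
fastq_stats <- function(path) {
  fq <- read_fastq(path)
  lens <- nchar(fq$seq)
  structure(list(read_count = nrow(fq), total_bases = sum(lens),
                 mean_length = if (nrow(fq)) mean(lens) else NA_real_),
            class = "fastq_stats")
}

#' @param x a `fastq_stats` object.
#' @rdname fastq_stats
#' @export
mean_length <- function(x) {
  stopifnot(inherits(x, "fastq_stats"))
  if (x$read_count == 0L) stop("mean length is undefined for an empty file")
  x$mean_length
}

#' @param other a second `fastq_stats` object (the reference total).
#' @rdname fastq_stats
#' @return `fraction_of`: `x$total_bases / other$total_bases`.
#' @export
fraction_of <- function(x, other) {
  stopifnot(inherits(x, "fastq_stats"), inherits(other, "fastq_stats"))
  if (other$total_bases == 0) stop("reference stats have zero bases")
  x$total_bases / other$total_bases
}

#' @export
print.fastq_stats <- function(x, ...) {
  cat(sprintf("FASTQ stats: %d reads, %d bases, mean length %s bp\n",
              x$read_count, x$total_bases,
              if (is.na(x$mean_length)) "NA" else format(x$mean_length)))
  invisible(x)
}
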