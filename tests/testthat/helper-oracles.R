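# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately re-derive results from first principles and never call
# the code paths they check.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT <- c("A", "C", "G", "T")

# --- translation oracle: hand-written codon table (NCBI table 11 translates
# identically to the standard code; it differs only in start codons) ---------
codon_table_oracle <- local({
  aa1 <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
  g <- expand.grid(b3 = c("T", "C", "A", "G"), b2 = c("T", "C", "A", "G"),
                   b1 = c("T", "C", "A", "G"), stringsAsFactors = FALSE)
  setNames(strsplit(aa1, "")[[1]], paste0(g$b1, g$b2, g$b3))
})

translate_oracle <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds) %/% 3
  out <- character(0)
  for (i in seq_len(n)) {
    aa <- codon_table_oracle[[substr(cds, 3 * i - 2, 3 * i)]]
    if (aa == "*") break
    out <- c(out, aa)
  }
  paste(out, collapse = "")
}

revcomp_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# --- quartile / fence oracle: explicit interpolation between order stats ----
quartile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

fence_flag_oracle <- function(lengths, k = 1.5) {
  q1 <- quartile_oracle(unname(lengths), 0.25)
  q3 <- quartile_oracle(unname(lengths), 0.75)
  names(lengths)[lengths > q3 + k * (q3 - q1)]
}

# random tree whose pendant edge lengths are exactly `pend` (named by tip)
tree_with_pendants <- function(pend) {
  k <- length(pend)
  tr <- ape::rtree(k, tip.label = names(pend))
  # rtree permutes the labels, so assign each pendant length by label
  tip_edge <- match(match(names(pend), tr$tip.label), tr$edge[, 2])
  tr$edge.length[tip_edge] <- unname(pend)
  tr
}

# --- fixture: 10 orthogroups, 3 outgroup taxa, 1 linked violation,
#     1 outgroup-only group, paralogs in the rest -----------------------------
fixture_ten_ogs <- function() {
  species <- c("Csub", "Cdem", "SpA", "SpB", "SpC", "O1", "O2", "O3")
  mk <- function(og, sp, extra = character(0)) {
    ids <- paste0(sp, "@", og)
    seqs <- vapply(seq_along(sp), function(i)
      paste(rep(AA[(i %% 20) + 1], 20), collapse = ""), "")
    if (length(extra)) {
      ids <- c(ids, paste0(extra, "@", og, ".p2"))
      seqs <- c(seqs, vapply(extra, function(e)
        paste(rep("A", 15), collapse = ""), ""))
      sp <- c(sp, extra)
    }
    orthogroup(og, seq_records(ids, seqs, sp))
  }
  ogs <- list(
    mk("OG01", species), mk("OG02", species, extra = "SpA"),
    mk("OG03", species), mk("OG04", species, extra = c("Csub", "SpB")),
    mk("OG05", species), mk("OG06", species),
    mk("OG07", species), mk("OG08", species),
    mk("OG09", c("Csub", "SpA", "SpB", "O1")),        # linked violation
    mk("OG10", c("O1", "O2")))                        # outgroup-only
  ogs
}

fixture_cfg <- function() {
  run_config(species_of_interest = "Csub",
             linked_groups = list(c("Csub", "Cdem")),
             outgroup = c("O1", "O2", "O3"))
}

# --- misc helpers ------------------------------------------------------------
random_records <- function(n, seed = 1, moltype = "aa") {
  set.seed(seed)
  alpha <- if (moltype == "aa") AA else NT
  seq_records(sprintf("sp%02d@g%03d", seq_len(n), sample(999, n)),
              vapply(seq_len(n), function(i)
                paste(sample(alpha, sample(10:60, 1), replace = TRUE),
                      collapse = ""), ""),
              sprintf("sp%02d", seq_len(n)), moltype)
}

write_tmp_fastq <- function(seqs, ids = sprintf("r%d", seq_along(seqs))) {
  path <- withr::local_tempfile(fileext = ".fastq",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                             vapply(nchar(seqs), strrep, "", x = "I"))), path)
  path
}

# hp candidate with a given support histogram, bypassing SAM machinery
mk_candidate <- function(run_len, support, coverage,
                         base = "A", start = 100L) {
  structure(list(contig = "contig", start = start,
                 end = start + run_len, base = base,
                 run_len = as.integer(run_len), maximal = TRUE,
                 support = support, coverage = as.integer(coverage)),
            class = "hp_candidate")
}
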