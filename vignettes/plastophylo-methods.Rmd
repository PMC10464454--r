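---
title: "plastophylo: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastophylo: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastophylo)
```

# Scope and model

plastophylo covers the desk-side half of a plastome phylogenomics study:
peptide extraction from annotated plastomes, cleaning of orthogroups
produced by any orthology tool, supermatrix construction with a built-in
distance tree, read-support-gated homopolymer polishing of a long-read
draft, sequencing-throughput planning, and a synthetic-data generator that
makes all of it testable without downloads. It deliberately does not
re-implement orthology inference, ML tree search, basecalling or assembly;
those remain external tools for which plastophylo prepares inputs and
command lines.

# Coordinates and conventions

All in-memory coordinates are 0-based half-open; every user-facing report,
file format and printed position is 1-based inclusive. Translation defaults
to NCBI genetic code 11 (the plastid/bacterial code — standard for plastome
CDSs; the code id is overridable per feature). Peptide ids follow the
`species@gene` convention and the species tag is recovered from headers by
a configurable regex.

# Orthogroup cleaning

**Pre-orthology trimming** removes, in order: within-species byte-identical
duplicates (one representative survives — the lexicographically smallest id;
deleting *all* copies would discard genuine single-copy genes duplicated
only by annotation artefacts), sequences containing `*` (stop codons inside
flawed conceptual translations), and peptides shorter than
`min_peptide_len` (default 10 aa, adjustable).

**Branch-length outliers.** "Edge length per taxon" is read as the terminal
(pendant) branch length of each leaf — the only per-taxon edge that is
unambiguous in a gene tree. Quartiles are computed by linear interpolation
between order statistics (R's default, type 7), and leaves above
`Q3 + k·IQR` with `k = 1.5` are flagged. The fence is one-sided by default:
long branches indicate misassignment, contamination or annotation error,
while short branches are never suspect; a `two_sided` option exists for the
symmetric variant. Outgroup taxa are excluded from both the statistics and
the flagging, since a distant outgroup would otherwise dominate the spread.
With fewer than four usable leaves quartiles are too unstable to act on, so
flagging is skipped and reported as such.

**Presence filters.** Linked species sets are all-or-none: an orthogroup
containing part of a linked set mixes orthologs with missing counterparts
and is discarded. Orthogroups with fewer species than there are outgroup
taxa are discarded, except outgroup-only groups, which are exempt (they are
kept as stated even though they carry no ingroup signal). **Paralog
pruning** keeps the longest member per species, ties broken by the smallest
id so runs are reproducible.

The four steps run in this order; a member that is both an outlier and a
paralog is removed at step 1 and the report attributes it there. Reports
reconcile exactly: members in = outliers removed + paralogs removed +
members out for every surviving group.

# Supermatrix and trees

The built-in aligner is center-star progressive alignment: all pairwise
global alignments under BLOSUM62 with affine gaps (open 10, extend 1, the
classic protein defaults), the member with the highest summed score becomes
the center, and other members are merged with the "once a gap, always a
gap" rule. It is deterministic, adequate for the short, highly similar
plastome peptides the pipeline sees, and makes no claim to match a modern
MSA tool; any external aligner can be supplied as a `{in}`/`{out}` command
template and is never a hard dependency.

Concatenation gap-fills species missing from an orthogroup (the standard
supermatrix convention) and records half-open partition ranges that tile
the matrix; export converts them to 1-based inclusive NEXUS charsets. Taxon
order is config order first, then lexicographic.

The built-in tree is neighbor joining on p-distances with pairwise gap
deletion — a deliberate desk-scale stand-in for an external ML analysis,
for which the exporter writes relaxed PHYLIP, the partition file, and an
IQ-TREE command with `-nt AUTO -bb 1000` and fixed seed 291752 so the
external run is reproducible. Negative NJ edge estimates are clamped to
zero. A pair of rows sharing no ungapped column has no defined distance and
is an error rather than a guess. Bootstrap resamples columns with
replacement; support of an internal edge is the percentage of replicate NJ
trees containing the same bipartition, computed on the point-estimate tree.

# Homopolymer polishing

Nanopore's dominant error mode is homopolymer length. Candidates are all
maximal single-base runs of length ≥ `min_run` (default 3 — short enough to
cover real ONT errors, long enough to keep candidate counts tractable; the
value is not prescribed by any upstream source). A read "supports" a run
length only if its alignment covers the run *plus one aligned anchor base
on each side*; reads ending inside the run, clipped through it, or
secondary/supplementary alignments are excluded. The observed length is
derived from the CIGAR: matched bases of the run's nucleotide inside the
run plus inserted copies at its edges, so a deletion spanning the run
yields an observation of 0.

The correction rule is strict: the best-supported alternative length `L*`
(ties: closest to the assembly length, then smaller — a tie-break fixed
here so results are deterministic) is adopted only when it has at least 10
supporting reads *and* strictly more than a quarter of the spanning reads.
Support of exactly one quarter does not qualify. Corrections are applied
right-to-left so earlier coordinates stay valid, with an old-to-new
coordinate shift table.

Candidate localisation in real data can come from internal-stop flags
raised during peptide extraction (`extract_peptides()` marks CDSs whose
translation hits a premature stop) or from an externally derived interval
list; the polisher itself is agnostic.

# Sequencing planning

`required_total_bp = plastome_size × target_coverage / plastid_fraction`.
Defaults follow organelle practice: 50× target coverage, plastid fraction
supplied by the user (a few percent is typical for total gDNA from leaf
tissue). The Gbp rendering rounds half-up to two decimals and drops a
trailing zero, matching how such figures are usually quoted.

# The synthetic world

`simulate_proteomes()` evolves i.i.d. residue substitutions down a fixed
8-taxon species tree (interest + reference sister pair, five background
taxa, one distant outgroup; pendant branches 0.03–0.05, outgroup 0.2
substitutions/site) with uniform replacement — no rate matrix, no indels,
no among-site rate variation. This is explicitly non-biological: it is
sufficient to exercise filters, alignments and distance trees, and its
truth tables (planted paralogs, losses, outliers) score every filter
exactly. Defaults: 40 genes of 80–250 aa, paralog/loss/outlier rates 0.05,
outlier branch multiplier 10 (a gross misassignment, the kind the IQR fence
is meant to catch). Gene trees handed to the outlier filter are rebuilt by
NJ from the simulated members rather than copied from the species tree, so
flagging sees estimation noise. A green end-to-end test therefore
establishes that the machinery recovers *synthetic* truth under benign
conditions — not that the pipeline is robust to alignment error,
heterotachy or real ONT error profiles.

`simulate_plastome_reads()` plants homopolymer indels (default four sites,
true run length 7, three draft deletions and one draft insertion) into a
random 20 kbp contig, and samples error-free 1 kbp reads at 30× where 60%
carry the true run length and the rest the draft's; CIGARs are correct by
construction. Quality strings are constant; there is no general indel or
substitution model. The planted support levels (~18 of ~30 spanning reads)
sit comfortably inside the correction rule, which is the point: the
end-to-end test checks the rule's plumbing, while the rule's boundaries are
tested directly on constructed support histograms.

All generators are byte-deterministic under a fixed seed.

# Numerical and degenerate-input choices

* Quartile definition is pinned (type 7) and factored into
  `iqr_quartiles()` so the test oracle can interpolate independently.
* `gc_content` excludes IUPAC ambiguity codes from numerator and
  denominator and refuses empty or all-ambiguous input.
* CDS lengths not divisible by 3 skip the feature with a warning rather
  than guessing a frame; trans-spliced genes (e.g. *rps12*) are joined in
  listed interval order — no trans-splicing is attempted.
* Empty orthogroup lists, empty FASTQ files, zero-coverage candidates and
  overlapping correction decisions all produce explicit errors or
  zero-effect results, never silent guesses.
* An orthogroup emptied by filtering is discarded at the step that emptied
  it; a run in which nothing survives raises an "empty supermatrix" error
  before any tree is attempted.

# Known limitations

* The built-in aligner and NJ tree are fixtures-grade; real analyses should
  use the external-tool hooks (MAFFT, IQ-TREE).
* The substitution simulator has no rate heterogeneity, so it cannot probe
  the outlier filter's false-positive behaviour on realistically uneven
  trees — on the default tree a few non-planted leaves do get flagged, which
  the pipeline tolerates by design.
* SAM support counting trusts the aligner's CIGAR; it does not re-align
  around the run the way a base-quality-aware polisher would.
* GenBank flat-file parsing covers CDS features with join/complement
  locations only.
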