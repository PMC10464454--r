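Package: plastophylo
Title: Plastome Phylogenomics: Orthogroup Cleaning, Supermatrix Trees and
    Homopolymer Polishing
Version: 0.1.0
Authors@R: person("Plastophylo", "Developers", role = c("aut", "cre"),
    email = "plastophylo@example.org")
Description: Toolkit for plastome-scale phylogenetics from long-read
    assemblies. Extracts peptides from annotated plastome records, trims
    peptide sets before orthology inference, cleans orthogroups (terminal
    branch-length outlier removal by the 1.5*IQR rule, linked-presence and
    outgroup-count filters, paralog pruning), aligns and concatenates
    orthogroups into a partitioned supermatrix, and builds neighbor-joining
    trees with bootstrap support or exports inputs for external maximum
    likelihood tools. Also detects homopolymer frameshift candidates in a
    draft plastome and corrects them when enough mapped reads support an
    alternative run length, plans sequencing throughput for organelle
    assemblies, and simulates all pipeline inputs with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
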