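Package: ohdlf
Title: Orthologous Haploid Duplication and Loss Filtering for Phylogenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects orthologous genes for phylogenetic tree construction from
    de novo transcriptome orthogroups. Orthogroups in the OrthoFinder table
    dialect are filtered by species missing rate and per-species maximum copy
    number; near-identical same-species copies (heterozygous alleles, recent
    duplicates) are gated by pairwise global-alignment identity and merged
    into consensus sequences by per-site voting, with divergent sites trimmed.
    Retained loci are emitted as per-locus alignments, a concatenated
    supermatrix in relaxed PHYLIP format with a partition table, and an
    aggregated multi-newick gene-tree file for coalescent species-tree
    methods. A synthetic-data generator emulates heterozygosity, duplication,
    loss and deep-paralog contamination with analytic ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
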