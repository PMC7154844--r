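Package: splfam
Title: Characterization of SQUAMOSA Promoter Binding Protein-Like (SPL) Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-level characterization of SPL
    (SQUAMOSA promoter binding protein-like) gene families: SBP-domain
    detection and zinc-finger typing (C3HC2HC vs C4C2HC), gene-family
    table statistics (ORF finding, molecular weight, isoelectric point),
    GO-annotation Venn bookkeeping, tissue/age/genotype expression
    partitions, Spearman rank co-expression networks with p-value
    threshold ladders, subsampling replicates and random-background
    negative controls, Markov clustering, neighbor-joining group
    classification, Nei-Gojobori (1986) Ka/Ks estimation, and
    sequence-logo information content. A synthetic-data module generates
    expression matrices with planted correlated blocks and group-specific
    transcripts, SPL-like proteins with embedded SBP domains, and codon
    pairs evolved at a controlled dN/dS, so the whole pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    phangorn,
    igraph,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
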