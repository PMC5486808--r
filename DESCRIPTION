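Package: amplimhc
Title: MHC Class I Amplicon Genotyping and Molecular Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes major histocompatibility complex (MHC) class I alleles
    from deep-sequenced per-individual amplicons and analyses their molecular
    evolution. The genotyping front end implements a four-step filtering
    cascade: a minimum read-depth gate per amplicon, greedy depth-ordered
    clustering that reassigns 1-2 bp PCR artefacts to their parent sequences,
    a per-amplicon frequency threshold calibrated from technical-duplicate
    concordance, and exhaustive-breakpoint PCR chimera screening. The
    statistics layer computes segregating sites, nucleotide diversity,
    Kimura two-parameter and p-distance divergence with bootstrap standard
    errors, Nei-Gojobori dN/dS partitioned over peptide-binding residues
    (PBR) versus non-PBR codons, and a counting-based per-site selection
    test on a neighbor-joining tree with parsimony ancestral codons. A
    simulator generates multi-locus amplicon read sets with PCR artefacts,
    chimeras and technical duplicates, together with machine-readable truth
    tables, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
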