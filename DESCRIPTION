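Package: mycovir
Title: Discovery and Characterization of Mycovirus Genomes from Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for triaging de novo assembled fungal transcriptome contigs
    for RNA virus signatures and characterizing the resulting candidate
    genomes. Includes six-frame ORF prediction under the standard and
    mold-mitochondrial genetic codes, a position-specific score matrix scanner
    for viral RNA-dependent RNA polymerase (RdRP) motif blocks with ingestion
    of HMMER3 per-domain tabular output, detectors for family-diagnostic
    genome features (-1 ribosomal frameshift slippery sites,
    termination-reinitiation junctions, amber stop-codon readthrough,
    conserved degenerate UTR motifs, read-coverage tracks, read-based contig
    extension and stitching), an ICTV-style species demarcation engine with
    per-taxon percent-identity thresholds, a ground-truthed synthetic viral
    genome and read simulator covering thirteen mycovirus family archetypes,
    and a machine-readable catalog of 59 mycoviral genomes with summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
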