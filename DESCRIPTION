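Package: tgaredox
Title: Regulatory Element Scanning and Cysteine Redox-Modification
    Profiling for TGA Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative analysis of TGA bZIP transcription
    factors and their regulatory cis-elements. Scans genomic sequences for
    the 33-bp AAGAAT-type response element of the AGAMOUS second intron and
    classifies candidates as full or partial motifs by a degenerate-hexamer
    anchor, a TGACG-core requirement and a nucleotide-deviation threshold;
    maps reference cysteine positions through protein multiple alignments to
    call equivalent cysteines in homologs and annotate N-terminal
    extensions; performs in-silico AspN digestion and assigns observed
    neutral masses to cysteine-modification hypotheses (S-glutathionylation,
    intra- and intermolecular disulfide bridges) by delta-mass matching;
    joins the per-species results into presence/absence profiles on a
    supplied species tree; and generates seeded synthetic inputs with exact
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
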