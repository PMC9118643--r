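Package: sodscan
Title: Gene-Family Analysis of Superoxide Dismutases from Sequence, Genome
    Context and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide characterisation of
    superoxide dismutase (SOD) gene families, as performed in mollusc
    comparative genomics. Candidate SODs are identified by local alignment
    of embedded Cu/Zn- and Fe/Mn-SOD reference domains with Karlin-Altschul
    E-value thresholding; physicochemical descriptors (molecular weight,
    isoelectric point, instability index, aliphatic index, GRAVY) are
    computed from sequence; conserved metal-ligand residues are mapped by
    global alignment and used to classify proteins into five functional
    groups (Mn-SOD, Cu/Zn-SOD with full ligand sets, Cu-only, Zn-only and
    metal-free); tandem duplications and collinear blocks are detected from
    gene coordinates under a 70/70 coverage-identity rule; motif and
    promoter PWM scanning annotate architectures and cis-elements;
    expression matrices are normalised to FPKM/TPM and responsive genes are
    called by one-way ANOVA followed by Duncan's multiple range test. A
    synthetic-data module generates proteins with controlled ligand
    knockouts, toy genomes with planted tandem arrays and collinear
    segments, and negative-binomial count matrices with planted effects,
    each with machine-readable truth tables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
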