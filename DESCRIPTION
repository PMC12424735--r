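Package: kmethyl
Title: Lysine Methylation Site Prediction with Multitask Transformers and
    Targeted Mass-Spectrometry Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Curates high-confidence lysine post-translational modification
    (PTM) datasets from proteome FASTA, PTM-annotation and solvent-accessibility
    tables; reduces sequence-window redundancy by greedy identity clustering and
    builds stratified train/validation/test splits; supplies per-residue
    embedding matrices (precomputed or synthetic with a planted, partially
    task-shared signal); defines MLP and transformer site classifiers, including
    a multitask transformer with four PTM-specific heads trained on
    task-homogeneous batches under a gamma-weighted methylation loss; evaluates
    with precision-recall and ROC curves, prevalence-corrected precision and
    operating-threshold selection; scans proteomes, extrapolates methylome size,
    samples score-matched candidate sets and computes mutation delta-scores; and
    generates in-silico tryptic digests, precursor and fragment mass-to-charge
    values, and parallel-reaction-monitoring isolation lists for wet-lab
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
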