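Package: epithread
Title: Neoepitope Prediction and Peptide/MHC Threading Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning somatic single-nucleotide variants into ranked
    candidate neoepitopes and for screening those peptides against HLA class I
    alleles by fixed-backbone structural threading. The variant side implements
    a caller-consensus filter, oxidative-artifact (OxoG) and RNA-expression
    filters, 2n-1 peptide windowing with self-peptide pairing, percentile-rank
    binder filtering, and grouping/ranking of ImmunoActive Regions. The
    structural side trims a template peptide/MHC complex to the binding groove,
    threads allele sequences onto the fixed backbone, repacks side chains over
    a bundled rotamer library by simulated annealing, and reports averaged
    binding energies with a polyAla control, per-residue decomposition,
    BLOSUM62 identity landscapes and Kullback-Leibler groove logos. Supporting
    analyses include Kabsch superposition and selection RMSD, Shrake-Rupley
    solvent-accessible and buried surface area, contact counting, phi/psi-based
    3_10-helix classification, theoretical peptide masses, and Boltzmann
    sigmoidal melting-curve fitting. Seeded generators provide synthetic
    fixtures for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    vcfR,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
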