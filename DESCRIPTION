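Package: fibrilcap
Title: Structure-Based Design of Miniproteins That Cap Amyloid Fibril Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing miniprotein inhibitors that bind the growing
    tips of amyloid fibrils and block further monomer addition. Infers the
    screw symmetry (axial rise and twist) relating stacked fibril layers,
    generates the virtual next layer a capping inhibitor must occupy,
    enumerates beta-strand binding sites at the fibril tip, builds idealized
    miniprotein scaffolds in seven helix/strand topology classes, grafts
    scaffold strands onto tip sites by backbone superposition, scores docked
    poses with funnel metrics (backbone hydrogen-bond satisfaction, interface
    atom counts, a contact-potential binding-energy surrogate, and
    dihedral-based residue propensity), greedily optimizes interface
    sequences, and ranks designs. Also fits thioflavin-T aggregation kinetics
    (logistic lag time) and saturation binding curves, and generates
    ground-truth synthetic fibrils and kinetic datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
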