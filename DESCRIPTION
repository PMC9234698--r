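Package: nmrmodelcheck
Title: Model-Versus-Data Validation of Protein Structures Against NMR Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Validates protein structure models (NMR ensembles, crystal
    structures, predicted models) against experimental solution NMR data.
    Implements RPF-DP scoring of interproton distance networks against
    ambiguous NOESY peak-list assignments, residual dipolar coupling (RDC)
    Q-factor analysis via SVD fitting of the alignment (Saupe) tensor, and
    ensemble structure comparison (Kabsch superposition, C-alpha RMSD,
    GDT_TS, medoid selection, pairwise similarity matrices). Includes
    seeded synthetic-data generators (toy structures, NOESY peak lists,
    RDC sets, freely-rotating-chain null conformers) so every metric can
    be exercised and tested without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
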