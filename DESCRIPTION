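Package: softdis
Title: Soft Disorder and Interface Analysis of Protein Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates X-ray crystal structures in legacy PDB format with
    per-residue soft disorder (normalized Calpha B-factors), missing-residue
    disorder (REMARK 465) and protein-protein / protein-nucleic-acid
    interface residues; clusters near-identical chains, maps annotations
    onto a cluster representative and computes cluster-level region unions
    (UIR, UMR, USDR, IDR, disorder-to-order), the number of distinct
    interfaces (NDI), interface containment hierarchies and connected
    spatial regions; scores the correspondence between soft disorder and
    interfaces with confusion-matrix metrics against closed-form random
    baselines; and generates synthetic PDB fixture clusters with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
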