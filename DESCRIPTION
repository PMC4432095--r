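Package: molforge
Title: Headless Molecular Building, Symmetry and Scalar-Field Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable construction and editing of molecular structures in
    ad-hoc internal coordinates (distances, angles, torsions over selected
    atoms), symmetry-operation based building with duplicate merging and
    symmetrization, point-group detection, volumetric scalar fields with
    isosurface extraction and electrostatic-potential surface coloring,
    orbital subspace (RAS) bookkeeping and export, geometric annotation
    objects with PLY scene export, multi-format molecular file I/O (XYZ,
    an XML-extended XYZ dialect, Gaussian cube) and an external converter
    plug-in framework, plus deterministic fixture generators. Designed as a
    headless library and command-line tool for computational chemistry
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    yaml,
    igraph,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
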