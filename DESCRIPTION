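Package: mivct
Title: Virtual Clinical Trials of Mechanical Imaging on Compressible Breast Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulates mechanical imaging (MI) of the breast under
    mammographic compression. Builds software breast phantoms from seeded
    multi-octave 3D Perlin gradient noise, calibrates thresholds to target
    dense-tissue percentages (an aging series sharing one anatomy),
    tetrahedralises the breast solid, maps voxel tissue mixtures to
    neo-Hookean stiffness moduli, solves quasi-static plate compression with
    frictionless rigid-plate penalty contact, and bins the plate contact
    forces into the 1 cm x 1 cm sensor pressure map with total reaction
    force, contact area and mean stress summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
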