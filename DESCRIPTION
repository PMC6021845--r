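Package: chipmold
Title: Blueprint-Driven 3D-Printable Master Molds for Lab-on-a-Chip Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts color-coded 2D blueprint images of Lab-on-a-Chip master
    templates into watertight, millimeter-scaled STL meshes ready for 3D
    printing. A palette maps blueprint colors to structural roles (channels,
    chambers, inlet ports) and extrusion heights; each pixel becomes one voxel
    column over a base slab, and the exposed voxel faces are exported as a
    manifold triangle mesh in binary or ASCII STL. Also provides the two
    quantitative procedures used to evaluate such molds: a top-view overlap
    metric (area accuracy from the symmetric-difference region, and the derived
    per-axis length error over the model diagonal), and an FFT-based striped
    marker visibility statistic that tracks bacterial growth through broth
    turbidity. Synthetic blueprint and marker generators make every pipeline
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
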