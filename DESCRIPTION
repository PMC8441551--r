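Package: tdrm
Title: Track-Density Ratio Mapping of Tractography Streamlines by Fiber Type
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-processing of whole-brain diffusion-MRI tractography.
    Classifies streamlines into projection, commissural, short-association
    and long-association fibers from the tissue compartments of their two
    terminals, rejects noise (white-matter terminal) and ineffective (no
    cortical terminal) tracks, counts terminals per 1 mm^3 voxel and per
    parcellation piece, renders RGB track-density ratio maps through
    exponential intensity transforms, and runs group-level density and
    hemispheric-asymmetry statistics. Includes a synthetic phantom with
    known fiber-class ground truth so the whole pipeline is testable
    without real data, readers and writers for MRtrix TCK streamline files
    and NIfTI label volumes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
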