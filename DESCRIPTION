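Package: MPIron
Title: Magnetic Particle Imaging Based Iron Quantification for Ex Vivo
    Vascular Samples
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for iron-oxide nanoparticle
    quantification in ex vivo tissue samples by magnetic particle imaging
    (MPI) and magnetic particle spectroscopy (MPS). Implements a Langevin
    mixture tracer model with Debye relaxation, field-free-point Lissajous
    scanning, system-function simulation on a voxel grid, frequency-component
    selection by SNR, bandwidth and mixing order, regularized Kaczmarz image
    reconstruction, cutoff-and-integrate volume-of-interest iron mass
    quantification, harmonic-ratio based MPS quantification with
    mobility-matched references, Perls' stain colour-profile morphometry,
    elemental-map linear calibration with limit-of-detection estimation, and
    an end-to-end synthetic cohort study with agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, Spatial, Visualization, Preprocessing
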