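Package: megsi
Title: Simulation-Trained Neural and Classical Inverse Solvers for MEG
    Source Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Electromagnetic source imaging for magnetoencephalography
    (MEG) built entirely on synthetic data. Provides a spherical
    single-shell forward model with radial magnetometers, a generator of
    Gaussian-damped sinusoidal dipole activity (focal and extended
    activations, white sensor noise at configurable SNR), a windowed
    convolutional/fully-connected neural network that maps multichannel
    sensor windows to whole-brain dipole amplitudes, reference
    implementations of four classical inverse solvers (LCMV beamformer,
    residual-variance dipole scanning, minimum-norm estimation, eLORETA),
    and the evaluation metrics used to benchmark them (distance of
    localization error, active volume, envelope NRMSE, intersection over
    union, depth-stratified analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'metrics.R'
    'forward.R'
    'recording.R'
    'inverse.R'
    'signals.R'
    'scenarios.R'
    'training-set.R'
    'network-layers.R'
    'network.R'
    'config.R'
    'benchmark.R'
    'bundle.R'
    'geometry-io.R'
    'model-io.R'
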