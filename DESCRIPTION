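Package: hespattern
Title: Stochastic Delay Models and Spatiotemporal Pattern Analysis of
    HES5 in Neural Progenitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates coupled HES5 gene-expression dynamics on a
    hexagonal lattice of neural progenitor cells using a chemical
    Langevin model with transcriptional delay, where cells repress each
    other's transcription through a delayed inter-cellular Hill function
    (Notch-Delta lateral inhibition). Provides the analysis toolkit used
    to characterise spatiotemporal HES5 micro-patterns: Hilbert-transform
    phase reconstruction and the Kuramoto order parameter, spatial
    periodicity by bootstrap autocorrelation and Lomb-Scargle
    periodograms, kymograph band persistence and phase maps, detection of
    microclusters of correlated nuclei in segmented-nucleus tables with
    randomisation controls and radial-gradient removal, and a
    differentiation-probability model driven by protein levels relative
    to the population mean. Synthetic-data generators with recorded
    ground truth emulate the live-imaging inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal,
    pracma
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
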