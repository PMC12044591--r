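Package: tgaftir
Title: Automated Identification and Semi-Quantification of Microplastics from TGA-FTIR Evolved-Gas Data
Version: 0.1.0
Authors@R:
    person("Daniel", "Keller", email = "dkeller@example.org", role = c("aut", "cre"))
Description: Tools for analysing thermogravimetric analysis coupled with
    Fourier-transform infrared spectroscopy (TGA-FTIR) of plastic-containing
    samples. Provides preprocessing of temperature-resolved evolved-gas FTIR
    spectra (adaptive smoothness penalised least-squares baseline correction,
    standard normal variate normalisation, region masking, transfer-line
    temperature-offset correction, Gram-Schmidt total-absorbance traces), a
    temperature-penalised Pearson spectral matching algorithm with iterative
    residual re-matching for mixtures, multilabel one-vs-rest machine-learning
    classification (k-nearest neighbours, multilayer perceptron, random
    forest, linear support vector classifier) with extended multiplicative
    scatter augmentation, synthetic mixture-thermogram generation for
    evaluation, multilabel performance metrics, and DTG-area / multivariate
    curve resolution based composition estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
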