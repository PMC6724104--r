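Package: iokr
Title: Input-Output Kernel Regression for Small Molecule Identification
    from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies small molecules from tandem mass (MS/MS) spectra by
    input-output kernel regression (IOKR): kernel ridge regression from a
    spectrum feature space into a molecular-fingerprint feature space, with a
    kernelized pre-image search that ranks candidate molecules. Implements the
    reverse direction (mapping molecules into the spectrum feature space), a
    late-fusion learner that combines many kernel regression models by
    minimizing a structured Hinge loss with mini-batch subgradient descent,
    probability product kernels on peak lists, linear, Gaussian, Tanimoto and
    Gaussian-Tanimoto kernels on binary fingerprints, kernel centering and
    cosine normalization, a structure-grouped cross-validation protocol with
    top-k accuracy reporting, and a synthetic benchmark generator for testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
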