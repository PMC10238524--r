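Package: mvmar
Title: Metal Artifact Reduction in kV-CT Slices Using Megavoltage CBCT Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative projection-domain reduction of metal artifacts in
    kilovoltage CT slices using a co-registered megavoltage CBCT prior.
    The megavoltage image, nearly free of metal artifacts, is segmented
    block-wise with multi-threshold Otsu into high/medium/low-density
    tissue regions; a piecewise-constant template filled with kV mean
    values predicts the artifact-free sinogram, and the kV/template
    sinogram difference restricted to the metal trace is smoothed,
    reconstructed and subtracted from the kV image, iterating as the
    template means improve. Includes LIMAR and NMAR baselines, ROI image
    quality metrics (mean CT value, noise SD, MRE, NRMSD, MAD), a
    parallel-beam projector/FBP pair, and a polychromatic dual-energy
    phantom simulator (beam hardening, photon starvation, Poisson noise)
    that generates co-registered kV/MV/ground-truth slice triples for
    end-to-end evaluation without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
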