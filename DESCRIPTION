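Package: petcycle
Title: Attention-Gated Cycle-Consistent Adversarial Enhancement of Short-Axis PET Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates low-quality short-axial-field-of-view PET slices into
    high-quality total-body-like PET slices with a cycle-consistent adversarial
    network whose generators carry convolutional block attention (channel and
    spatial gating) and whose objective combines a gradient-penalty critic loss
    with cycle-consistency, identity and supervised paired L1 terms. Includes a
    synthetic paired-phantom simulator emulating sensitivity-dependent PET
    degradation, NIfTI slice input/output, the NRMSE/PSNR/SSIM evaluation
    metrics, a deterministic CPU training loop, and a command-line interface.
    The convolutional network engine (convolution, transposed convolution,
    batch normalisation, reverse-mode gradients, Adam) is implemented in
    vectorized base R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
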