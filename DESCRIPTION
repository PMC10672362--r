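Package: octshot
Title: Few-Shot Speckle Suppression for Optical Coherence Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for one-shot and few-shot supervised speckle suppression in
    optical coherence tomography (OCT) B-scans. Includes a physics-based speckle
    simulator (layered phantoms, separable Gaussian/Hanning-FFT point spread
    functions, fully developed speckle with exponential intensity statistics,
    incoherent angular compounding), four trainable patch-based despecklers
    (recurrent encoder-decoder, its deblurring variant, an adversarially refined
    patch-averaging variant, and a patch U-Net) with built-in gradient-based
    training, and a domain-awareness layer that computes per-axis
    sampling-resolution ratios of acquisition systems and plans rational
    resampling to adapt images between systems with mismatched speckle grain
    size. Ships PSNR/SSIM tile evaluation, TIFF/PNG/NPY image I/O and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
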