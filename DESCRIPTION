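Package: niend
Title: Neuronal Image Enhancement Through Noise Disentanglement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhancement pipeline for 3D light-microscopy neuronal image
    stacks, targeting the noise classes of sectioning-based whole-brain
    imaging (fMOST): a slice-recursive Gaussian diffusion filter that removes
    the axial flare/attenuation artifact, an orthogonal profile filter for
    separable low-frequency backgrounds (stripes, mosaic boundaries),
    instance-aware intensity shifting with 16-to-8-bit downgrade, and
    slice-wise Haar wavelet denoising with BayesShrink thresholds. Also
    provides the companion image-quality metrics (signal-background contrast,
    background uniformity, foreground relative standard deviation), neuron
    reconstruction scoring against gold standards via the
    percent-of-different-structures metric (precision, recall, F1), a
    synthetic phantom and degradation simulator for ground-truth testing, and
    an LZMA compression-rate utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
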