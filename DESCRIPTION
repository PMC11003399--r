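Package: aoholo
Title: Computer-Generated Acousto-Optic Holography for Pseudo-2D Light Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieval, composition and evaluation of computer-generated holograms
    for acousto-optic deflector (AOD) based light patterning. Implements regularized
    iterative Fourier transform (Gerchberg-Saxton) retrieval of phase-only, apodized
    and complex (joint amplitude and phase) one-dimensional holograms; their
    composition into pseudo-2D holograms for crossed-AOD systems, including a
    circular-aperture-aware extended retrieval; numerical reconstruction with
    configurable input beam and system aperture; reconstruction quality metrics
    (target error, speckle noise, first-order power efficiency, moving phase
    variance); conversion between optical phase profiles and AOD acoustic frequency
    modulation envelopes; an orthonormal basis of pseudo-2D polynomials on the unit
    disk with Zernike decomposition; and serial holography of seven-segment-display
    text via pseudo-2D-separable meta segments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
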