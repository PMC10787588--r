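Package: corrdop
Title: Correlational Photoacoustic Doppler Flowmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain correlational Doppler flowmetry for co-registered
    photoacoustic/ultrasound (AR-PAM/US) endoscopic scans. Implements the full
    off-line processing chain: FIR band-pass conditioning of raw RF A-lines,
    noise-floor estimation and amplitude gating, band-limited axial
    interpolation, sliding-window cross-correlation lag search between adjacent
    A-lines with correlation-amplitude filtering, conversion of correlation
    shifts to axial velocities, ultrasound time-of-arrival surface detection
    with outlier rejection and A-line alignment, surface-geometry beam-to-flow
    angle estimation with capped cosine compensation, polar B-scan display, and
    region statistics. A rotational scan simulator with known flow ground truth
    (linear tube, spiral tube, and lumen phantoms) supports validation of every
    stage in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rhdf5,
    signal,
    yaml,
    jsonlite,
    png,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
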