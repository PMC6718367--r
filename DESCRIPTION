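Package: mlcscatter
Title: In-Air Output Ratio Modeling with an Explicit MLC Scatter Source
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Head-scatter modeling for linear-accelerator photon beams.
    Implements a dual-source in-air output ratio (Sc) engine (focal source
    plus flattening-filter extra-focal Gaussian source and monitor
    backscatter) together with an explicit multi-leaf collimator (MLC)
    scatter source composed of a line-based component (rounded leaf ends)
    and an area-based component (radiation-exposed leaf faces), separated
    by a geometric scatter interface at the mid-MLC plane. Provides
    rectilinear aperture geometry for 60-pair MLC banks, constrained
    nonlinear least-squares parameter fitting from measured-Sc tables,
    quadratic area-to-perimeter-ratio parameter interpolation, Clarkson
    sector integration of phantom scatter factor and tissue maximum ratio
    for point dose in irregular fields, and a synthetic measurement
    campaign generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
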