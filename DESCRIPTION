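Package: cryptvillus
Title: Agent-Based Simulation of Ileal Crypt-Villus Epithelium Under Inflammation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: A spatially explicit, discrete-time agent-based simulator of the
    ileal crypt-villus epithelium. Crypts and villi are rectangular prisms
    unwrapped onto 2-D lattices on which morphogen fields (Wnt, BMP, Hedgehog,
    SFRP1, inflammatory cytokines) diffuse and decay, and gut epithelial cells
    (stem, transit-amplifying, enterocyte) divide, migrate, differentiate and
    die under the control of an intracellular signaling network evaluated as
    time-delayed rules (Wnt/beta-catenin, BMP receptor binding, Hh/SFRP1,
    PTEN/PI3K/Akt, TLR4/NF-kB/RIP). Inflammatory cell agents (monocytes,
    macrophages, neutrophils) arrive at abstracted blood vessels, chemotax
    along cytokine gradients and clear necrotic debris. A scenario library
    reproduces homeostasis, morphogen pathway inhibitions, local mucosal
    wounding, ischemia-reperfusion injury with and without enterocyte
    sloughing, and chronic low-grade TLR4 stimulation driving colonic
    metaplasia. Observables (cell populations, architecture dimensions,
    renewal time, gradient profiles, outcome classification) are returned as
    tidy tibbles with broom-style tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    dplyr,
    tidyr
Config/testthat/edition: 3
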