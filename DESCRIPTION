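Package: cfmphyto
Title: Cell Flux Model of Phytoplankton Growth Under Phosphorus Limitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained macromolecular allocation model of phytoplankton
    growth (CFM-Phyto) under phosphorus and carbon limitation. Computes
    steady-state growth rates from a carbon-conservation quadratic and a
    phosphorus-balance cubic, partitions cellular carbon and phosphorus among
    protein, RNA, DNA, chlorophyll, thylakoid phospholipid, storage and
    essential pools, and calibrates either the allocation model (phosphate
    affinity and photosynthetic-machinery ratio) or a Monod reference model
    (maximum growth rate and half-saturation constant) against growth-rate
    versus phosphate datasets by Metropolis-Hastings sampling. Includes a
    synthetic-data generator for saturating growth curves, experiment runners
    for allocation profiles, light sweeps and nitrogen-phosphorus contrasts,
    and a thin command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
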