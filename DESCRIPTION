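Package: spiroscan
Title: Quantitative Structural Analysis of AdhE Spirosomes and Substrate Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative structural analysis of bifunctional
    aldehyde-alcohol dehydrogenase (AdhE) spirosomes and, more generally, of
    oligomeric protein assemblies with internal substrate channels. Implements
    Shrake-Rupley solvent-accessible surface area and interface buried surface
    area, inter-protomer salt-bridge and hydrogen-bond network detection, a
    grid-probe tunnel finder with channel-lining residue extraction and
    solvent-enclosure profiling, amino-acid composition and log2-fold channel
    enrichment, multiple-sequence-alignment column conservation and motif
    scanning, ligand residence-time and hydrogen-bond occupancy analysis of
    trajectories, rank-based length statistics (exact and approximate
    Mann-Whitney U), and a synthetic-data module that generates every fixture
    class with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
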