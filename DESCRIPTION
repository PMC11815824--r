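Package: cgsugar
Title: Systematic Coarse-Grained Parametrization of Glucose and Mannose
    Disaccharides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds Martini 3 coarse-grained models of glucose- and
    mannose-based disaccharides from all-atom simulation data.  Covers
    enumeration of glycosidic linkage and anomer combinations with
    GLYCAM-style names, graph-based atom-to-bead mapping with ring virtual
    sites, projection of trajectories onto bead coordinates, Boltzmann
    inversion of bonded distributions into harmonic parameters, GROMACS
    topology and run-protocol emission, histogram-overlap comparison of
    bonded distributions, and minimum-distance network analysis of
    disaccharide aggregation.  A synthetic trajectory generator with
    prescribed bonded distributions supports end-to-end validation without
    reference trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
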