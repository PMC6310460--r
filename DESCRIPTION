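Package: triphos
Title: Triphosphate-Chain Conformations and Cation Binding in Mg-NTP Complexes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Geometric analysis of the triphosphate chain of Mg-ATP/Mg-GTP
    complexes from molecular-dynamics trajectories and from experimental
    P-loop NTPase structures. Computes chain-shape descriptors (P(A)-P(G)
    distance, P(B)-O(3B)-P(G) bridge angle, inter-phosphate dihedrals),
    classifies Mg2+ coordination modes (bidentate beta-gamma, tridentate
    alpha-beta-gamma, curled), assigns monovalent cations (K+, Na+, NH4+) to
    the AG/BG/G binding sites and estimates site occupancies, and provides
    the accompanying statistics: autocorrelation-based frame decimation,
    pooled-variance t-tests, Gaussian fits of dihedral histograms, and
    normalized conformational heat maps. A comparative structure survey
    screens PDB/mmCIF files for P-loop-bound Mg-NTP(-analog) sites, maps
    transition-state mimics (AlF4-, AlF3, MgF3-, BeF3-) onto the
    triphosphate frame, measures their geometry and detects AG-site
    occupants. A synthetic-trajectory generator with known ground truth
    makes every pipeline stage testable without MD engines or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
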