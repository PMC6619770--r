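Package: solvmap
Title: Solvation Thermodynamic Maps from 3D-RISM and GIST
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integral-equation solvation mapping around rigid solutes.
    Solves dielectrically consistent 1D RISM (DRISM) for a rigid three-site
    water model, then the 3D reference interaction site model (3D-RISM) with
    the PSE-n closure family on a rectangular grid, and converts converged
    correlation functions into voxel maps of excess chemical potential,
    solvation entropy (isochoric temperature derivatives), and solute-water /
    water-water energy components, with partial-molar-volume (UCT)
    corrections.  Hydrogen-site maps can be collapsed onto the oxygen
    distribution through an intramolecular shell-kernel reconstruction to
    give molecule-centred maps.  Matching grid inhomogeneous solvation
    theory (GIST) voxel maps (occupancy, translational and orientational
    entropy, energies) are computed from explicit rigid-water frame sets for
    direct comparison, and synthetic fixture generators make every stage
    testable without external data.  Volumetric grids are read and written
    as OpenDX files; solutes are read from PQR files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
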