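Package: foldbind
Title: Residue Interaction Energetics, Surface Hydropathy and 2D Zernike
    Shape Complementarity for Fold Stability and Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare the molecular determinants of protein fold
    stability and protein-protein binding affinity from 3D structures.
    Computes residue-residue non-bonded Coulomb and 12-6 Lennard-Jones
    interaction energy networks with node strengths, totals and
    energy-distribution statistics; solvent-accessible dot surfaces with
    outward normals, relative solvent accessibility, surface and
    interface residue detection; amino-acid composition and interface
    hydropathy profiling; and rotation-invariant 2D Zernike descriptors
    of molecular surface patches for local shape-complementarity
    scoring. Includes generators for parameterized toy dimers and
    complementary surface-patch fixtures, and pipeline drivers that
    stratify datasets by melting temperature or dissociation constant
    and report correlation tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, bio3d
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
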