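# foldbind

Residue interaction energetics, surface hydropathy and 2D Zernike shape
complementarity for comparing protein **fold stability** (melting
temperature, T<sub>m</sub>) and **binding affinity**
(B<sub>a</sub> = log<sub>10</sub> K<sub>d</sub>) from 3D structures.

Stability and affinity are both driven by non-bonded interactions, but
not necessarily the same ones. `foldbind` computes, from a PDB
structure or from built-in synthetic generators:

- **Energy networks** — residue-residue Coulomb
  (E = K·q<sub>l</sub>q<sub>m</sub>/r, K = 332.0636 kcal·Å/(mol·e²))
  and 12-6 Lennard-Jones
  (E = √(ε<sub>l</sub>ε<sub>m</sub>)[(R/r)¹² − 2(R/r)⁶],
  R = R<sub>min</sub><sup>l</sup> + R<sub>min</sub><sup>m</sup>)
  energies summed over atom pairs, as weighted graphs with node
  strengths s<sub>i</sub> = Σ<sub>j</sub> E<sub>ij</sub>, totals, and
  energy-distribution statistics (intra- or inter-molecular scope).
- **Surfaces** — solvent-accessible dot surfaces with outward normals,
  per-residue SASA/RSA, surface (RSA > 0.25) and interface (4 Å)
  residue detection, binding-site points (3 Å).
- **Zernike descriptors** — each surface patch (R<sub>s</sub> = 8 Å) is
  oriented along its mean normal, cone-projected (45°) onto the unit
  disk and expanded in the 2D Zernike basis; the moduli
  z<sub>nm</sub> = |c<sub>nm</sub>| form a 121-component
  rotation-invariant descriptor (order N = 20). The Euclidean distance
  between an "up" template patch and a "down" ligand patch scores local
  shape complementarity; its minimum over the binding site scores the
  complex.
- **Composition & hydropathy** — amino-acid frequency profiles,
  per-chain mean interface hydropathy on a bundled (synthetic,
  documented) water-affinity scale, hydropathy windows and classes.
- **Pipelines** — `runStabilityStudy()` and `runAffinityStudy()`
  stratify labelled datasets by T<sub>m</sub> / B<sub>a</sub> ranges and
  report correlation tables.

## Worked example

```r
library(foldbind)

# a toy dimer with 3 cross-chain contacts at the LJ-minimum distance
toy <- makeToyDimer(residuesPerChain = 6, contacts = 3,
                    contactDistance = 3.8, chargesA = 0.4,
                    chargesB = -0.4, seed = 42)
net <- buildEnergyNetwork(toy$complex, kind = "LJ", scope = "inter")
net
#> EnergyNetwork: toy [LJ, inter]
#>   residues: 12  edges: 36
totalEnergy(net)
#> [1] -0.3063555

interfaceResidues(toy$complex)$A
#>   index chain resno resid
#> 1     1     A     1   GLY
#> 2     2     A     2   GLY
#> 3     3     A     3   GLY

# shape complementarity: a patch is far closer to its exact mold than
# to an independently generated decoy patch
fix <- makePatchWithMold(shape = "bumpy", seed = 7, nDecoys = 1)
descriptorDistance(patchDescriptor(fix$patch, "up"),
                   patchDescriptor(fix$mold, "down"))
#> [1] 0.998229
descriptorDistance(patchDescriptor(fix$patch, "up"),
                   patchDescriptor(fix$decoys[[1]], "down"))
#> [1] 4.153935

# sign recovery on a labelled synthetic dataset: more contacts means
# a more negative LJ total and tighter binding (lower Ba), so the
# correlation of the two is positive
ds <- makeLabelledDataset(n = 20, kind = "affinity", seed = 3)
rep <- runAffinityStudy(ds)
rep$corTotalLJ
#> $r
#> [1] 0.9878849
#> $p
#> [1] 4.750214e-16
#> $n
#> [1] 20
```

Real structures enter through `readPDB()` →
`assignParameters(s, loadForceField())`, after which every function
above applies unchanged.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "foldbind",
                               load_package = "installed")'
```

The suite contains per-module unit/property tests (analytic kernels,
brute-force oracles, an independent Monte-Carlo SASA oracle,
orthogonality and rotation invariance of the Zernike basis) plus an
acceptance file with one test per headline property.

## Notes on bundled data

The force-field table (`united_heavy_atom_nb.tsv`) is an in-house
united-charge heavy-atom set with exactly integral residue charges; the
hydropathy scale (`water_affinity_synthetic.tsv`) is a synthetic affine
rescale of Kyte-Doolittle onto [0, 3]. Both are documented in their
headers and swappable via `loadForceField(path)` /
`loadHydropathyScale(path)`. See the methods vignette
(`vignettes/foldbind-methods.Rmd`) for the full model description.
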