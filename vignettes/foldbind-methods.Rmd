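---
title: "foldbind: methods and model choices"
author: "Package Author"
date: "2026-10-02"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldbind: methods and model choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbind)
```

# The scientific question

Protein fold stability (summarized by the melting temperature $T_m$)
and protein-protein binding affinity (summarized by
$B_a = \log_{10} K_d$) are both governed by non-bonded interactions,
but not necessarily by the same ones. `foldbind` provides the three
computational layers needed to compare their molecular determinants
from 3D structures:

1. **Residue interaction energy networks** — pairwise Coulomb and 12-6
   Lennard-Jones energies aggregated per residue pair, with node
   strengths, totals, and energy-distribution statistics.
2. **Molecular surfaces and composition** — solvent-accessible dot
   surfaces with outward normals, relative solvent accessibility (RSA),
   interface detection, amino-acid composition and interface
   hydropathy.
3. **2D Zernike shape descriptors** — rotation-invariant descriptors of
   surface patches used to score local shape complementarity across a
   binding interface.

Synthetic generators provide structures with known ground truth, and
two pipeline drivers (`runStabilityStudy()`, `runAffinityStudy()`)
stratify labelled datasets and report correlation tables.

# Energy model

## Kernels

For two atoms at distance $r$ (Å) the Coulomb energy is

$$E_C = K \frac{q_l q_m}{r}, \qquad K = 332.0636\
\mathrm{kcal\,\unicode{x212B}/(mol\,e^2)},$$

with partial charges in elementary-charge units, vacuum permittivity
and no distance cutoff or screening. $K$ is derived once from CODATA
constants and frozen as `COULOMB_K`. A useful anchor: two unit charges
of opposite sign at $r = 3.320636$ Å give exactly $-100$ kcal/mol.

```{r}
coulombPair(1, -1, 3.320636)
```

The 12-6 Lennard-Jones energy is

$$E_{LJ} = \sqrt{\varepsilon_l \varepsilon_m}\left[
\left(\tfrac{R}{r}\right)^{12} - 2 \left(\tfrac{R}{r}\right)^{6}
\right], \qquad R = R_{min}^l + R_{min}^m,$$

where the per-atom parameters stored in the force-field table are
$R_{min}/2$ values, so the *sum* of the two table entries is the
location of the minimum, and the depth there is exactly
$-\sqrt{\varepsilon_l\varepsilon_m}$:

```{r}
ljPair(0.1, 0.1, 1.9, 1.9, r = 3.8)
```

## Parameters

Atomic partial charges and LJ terms come from a bundled in-house
united-charge heavy-atom parameter set
(`inst/extdata/united_heavy_atom_nb.tsv`): every heavy atom of the 20
standard residues has a charge chosen so that each residue's total
charge is exactly integral (−1 for ASP/GLU, +1 for LYS/ARG, 0
otherwise), with CHARMM-like LJ well depths and radii by atom class.
The table is deliberately swappable: `loadForceField(path)` accepts any
TSV with the same columns, so a published force field can be dropped in
without code changes. `assignParameters()` matches on (residue, atom
name), reports unmatched atoms, and refuses structures with more than
20% unmatched atoms.

## Networks

`buildEnergyNetwork()` computes residue-pair energies as sums over all
atom pairs (never distance-truncated), for two scopes:

* **intra** — same-structure pairs, excluding self and
  sequence-adjacent pairs (separation < 2), which are dominated by
  bonded terms the non-bonded model does not describe;
* **inter** — cross-chain pairs of a two-chain complex only.

An optional minimum-distance cutoff (4 Å throughout the pipelines)
restricts the network to contacting pairs when building energy
*distributions*; totals are computed without it. CYS–CYS pairs whose
SG–SG distance is below 2.5 Å (disulfide bridges) are excluded by
default from LJ networks only, where the covalent overlap would
otherwise produce enormous repulsive artifacts; for Coulomb the pair
energies stay physically moderate and are kept.

Node strength is $s_i = \sum_j E_{ij}$ over incident edges, satisfying
$\sum_i s_i = 2\sum_{edges} E_{ij}$. Pooled edge-energy distributions
are summarized by four regions (kcal/mol): very strong favorable
($E \le -100$), strong favorable ($-100 < E < -10$), weak
($|E| \le 10$), strong unfavorable ($E > 10$); the strong-interaction
probability is $P(|E| > 10)$. The high-strength tail probability uses a
data-adaptive threshold, the pooled 5th percentile of node strengths.

# Surface model

`computeSurface()` samples each atom's solvent-accessible sphere
(radius $r_{vdw} + 1.4$ Å, Bondi radii) with a deterministic Fibonacci
spiral lattice at 5 points/Å² and removes points occluded by any
neighbouring sphere. Normals are exact radial directions. SASA is the
surviving lattice fraction times the sphere area; RSA divides by a
bundled theoretical per-residue maximum (Gly-X-Gly reference). A
residue is *surface* if RSA > 0.25; residues are *interface* when any
atom is within 4 Å of the partner chain; *binding-site points* are
template surface points within 3 Å of the ligand surface.

# 2D Zernike shape descriptors

A patch is the set of surface points within $R_s = 8$ Å of a center.
It is oriented so its mean normal points along $+z$ ("up") or $-z$
("down"), then projected to the unit disk: a cone apex $C$ is placed on
the $z$ axis, at the height (found by bisection) where the largest
angle between the axis and a secant to any patch point is 45°; each
point maps to the disk by its in-plane coordinates (scaled by the
maximum in-plane radius) and carries its distance $r$ from $C$. Points
are binned on a $G \times G$ grid ($G = 25$ by default; large enough to
resolve order-20 angular structure, small enough that single-patch
pixel statistics stay stable), and interior holes are filled by
iterated 8-neighbour means.

The resulting image $f$ on the unit disk is expanded in the 2D Zernike
basis $Z_{nm}(r,\phi) = R_{nm}(r) e^{im\phi}$:

$$c_{nm} = \frac{n+1}{\pi} \langle Z_{nm} | f \rangle,$$

and the rotation-invariant descriptor is $z_{nm} = |c_{nm}|$. At order
$N = 20$ there are exactly 121 invariants. Numerically the inner
products use per-pixel basis integrals computed by 4×4 sub-pixel
quadrature over the pixel-disk overlap (cached per grid size and
order); on a 101×101 grid this reproduces the orthogonality relation
$\langle Z_{nm}|Z_{n'm'}\rangle = \frac{\pi}{n+1}\delta\delta$ to
about 0.1%.

```{r}
length(descriptorValues(patchDescriptor(
  makePatchWithMold(seed = 1)$patch, "up")))
```

Complementarity between two partners is scored by expanding the
template patch "up" and the ligand patch "down" around the same center
and taking the Euclidean distance between the invariant vectors;
`complementarityScan()` minimizes this over the binding-site points,
and the minimum is the complex's shape-complementarity score (smaller =
more complementary).

# Composition and hydropathy

Interface hydropathy uses a bundled **synthetic** water-affinity scale
(an affine rescale of Kyte–Doolittle onto $[0,3]$, with $H = 0$ at the
purely hydrophobic end); the raw Kyte–Doolittle scale is bundled as an
alternative with the opposite orientation. Each chain's interface
residues are averaged to one $H$ per chain; windows of width 0.6 swept
along the $H$ axis select the complexes whose **both** chains fall in
the window, and class thresholds at 1.3/1.7 split binding regions into
mainly hydrophobic / intermediate / mainly hydrophilic.

# Synthetic data as study conditions

The generators are not mocks: they create structures whose ground truth
is known, so the full pipeline can be validated end to end.

* `makeToyDimer()` — two single-atom-residue chains with an exact
  number of cross-chain contacts at an exact distance; contacts placed
  at the LJ minimum ($r = 2 R_{min}/2$) each contribute $-\varepsilon$.
* `makeToyMonomer()` — a chain with $\pm 1$ salt bridges at sequence
  separation 2, each contributing a controlled Coulomb attraction.
* `makePatchWithMold()` — a smooth (optionally bumpy) patch with
  analytic normals, its exact mold (offset `gap` along flipped
  normals), and independently-seeded decoy patches.
* `makeLabelledDataset()` — toy dimers with
  $B_a = -4 - 0.6\,\mathrm{knob} + \mathcal{N}(0, 0.3)$ (more contacts,
  tighter binding) or toy monomers with
  $T_m = 45 + 4\,\mathrm{knob} + \mathcal{N}(0, 0.3)$ (more bridges,
  more stable), reproducing the experimental sign conventions.

All generators take an integer seed, are bit-reproducible, and leave
the caller's random stream untouched.

```{r}
ds <- makeLabelledDataset(n = 12, kind = "stability", seed = 7)
rep <- runStabilityStudy(ds)
rep$corTotalC
```

# Stratification

Melting temperatures are stratified as very low ($< 55$), low
($[55, 60]$), high ($(60, 70]$), very high ($> 70$) °C; affinities as
very high ($< -9$), high ($[-9, -8]$), medium ($(-8, -7]$), low
($(-7, -5]$), very low ($> -5$) in $\log_{10} K_d$. Shared endpoints
are right-closed, so every value lands in exactly one stratum.

# Numerical choices and limitations

* Problem sizes: the package targets desk-scale structures (up to a
  few thousand atoms); all-pair energy matrices are $O(n^2)$ in atoms.
* The dot-surface SASA is a lattice estimate; at 5 points/Å² it agrees
  with an independent Monte-Carlo rolling-probe estimate to a few
  percent (see the test suite).
* The lattice is not rotated with the structure, so individual boundary
  points near sphere intersections may differ after a rigid rotation;
  aggregate quantities (point counts, SASA) are rotation stable.
* Descriptor distances depend on the shared projection protocol
  (45° cone, $G = 25$, order 20); compare only descriptors produced
  with identical settings.
* The bundled force field and hydropathy scale are synthetic,
  documented, and swappable; absolute energies should not be compared
  against published force-field values, only used comparatively within
  one parameter set.
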