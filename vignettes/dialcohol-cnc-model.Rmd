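---
title: "Modelling core-shell dialcohol cellulose nanocrystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling core-shell dialcohol cellulose nanocrystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dacnc)
```

## The model system

Native cellulose cannot be melt-processed: it degrades before it melts.
Partial conversion to *dialcohol cellulose* - periodate oxidation cleaves
the C2-C3 bond of glucose units, and borohydride reduction turns the two
aldehydes into alcohols - opens the pyranose ring, makes the chains far
more flexible, and renders the fibers thermoformable. Because the
heterogeneous reaction proceeds from the fibril surface inward, partially
modified fibrils are *core-shell* particles: a crystalline native core
wrapped in a disordered dialcohol shell.

`dacnc` builds atomistic models of such particles at the nanocrystal
(CNC) scale and computes the observables used to characterize them:

* a crystal builder for the cellulose I-beta allomorph with graded
  C2-C3 dialcohol modification recipes,
* structural analyses: interchain radial distribution functions and the
  derived structure factor $S(q)$, geometric hydrogen-bond counts,
  glycosidic torsion distributions, solvent-accessible surface area,
  and hydration-shell selections,
* post-processing of steered-shear force-displacement traces into
  engineering stress, maximum shear stress $\tau_{max}$, interfacial
  stiffness $\Delta\tau/\Delta d$, stick-slip events, and force-curve
  interaction energies,
* a synthetic-data module (jittered crystals, random hydration shells,
  parameterized stick-slip traces) whose ground truth makes every
  analysis stage testable without running molecular dynamics.

Running MD itself - force fields, solvation, thermostats - is out of
scope; the package builds the inputs such simulations consume and
analyses the outputs they produce.

## Crystal geometry

The builder uses the monoclinic I-beta cell, the dominant allomorph of
plant cellulose: $a = 7.784$ Å, $b = 8.201$ Å, $c = 10.38$ Å (chain
axis, one cellobiose), $\gamma = 96.5^\circ$. These constants are
embedded package data taken from the published I-beta crystal structure.

The glucose residue itself is *constructed*, not copied from deposited
coordinates: a $^4C_1$ chair is closed from ideal sugar internal
coordinates (C-C 1.52-1.53 Å, C-O 1.42-1.44 Å, ring angles
110-112°), decorated with equatorial O2/O3/O4 and C6 substituents
(beta anomer, *tg* hydroxymethyl, $\chi_{O5-C5-C6-O6} = 180^\circ$), and
then rigid-body fitted under the two-fold screw constraint of the chain
axis: residue $k{+}1$ is residue $k$ rotated by $180^\circ$ about the
axis and translated by $c/2$. The fit targets a glycosidic bond
C1-O4' of 1.41 Å, a C1-O4'-C4' angle of 116°, and linkage torsions
$\Phi$(C4'-O4'-C1-O5) $= -95^\circ$,
$\Psi$(C5'-C4'-O4'-C1) $= -145^\circ$, the crystallographic
conformation of cellulose. Only one sugar enantiomer can satisfy these
constraints (the fit residual grows three orders of magnitude for the
mirror ring), which pins the construction to D-glucose without any
reference coordinates. The fitted template is deterministic: the
optimizer starts from the stored solution and only polishes it.

Chains sit on a grid of the half-diagonal lattice vectors
$u = (a+b)/2$ ($|u| = 5.32$ Å) and $v = (a-b)/2$ ($|v| = 5.96$ Å),
which interleaves the origin and center chains of the cell; grid
diagonals are the (200) sheets, and alternating diagonals are staggered
by $c/4$ along the chain axis. A 7x7 grid of 40-unit chains reproduces
the conventional particle dimensions (see below). Chain ends are capped
at the positions the continuing chain would occupy (O4-H at the
non-reducing end, O1-H at the reducing end), so caps stay inside the
crystallographic envelope.

Hydroxyl hydrogens realize the canonical I-beta hydrogen-bond network:
O3-H donates to O5 of the previous residue (intrachain), O6-H to the
nearest interchain O3 within a sheet. The O2-H proton - whose network
is orientationally disordered in real I-beta - is left at a neutral
trans torsion. This choice is deliberate: orienting *every* hydroxyl
into a perfect network would give about 2.7 bonds per glucose, well
above what equilibrated structures show (about 2); the chosen static
network gives 1.71 per glucose on the 7x7x40 crystal with the default
0.35 nm / 30° criteria, inside the plausible band for an equilibrated
crystal once surface truncation is accounted for.

### Reported dimensions

`measure_dimensions()` reports, by default, the *nominal crystallographic
size* that particle dimensions are conventionally quoted in: length
$= n_{units} \cdot c/2$ (20.8 nm for 40 units) and cross-section = span
of the outermost chain axes plus one carbon van der Waals diameter
(0.40 nm), giving 3.6 x 4.0 nm for the 7x7 grid. The raw atomic-center
extents (`method = "extent"`) are systematically larger (about
3.9 x 4.3 x 20.9 nm) because atoms protrude beyond the outermost chain
axes; both conventions are invariant under rigid motion.

## Modification recipes

Two idealized chain patterns model the periodate chemistry: pattern A
cleaves every second C2-C3 bond along a chain (the alternate bonds
point into the crystal and react later), pattern B cleaves all of them.
The standard recipes combine the patterns by surface layer:

| label | recipe | modified units (7x7x40) |
|-------|--------|--------------------------|
| 0     | native | 0 |
| 25    | layer 1: 22 side chains A + 2 top/bottom chains B | 520 / 1960 (26.5%) |
| 40    | layers 1 and 2, same rule | 880 / 1960 (44.9%) |
| 100   | pattern B everywhere | 1960 / 1960 |

The labels are recipe *names*; the exact modified fraction is what
`compute_dom()` returns (the label-25 recipe flags 26.5% of units - the
accounting basis behind the rounded labels is not specified by the
source modification series, so the package keeps labels and fractions
separate). A control variant (`variant = "surface_B"`) modifies every
bond of the outermost layer only. "Top/bottom" chains are the two at
the extremes of the sheet-stacking diagonal, whose C2-C3 bonds all
face the solvent; for the 7x7 grid this yields the 22 + 2 split of the
perimeter layer. Pattern A's phase (which alternate set reacts) is a
parameter, defaulting to even units.

Modification is pure bookkeeping plus minimal geometry: the C2-C3 bond
is removed from the topology, and one hydrogen is added to each carbon
at the ideal tetrahedral completion of its remaining substituents. No
ring-opening relaxation is attempted - that is the job of whatever
simulation engine consumes the structure, and the two added hydrogens
therefore sit close together until the engine relaxes them. Modified
units are renamed `DAG` (native units are `GLC`) so that files
round-trip the modification state.

## Structural observables

**Interchain RDF.** `interchain_rdf()` histograms distances between
C-O, C-H, or O-H atom pairs *on different chains*; same-chain pairs
are excluded so the profile probes packing rather than covalent
structure. Normalization divides by the spherical shell volume and the
partner-atom density over the frame's bounding box - the appropriate
reference for a single finite particle rather than a periodic liquid.
The implementation is an O(N)-cell-list kernel verified against a
brute-force all-pairs oracle.

**Structure factor.** $S(q)$ is the sine Fourier transform of each
pair-class RDF,
$$S_c(q) = 1 + 4\pi\rho_c \int_0^{r_{max}} r^2\,(g_c(r)-1)\,
\frac{\sin qr}{qr}\, w(r)\, dr,$$
averaged over the three classes (equal weights by default; the peak
positions are insensitive to the weighting, and that insensitivity is
itself a test). Defaults: $r_{max} = 3$ nm with a Lorch window to damp
truncation ripples, $q \in [0.5, 30]$ nm$^{-1}$ at
$\Delta q = 0.05$ nm$^{-1}$. Peaks are extracted by topographic
prominence with three-point quadratic refinement.

On the built crystal (lightly jittered, see below) the dominant
reflection sits at 16.1 nm$^{-1}$, the (200) inter-sheet spacing
($2\pi/0.39$ nm). The merged (1-10)/(110) family appears as a broad,
window-sensitive feature between 9 and 12 nm$^{-1}$, consistent with
the experimental wide-angle positions of those reflections
($q \approx 10.5$ and $11.9$ nm$^{-1}$). Reference analyses of
equilibrated, solvated crystals have quoted the merged peak as high as
13 nm$^{-1}$; the static lattice model does not reproduce that value
under any windowing or normalization we tested, and the package makes
no attempt to force it - the discrepancy is documented rather than
calibrated away.

**Hydrogen bonds.** `detect_hbonds()` uses the standard geometric
criterion - donor-acceptor distance $\le 0.35$ nm and
hydrogen-donor-acceptor angle $\le 30^\circ$, both configurable - with
donors identified from the bond table when present and geometrically
(O-H within 0.115 nm) otherwise. Counts between two groups include
both donation directions, so swapping the groups is symmetric; when the
groups contain glucose units the count is normalized per unit.

**Glycosidic torsions.** One $(\Phi, \Psi)$ pair per linkage, IUPAC
sign convention (cross-checked against an independent implementation),
with 5°-bin histograms normalized to integrate to one. The built
crystal is a single point in torsion space ($-95.6^\circ, -145.9^\circ$
on every linkage); equilibrated structures broaden and, at high
modification, bimodalize these distributions - a static model can only
assert the location of the crystalline mode, not the spread.

**SASA.** Shrake-Rupley with Bondi radii, a water-sized probe
(0.14 nm) and a deterministic golden-spiral point set (960 points by
default; single spheres are exact by construction, overlapping pairs
converge as the point count grows).

**Hydration shells.** `water_shell()` selects whole water residues
with any atom within a cutoff (default 0.6 nm) of the solute.

## Synthetic data: what it emulates and what it does not

**Jittered crystals** stand in for thermal equilibration.
`jitter_crystal()` adds i.i.d. Gaussian displacements with *two*
scales: `sigma` (default 0.02 nm) for native units - of the order of
crystalline fluctuation amplitudes - and `sigma_modified` (default
$10\times$ `sigma`, i.e. 0.2 nm) for dialcohol units. The second scale
is the generator's definition of "amorphous": displacement disorder
comparable to the interchain spacing itself, as seen for flexible
surface chains in equilibrated simulations (0.2-0.5 nm, versus
0.05-0.07 nm in the core). With these two scales the modification
series behaves like its equilibrated counterpart in reciprocal space:
the (200) prominence decays monotonically along the 0 / 25 / 40 / 100
recipes and vanishes at full modification. What i.i.d. jitter does
*not* emulate: correlated chain motion, swelling, water penetration, or
any relaxation of the modified geometry - so passing tests demonstrate
the analysis chain and the disorder bookkeeping, not the thermodynamics
of real shells.

**Random hydration shells** place rigid three-site waters uniformly at
a target density in the accessible shell (within `thickness` of the
solute but at least 0.25 nm from solute heavy atoms and other water
oxygens), with uniform random orientations. This is a Poisson gas, not
liquid water: adequate for testing geometric selections and
cellulose-water hydrogen-bond plumbing, silent about water structure.

**Stick-slip traces.** `synth_force_trace()` builds a piecewise-linear
engineering-stress trace - `n_events` teeth rising at `slope` to
programmed peak heights and dropping over `drop_width` - samples it on
a grid that includes every vertex (so the programmed $\tau_{max}$,
slope, event count and integral are exact before noise), adds Gaussian
noise, and returns the ground truth alongside. The defaults (four
teeth, 120/100/90/80 MPa, 150 MPa/nm, 1 MPa noise) emulate the
qualitative axial-shear signature of two native crystals in close
contact: a few stick-slip events with decreasing peak stress as the
contact area erodes. Over 100 seeds at default noise, the pipeline
recovers $\tau_{max}$, stiffness and energy with well under 2% median
relative error and the event count exactly in at least 95 runs.

## Shear analysis definitions

* **Engineering stress**: $\tau(d) = F(d)/A$ with a *constant* contact
  area $A$ (default 65.5 nm$^2$, the SASA-derived contact area of an
  unmodified crystal pair). Unit chain: 1 kJ mol$^{-1}$ nm$^{-1}$ =
  1.66054 pN; pN/nm$^2$ = MPa.
* **$\tau_{max}$**: global maximum, ties broken toward smaller
  displacement.
* **Interfacial stiffness**: least-squares slope of $\tau(d)$ from the
  start to the first detected stick-slip peak; with no detectable peak
  the window falls back to the first 10% of the displacement range
  (logged). The fit window is a convention - no standard definition
  exists - and on noise-free linear segments the estimate is exact.
* **Stick-slip events**: local maxima with topographic prominence at
  least 10% of the stress range (configurable), each paired with the
  subsequent stress drop.
* **Interaction energy**: trapezoidal integral of the force curve over
  a displacement range, endpoint-interpolated so adjacent ranges add
  exactly. This mirrors the usual qualitative use of pull-curve
  integrals; it is not a rigorous free energy (no enhanced sampling).

Pull traces are ingested from two-column XVG (comment lines `#`/`@`
skipped) or CSV; force-versus-time traces are converted to displacement
through the pull rate (at 1 nm/ns, displacement in nm equals time in
ns numerically). Duplicate abscissae are averaged.

## Numerical choices and degenerate inputs

* RDF bins default to 0.002 nm; the two-atom profile reduces to the
  closed-form single-shell normalization, and $S(q)$ of a single pair
  reproduces the Debye form $1 + \sin(qd)/qd$ (the finite-volume
  background term vanishes as the normalization volume grows).
* `find_peaks` on a flat profile returns an empty table, not an error;
  boundary maxima are not refined.
* `measure_dimensions` rounds to 0.1 nm, the precision at which such
  dimensions are quoted.
* Builder validation: chains come in whole cellobiose repeats (even
  `n_units`); degenerate 1x1 grids classify as a single layer-1 chain.
* All generators restore the caller's RNG state; the same seed gives
  bitwise-identical output.
* File round-trips hold to format precision (PDB 0.001 Å, GRO
  0.001 nm); chain partitions survive via chain identifiers (PDB) or
  residue-number resets (GRO); CONECT records carry the modified
  topology (no C2-C3 bond in `DAG` units).

## Problem sizes used by the test suite

The full 7x7x40 crystal (41,307 atoms) is built and analysed directly:
one three-class RDF/S(q) pass takes a few seconds through the compiled
cell-list kernel, and the four-recipe modification series with
jittering completes in about half a minute. Oracle-equivalence tests
run on 3x3 crystals where brute-force O(N^2) enumeration is cheap.
Parameter-recovery tests use 100 generator seeds.

## Known limitations

* The geometry is idealized: bond lengths and angles are textbook
  values fitted to the screw constraint, not refined coordinates;
  analyses that depend on sub-0.1-Å detail should re-derive the
  template from refined structures.
* Static crystals plus i.i.d. jitter cannot reproduce observables that
  are intrinsically thermodynamic: absolute hydrogen-bond counts of
  solvated systems, torsional broadening, water penetration, or the
  position shift of the merged (1-10)/(110) reflection discussed
  above.
* The dialcohol geometry is unrelaxed by design; downstream engines
  must minimize before use.
* Engineering stress uses one constant contact area; evolving-contact
  (true stress) analyses are out of scope.
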